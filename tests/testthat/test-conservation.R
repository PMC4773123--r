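seq21 <- "UCGGACCAGGCUUCAUUCCCCC"

test_that("the rate counts other-species entries matching the query", {
  ref <- dplyr::bind_rows(
    make_reference(seq21, "miR166a", species = "ath"),
    make_reference(seq21, "miR166b", species = "osa"),
    make_reference(seq21, "miR166c", species = "gma"),
    make_reference(seq21, "miR166x", species = "mol"),  # query species
    make_reference("AAGCUCAGGAGGGAUAGCGCC", "miR390a", species = "ath"))
  q <- tibble::tibble(mirna_name = "mol-miR166i", sequence = seq21,
                      count = 100L)
  out <- conservation_rate(q, ref, query_species = "mol")
  expect_equal(out$conservation_rate, 3L)
  expect_equal(out$seed_count, 100L)

  own_only <- make_reference(seq21, "miR166x", species = "mol")
  expect_warning(out0 <- conservation_rate(q, own_only, "mol"),
                 "no other-species")
  expect_equal(out0$conservation_rate, 0L)
})

test_that("duplicating the reference doubles every exact rate", {
  cfg <- simulation_config(seed = 19, n_families = 8)
  refs <- build_references(cfg)
  q <- dplyr::distinct(refs$plant, sequence, .keep_all = TRUE) |>
    dplyr::transmute(mirna_name = name, sequence = sequence, count = 1L)
  once <- conservation_rate(q, refs$plant, "mol")
  twice <- conservation_rate(q, dplyr::bind_rows(refs$plant, refs$plant),
                             "mol")
  expect_equal(twice$conservation_rate, 2L * once$conservation_rate)
})

test_that("containment mode never scores below exact mode", {
  cfg <- simulation_config(seed = 19, n_families = 8)
  refs <- build_references(cfg)
  q <- dplyr::distinct(refs$plant, sequence, .keep_all = TRUE) |>
    dplyr::transmute(mirna_name = name, sequence = sequence, count = 1L)
  exact <- conservation_rate(q, refs$plant, "mol", "exact_equal")
  cont <- conservation_rate(q, refs$plant, "mol",
                            "containment_either_direction")
  expect_true(all(cont$conservation_rate >= exact$conservation_rate))
})

test_that("rates agree with a brute-force all-pairs scan and planted truth", {
  cfg <- simulation_config(seed = 29, n_families = 10,
                           conserved_fraction = 0.5)
  refs <- build_references(cfg)
  q <- dplyr::distinct(refs$plant, sequence, .keep_all = TRUE) |>
    dplyr::transmute(mirna_name = name, sequence = sequence, count = 1L)
  for (mode in c("exact_equal", "containment_either_direction")) {
    got <- conservation_rate(q, refs$plant, "mol", mode)
    oracle <- vapply(q$sequence, oracle_conservation, integer(1),
                     reference = refs$plant, query_species = "mol",
                     mode = mode, USE.NAMES = FALSE)
    expect_equal(got$conservation_rate, oracle)
  }
  truth <- refs$truth$conservation
  got <- conservation_rate(
    tibble::tibble(mirna_name = "x", sequence = truth$sequence, count = 1L),
    refs$plant, "mol")
  expect_equal(got$conservation_rate, truth$n_entries)
})

test_that("ranking orders by rate, then seed count, then name", {
  t3 <- load_fixture("table3") |>
    dplyr::rename(mirna_name = name, seed_count = read_count)
  top <- rank_by_conservation(t3, top_n = 1)
  expect_equal(top$mirna_name, "mol-miR166i")
  expect_equal(top$conservation_rate, 147)

  ties <- tibble::tibble(mirna_name = c("b", "a"),
                         sequence = c("ACGU", "UGCA"),
                         conservation_rate = c(5L, 5L),
                         seed_count = c(5L, 10L))
  expect_equal(rank_by_conservation(ties, 2)$mirna_name, c("a", "b"))
  expect_equal(nrow(rank_by_conservation(ties, 10)), 2)
})

test_that("correlation is exact on collinear points and errs on degenerate input", {
  lin <- tibble::tibble(conservation_rate = 1:5,
                        seed_count = 10^(1:5))
  expect_equal(conservation_abundance_correlation(lin)$estimate, 1.0)
  anti <- tibble::tibble(conservation_rate = 1:5,
                         seed_count = 10^(5:1))
  expect_equal(conservation_abundance_correlation(anti)$estimate, -1.0)

  expect_error(
    conservation_abundance_correlation(lin[1:2, ]),
    class = "seedmir_undefined_correlation")
  flat <- tibble::tibble(conservation_rate = rep(3L, 4),
                         seed_count = 10^(1:4))
  expect_error(conservation_abundance_correlation(flat),
               class = "seedmir_undefined_correlation")
})

test_that("the published top-20 table gives the hand-computed correlation", {
  t3 <- load_fixture("table3") |>
    dplyr::rename(mirna_name = name, seed_count = read_count)
  ct <- conservation_abundance_correlation(t3)
  # frozen value from an explicit sum-formula Pearson on the 20 printed pairs
  expect_equal(ct$estimate, 0.0673889819, tolerance = 1e-8)
  expect_equal(ct$n, 20L)
  td <- tidy(ct)
  expect_equal(td$estimate, ct$estimate)
  expect_equal(glance(ct)$n, 20L)
})
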