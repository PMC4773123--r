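test_that("overlays report per-position agreement in the animal frame", {
  s <- "ACGUACGUACGUACGUACGUA"  # 21 nt
  full <- overlay(s, s, 0)
  expect_equal(full$matches, 21)
  expect_equal(full$alignment_length, 21)
  expect_false(grepl("-", full$pattern, fixed = TRUE))

  animal <- strrep("AC", 10)                 # 20-mer
  plant <- substr(animal, 1, 10)             # covers positions 1-10
  half <- overlay(plant, animal, 0)
  expect_equal(half$matches, 10)
  expect_equal(half$alignment_length, 20)
  expect_equal(half$pattern, paste0(plant, strrep("-", 10)))

  expect_error(overlay("ACGUACGUAC", "ACGUACGUAC", 15),
               class = "seedmir_invalid_offset")
})

test_that("pattern scoring reproduces every published r-value", {
  t5 <- load_fixture("table5")
  scored <- score_pattern(t5$pattern)
  expect_equal(scored$r_value_rounded, t5$r_value)
  # spot-check the reconstruction arithmetic on three rows
  expect_equal(scored$matches[t5$plant_name == "mol-miR166i"], 14L)
  expect_equal(scored$alignment_length[t5$plant_name == "mol-miR166i"], 21L)
  expect_equal(scored$matches[t5$plant_name == "mol-miR6478"], 14L)
  expect_equal(scored$matches[t5$plant_name == "mol-miR168a"], 12L)
})

test_that("pattern scoring handles degenerate and malformed patterns", {
  z <- score_pattern("----")
  expect_equal(z$matches, 0L)
  expect_equal(z$r_value, 0)
  expect_error(score_pattern("ACGT-"), class = "seedmir_malformed_pattern")
})

test_that("an identical pair scores a perfect, passing comparison", {
  s <- "UCGCUUGGUGCAGGUCGGGAC"
  res <- compare_pair(s, s)
  expect_equal(res$r_value, 1.0)
  expect_equal(res$offset, 0L)
  expect_equal(res$seed_matches, 7L)  # full 2-8 window
  expect_true(res$passes)
})

test_that("pass thresholds act on r-value and seed matches independently", {
  s <- "UCGCUUGGUGCAGGUCGGGAC"
  res <- compare_pair(s, s, compare_params(r_min = 0.55, seed_min = 5))
  over <- compare_pair(s, s, compare_params(r_min = 1.0, seed_min = 8))
  expect_true(res$passes)
  expect_false(over$passes)
  # a best r-value below the floor fails even with a perfect seed
  d6 <- "UCGCUUGacGCAGGacGGGgg"  # would-be mismatches in lowercase
  res2 <- compare_pair(toupper(chartr("acg", "acg", d6)), s,
                       compare_params(r_min = 0.99, seed_min = 1))
  expect_false(res2$passes)
})

test_that("Hamming-distance pairs score (L - d) / L at offset zero", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      L <- 21L
      p <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
      d <- sample(0:6, 1)
      a <- strsplit(p, "")[[1]]
      if (d > 0) {
        pos <- sample(L, d)
        for (k in pos) a[k] <- setdiff(c("A", "C", "G", "U"), a[k])[1]
      }
      a <- paste(a, collapse = "")
      res <- compare_pair(p, a, compare_params(seed_min = 0))
      oracle <- oracle_best_overlay(p, a, 10)
      expect_equal(res$matches, oracle$matches)
      expect_gte(res$matches, L - d)  # offset 0 is always admissible
    }
  })
})

test_that("best-offset selection matches exhaustive enumeration", {
  withr::with_seed(37, {
    for (rep in 1:10) {
      lp <- sample(17:30, 1)
      la <- sample(17:30, 1)
      p <- paste(sample(c("A", "C", "G", "U"), lp, TRUE), collapse = "")
      a <- paste(sample(c("A", "C", "G", "U"), la, TRUE), collapse = "")
      res <- compare_pair(p, a, compare_params(seed_min = 0))
      oracle <- oracle_best_overlay(p, a, 10)
      expect_equal(res$matches, oracle$matches)
      expect_equal(res$offset, oracle$offset)
    }
  })
})

test_that("r-values are invariant under consistent U/T relabeling", {
  p <- "TCGCTTGGTGCAGGTCGGGAC"
  a <- "TCGCTTGGTGCAGGTCGGTTT"
  rna <- compare_pair(chartr("T", "U", p), chartr("T", "U", a))
  dna <- compare_pair(p, a)
  expect_equal(dna$r_value, rna$r_value)
})

test_that("library screening finds self-pairs and is monotone in r_min", {
  cfg <- simulation_config(seed = 41, n_families = 6, n_animal = 8)
  refs <- build_references(cfg)
  plant <- dplyr::distinct(refs$plant, sequence, .keep_all = TRUE)[1:8, ]

  self <- compare_libraries(plant, plant,
                            compare_params(r_min = 0.99, seed_min = 5))
  expect_gte(nrow(self), nrow(plant))
  expect_true(all(self$r_value[self$plant_name == self$animal_name] == 1))

  loose <- compare_libraries(plant, refs$animal,
                             compare_params(r_min = 0.4, seed_min = 0))
  strict <- compare_libraries(plant, refs$animal,
                              compare_params(r_min = 0.7, seed_min = 0))
  key <- function(x) paste(x$plant_name, x$animal_name)
  expect_true(all(key(strict) %in% key(loose)))
})
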