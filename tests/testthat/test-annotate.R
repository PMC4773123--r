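rrna <- paste0("AAGGCUGCAUGCUAGCUAGCAUCGAUCGAUGCUAGCAUGCAUGCAUGGAU",
               "CCGAUCGAUCGAUCGAUUAGCAUCGAUCAGUCAGUCAGUCAUGCAUCGAU")
ncref <- make_reference(rrna, "rRNA1", species = "sim", rna_class = "rRNA")

test_that("ncRNA subtraction removes exact full-tag substrings only", {
  window <- substr(rrna, 11, 30)
  mismatched <- paste0(substr(window, 1, 19),
                       setdiff(c("A", "C", "G", "U"),
                               substr(window, 20, 20))[1])
  tags <- tibble::tibble(sequence = c(window, mismatched, "ACGUACGUACGUAC"),
                         count = c(5L, 5L, 5L))
  out <- subtract_ncrna(tags, ncref, min_tag_length = 15)
  expect_equal(out$removed$sequence, window)
  expect_equal(out$retained$sequence, mismatched)
  expect_equal(out$short$sequence, "ACGUACGUACGUAC")
  expect_equal(out$stage_counts$surviving, c(2L, 1L))
})

test_that("an empty ncRNA reference is a configuration error", {
  tags <- tibble::tibble(sequence = "ACGUACGUACGUACGU", count = 1L)
  expect_error(subtract_ncrna(tags, ncref[0, ]), class = "seedmir_config")
})

test_that("conserved identification needs full-length identity and 10 copies", {
  ref <- make_reference(
    c("UCGCUUGGUGCAGGUCGGGAC", "UUUGGAUUGAAGGGAGCUCUA"),
    c("miR168a", "miR159a"), species = "osa")
  tags <- tibble::tibble(
    sequence = c("UCGCUUGGUGCAGGUCGGGAC",      # exact, abundant
                 "UUUGGAUUGAAGGGAGCUCUA",      # exact, below floor
                 "UCGCUUGGUGCAGGUCGGGA",       # truncated: no overhang match
                 "GGGGCCCCAAAAUUUUGGCC"),      # matches nothing
    count = c(165L, 9L, 50L, 20L))
  out <- identify_conserved(tags, ref, species_prefix = "mol", min_count = 10)
  expect_equal(out$annotations$assigned_name, "mol-miR168a")
  expect_equal(out$annotations$family, "miR168")
  expect_equal(out$annotations$count, 165L)
  expect_equal(out$below_abundance$count, 9L)
  expect_setequal(out$unmatched$sequence,
                  c("UCGCUUGGUGCAGGUCGGGA", "GGGGCCCCAAAAUUUUGGCC"))
})

test_that("multi-species identical matches take the smallest name and keep all sources", {
  seq21 <- "UCGGACCAGGCUUCAUUCCCCC"
  ref <- dplyr::bind_rows(
    make_reference(seq21, "miR166i", species = "osa"),
    make_reference(seq21, "miR166a", species = "ath"),
    make_reference(seq21, "miR166b", species = "ath"))
  tags <- tibble::tibble(sequence = seq21, count = 100L)
  out <- identify_conserved(tags, ref, species_prefix = "mol")
  expect_equal(out$annotations$assigned_name, "mol-miR166a")
  expect_equal(out$annotations$sources,
               "ath-miR166a;ath-miR166b;osa-miR166i")
})

test_that("novel candidates keep unmatched tags of 18 nt and longer", {
  unmatched <- tibble::tibble(
    sequence = c(strrep("ACGUG", 4) |> substr(1, 17),
                 substr(strrep("ACGUG", 4), 1, 18),
                 substr(strrep("ACGUG", 5), 1, 21)),
    count = c(3L, 3L, 3L))
  expect_equal(nrow(extract_novel_candidates(unmatched, 18)), 2)
  expect_equal(nrow(extract_novel_candidates(unmatched[0, ], 18)), 0)
})

test_that("family summaries aggregate both arms and skip absent counts", {
  one <- tibble::tibble(assigned_name = "mol-miR393c", count = 11813L)
  fam <- family_summary(one)
  expect_equal(fam$family, "miR393")
  expect_equal(fam$total_count, 11813)

  both <- tibble::tibble(member = c("mol-miR156f", "mol-miR156h"),
                         mir_count = c(86L, 33L),
                         mirstar_count = c(34L, NA))
  fam2 <- family_summary(both)
  expect_equal(fam2$n_members, 2L)
  expect_equal(fam2$total_count, 86 + 34 + 33)
})

test_that("length distributions weight by read or by tag", {
  tags <- tibble::tibble(
    sequence = c(strrep("A C G U G C A", 3) |> gsub(" ", "", x = _) |>
                   substr(1, 21), substr(strrep("ACGGUCA", 4), 1, 24)),
    count = c(3L, 1L))
  by_read <- length_distribution(tags, "by_read")
  expect_equal(by_read$proportion[by_read$length == 21], 0.75)
  expect_equal(by_read$proportion[by_read$length == 24], 0.25)
  by_tag <- length_distribution(tags, "by_tag")
  expect_equal(by_tag$proportion, c(0.5, 0.5))
  expect_equal(nrow(length_distribution(tags[0, ])), 0)
})

test_that("every tag lands in exactly one annotation bin", {
  cfg <- simulation_config(seed = 17, total_reads = 4000)
  refs <- build_references(cfg)
  lib <- simulate_library(cfg, refs)
  tags <- preprocess_reads(lib$reads)$tags
  ann <- annotate_tags(tags, refs$ncrna, refs$plant)
  bins <- c("short", "ncrna_removed", "conserved", "below_abundance",
            "candidate", "other_unmatched")
  n_bins <- vapply(ann[bins], nrow, integer(1))
  expect_equal(sum(n_bins), nrow(tags))
  seqs <- unlist(lapply(ann[bins], function(b) b$sequence),
                 use.names = FALSE)
  expect_equal(sort(seqs), sort(tags$sequence))  # no tag in two bins
})

test_that("exact-identity matching agrees with a brute-force all-pairs scan", {
  cfg <- simulation_config(seed = 23, total_reads = 3000, n_families = 10)
  refs <- build_references(cfg)
  lib <- simulate_library(cfg, refs)
  tags <- preprocess_reads(lib$reads)$tags
  tags <- tags[seq_len(min(nrow(tags), 200)), ]

  sub <- subtract_ncrna(tags, refs$ncrna, 15)
  oracle <- oracle_subtract(tags, refs$ncrna$sequence, 15)
  expect_equal(sub$retained$sequence, oracle$sequence)

  idc <- identify_conserved(sub$retained, refs$plant, min_count = 1)
  hit <- oracle_identify(sub$retained, refs$plant$sequence)
  expect_setequal(idc$annotations$sequence, sub$retained$sequence[hit])
  expect_setequal(idc$unmatched$sequence, sub$retained$sequence[!hit])
})

test_that("an error-free library is recovered exactly above the abundance floor", {
  cfg <- simulation_config(seed = 11, total_reads = 8000)
  refs <- build_references(cfg)
  lib <- simulate_library(cfg, refs)
  ann <- annotate_tags(preprocess_reads(lib$reads)$tags,
                       refs$ncrna, refs$plant, min_count = 10)
  truth <- lib$manifest[lib$manifest$class == "mirna" &
                          lib$manifest$count >= 10, ]
  expect_setequal(ann$annotations$sequence, truth$sequence)
  merged <- merge(ann$annotations, truth, by = "sequence")
  expect_equal(nrow(merged), nrow(truth))
  expect_equal(merged$count.x, merged$count.y)
  expect_equal(merged$assigned_name, paste0("mol-", merged$name))
})
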