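# Independent brute-force oracles: naive all-pairs scans and exhaustive
# offset enumeration, deliberately distinct code paths from the package
# implementations they check.

oracle_is_substring_of_any <- function(tag, references) {
  for (r in references) {
    if (grepl(tag, r, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

oracle_subtract <- function(tags, ref_seqs, min_len = 15) {
  keep <- logical(nrow(tags))
  for (i in seq_len(nrow(tags))) {
    s <- tags$sequence[i]
    keep[i] <- nchar(s) >= min_len && !oracle_is_substring_of_any(s, ref_seqs)
  }
  tags[keep, ]
}

oracle_identify <- function(tags, ref_seqs) {
  hit <- logical(nrow(tags))
  for (i in seq_len(nrow(tags))) {
    for (r in ref_seqs) {
      if (identical(tags$sequence[i], r)) hit[i] <- TRUE
    }
  }
  hit
}

oracle_conservation <- function(query_seq, reference, query_species,
                                mode = "exact_equal") {
  n <- 0L
  for (i in seq_len(nrow(reference))) {
    if (reference$species_code[i] == query_species) next
    if (reference$rna_class[i] != "miRNA") next
    r <- reference$sequence[i]
    ok <- if (mode == "exact_equal") {
      identical(query_seq, r)
    } else {
      grepl(query_seq, r, fixed = TRUE) || grepl(r, query_seq, fixed = TRUE)
    }
    if (ok) n <- n + 1L
  }
  n
}

# Exhaustive best-offset search by sliding character-by-character.
oracle_best_overlay <- function(plant, animal, min_overlap = 10) {
  p <- strsplit(plant, "")[[1]]
  a <- strsplit(animal, "")[[1]]
  best_m <- -1L; best_o <- NA
  for (o in seq(-(length(p) - 1), length(a) - 1)) {
    m <- 0L; overlap <- 0L
    for (i in seq_along(a)) {
      j <- i - o
      if (j >= 1 && j <= length(p)) {
        overlap <- overlap + 1L
        if (p[j] == a[i]) m <- m + 1L
      }
    }
    if (overlap < min_overlap) next
    better <- m > best_m ||
      (m == best_m && (abs(o) < abs(best_o) ||
                       (abs(o) == abs(best_o) && o < best_o)))
    if (better) { best_m <- m; best_o <- o }
  }
  list(matches = best_m, offset = best_o)
}

make_reads <- function(seqs, quality = NULL, ids = NULL) {
  tibble::tibble(
    read_id = ids %||% paste0("r", seq_along(seqs)),
    sequence = seqs,
    quality = quality %||% strrep("I", nchar(seqs)))
}

make_reference <- function(seqs, names, species = "ath",
                           rna_class = "miRNA") {
  tibble::tibble(
    accession = paste0("ACC", seq_along(seqs)),
    species_code = rep_len(species, length(seqs)),
    name = names,
    family = ifelse(rep_len(rna_class, length(seqs)) == "miRNA",
                    derive_family(names), NA),
    rna_class = rep_len(rna_class, length(seqs)),
    sequence = seqs,
    arm = "unspecified")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
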