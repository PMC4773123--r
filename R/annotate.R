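#' Subtract structural non-coding RNAs from a tag set
#'
#' The stringent pre-annotation filter: a tag is removed if and only if its
#' full sequence occurs as an exact contiguous substring of any reference
#' ncRNA (100% identity over the tag's whole length; no mismatch
#' tolerance, strand as given). Tags shorter than `min_tag_length` are
#' removed here and counted separately.
#'
#' @param tags tibble of unique tags (`sequence`, `count`).
#' @param ncrna_reference reference tibble of rRNA/tRNA/snRNA/snoRNA and
#'   other structural RNA sequences.
#' @param min_tag_length inclusive length floor applied before matching.
#' @return list with `retained`, `removed` and `short` tag tibbles plus a
#'   `stage_counts` tibble.
#' @export
subtract_ncrna <- function(tags, ncrna_reference, min_tag_length = 15L) {
  if (is.null(ncrna_reference) || nrow(ncrna_reference) == 0) {
    seedmir_abort("ncRNA reference is empty; refusing to pass tags through",
                  "config")
  }
  n0 <- nrow(tags)
  short <- nchar(tags$sequence) < min_tag_length
  long_tags <- tags[!short, , drop = FALSE]
  # One concatenated subject (class-separated) instead of an all-pairs scan;
  # the '#' separator cannot occur inside a tag, so matches never span entries.
  subject <- paste(ncrna_reference$sequence, collapse = "#")
  hit <- if (nrow(long_tags)) {
    stringi::stri_detect_fixed(subject, long_tags$sequence)
  } else {
    logical(0)
  }
  list(
    retained = long_tags[!hit, , drop = FALSE],
    removed = long_tags[hit, , drop = FALSE],
    short = tags[short, , drop = FALSE],
    stage_counts = tibble(
      stage = c("short_tag_filter", "ncrna_subtraction"),
      entering = c(n0, n0 - sum(short)),
      surviving = c(n0 - sum(short), sum(!hit))))
}

#' Identify conserved miRNAs by full-length identity
#'
#' A tag is annotated if and only if it is character-identical to a mature
#' reference sequence — full length in both directions, no overhangs and
#' no mismatches. Matched tags below the abundance floor are dropped from
#' the annotation output (reported separately); unmatched tags are
#' returned for novel-candidate extraction. When several reference species
#' carry the identical sequence the assigned name follows the
#' lexicographically smallest (species code, member name) pair and every
#' source is recorded.
#'
#' @param tags tibble of tags surviving ncRNA subtraction.
#' @param reference mature miRNA reference tibble ([load_reference()]).
#' @param species_prefix species code stamped onto assigned names.
#' @param min_count abundance floor (inclusive): tags with fewer copies are
#'   excluded from the annotation output.
#' @return list with `annotations` (assigned_name, family, arm, sequence,
#'   count, source columns), `unmatched` tags, and `below_abundance`
#'   matched-but-rare tags.
#' @export
identify_conserved <- function(tags, reference, species_prefix = "mol",
                               min_count = 10L) {
  ref <- dplyr::filter(reference, .data$rna_class == "miRNA")
  hits <- tags |>
    inner_join(ref, by = "sequence", relationship = "many-to-many") |>
    group_by(.data$sequence) |>
    arrange(.data$species_code, .data$name, .by_group = TRUE) |>
    summarise(
      sources = paste(paste0(.data$species_code, "-", .data$name),
                      collapse = ";"),
      name = first(.data$name),
      family = first(.data$family),
      arm = first(.data$arm),
      accession = first(.data$accession),
      species_code = first(.data$species_code),
      count = first(.data$count),
      .groups = "drop")

  annotations <- hits |>
    dplyr::filter(.data$count >= min_count) |>
    transmute(
      assigned_name = paste0(species_prefix, "-", .data$name),
      family = .data$family,
      arm = ifelse(.data$arm == "unspecified", "mature", .data$arm),
      sequence = .data$sequence,
      count = .data$count,
      source_reference = paste0(.data$species_code, "-", .data$name),
      source_accession = .data$accession,
      sources = .data$sources) |>
    arrange(dplyr::desc(.data$count), .data$assigned_name)

  below <- hits |>
    dplyr::filter(.data$count < min_count) |>
    select("sequence", "count")

  unmatched <- anti_join(tags, ref, by = "sequence")
  list(annotations = annotations, unmatched = unmatched,
       below_abundance = below)
}

#' Extract novel-miRNA candidate tags
#'
#' Unmatched tags of at least `novel_min_length` nucleotides, ready to be
#' written as FASTA input for external novel-miRNA predictors. No duplex
#' or hairpin prediction is performed here.
#'
#' @param unmatched unmatched-tag tibble from [identify_conserved()].
#' @param novel_min_length inclusive length floor (18 nt guards against
#'   degraded-mRNA contamination).
#' @return candidate tag tibble.
#' @export
extract_novel_candidates <- function(unmatched, novel_min_length = 18L) {
  filter_length(unmatched, novel_min_length)
}

#' Write candidate tags as FASTA
#'
#' @param candidates tag tibble (`sequence`, `count`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  x <- tibble(
    header = sprintf("candidate_%05d count=%d",
                     seq_len(nrow(candidates)), candidates$count),
    sequence = candidates$sequence)
  write_fasta(x, path)
}

#' Summarise annotations by miRNA family
#'
#' Groups records by the derived family name (see [derive_family()]) and
#' totals all present read counts; absent (`NA`) arm counts contribute
#' nothing. Accepts either annotation output (`assigned_name`, `count`) or
#' a catalogue-style table with `member`, `mir_count` and `mirstar_count`
#' columns. Duplicate member labels count as distinct members.
#'
#' @param x tibble of annotated miRNAs.
#' @return tibble with `family`, `n_members`, `total_count`, ordered by
#'   descending total count.
#' @export
family_summary <- function(x) {
  name_col <- intersect(c("member", "assigned_name", "mirna_name", "name"),
                        names(x))[1]
  if (is.na(name_col)) {
    seedmir_abort("no miRNA name column found", "config")
  }
  count_cols <- intersect(c("count", "mir_count", "mirstar_count"), names(x))
  if (!length(count_cols)) {
    seedmir_abort("no count column found", "config")
  }
  totals <- rowSums(as.matrix(x[count_cols]), na.rm = TRUE)
  tibble(family = derive_family(x[[name_col]]), member_total = totals) |>
    group_by(.data$family) |>
    summarise(n_members = n(), total_count = sum(.data$member_total),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$total_count), .data$family)
}

#' Length distribution of reads or tags
#'
#' @param x tibble with a `sequence` column; a `count` column is used for
#'   read weighting when present.
#' @param weighting `"by_read"` weights each tag by its copy number;
#'   `"by_tag"` counts unique sequences once.
#' @return tibble with `length`, `n` and `proportion` (summing to 1 over
#'   observed lengths); empty input gives an empty tibble.
#' @export
length_distribution <- function(x, weighting = c("by_read", "by_tag")) {
  weighting <- match.arg(weighting)
  out <- tibble(length = integer(), n = numeric(), proportion = numeric())
  if (nrow(x) == 0) return(structure(out, class = c("seedmir_lengthdist", class(out))))
  w <- if (weighting == "by_read" && "count" %in% names(x)) x$count else
    rep(1, nrow(x))
  out <- tibble(length = nchar(x$sequence), w = w) |>
    group_by(.data$length) |>
    summarise(n = sum(.data$w), .groups = "drop") |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    arrange(.data$length)
  structure(out, class = c("seedmir_lengthdist", class(out)))
}

#' Classify every tag of a library into exactly one bin
#'
#' Convenience wrapper running ncRNA subtraction, conserved identification
#' and candidate extraction, and returning the partition of the input tag
#' set: `short`, `ncrna_removed`, `conserved`, `below_abundance`,
#' `candidate` and `other_unmatched`. Bin totals sum to the input total.
#'
#' @param tags tibble of unique tags.
#' @param ncrna_reference,mirna_reference reference tibbles.
#' @param species_prefix species code for assigned names.
#' @param min_tag_length,min_count,novel_min_length filter thresholds.
#' @return list of bins plus `annotations` and combined `stage_counts`.
#' @export
annotate_tags <- function(tags, ncrna_reference, mirna_reference,
                          species_prefix = "mol", min_tag_length = 15L,
                          min_count = 10L, novel_min_length = 18L) {
  sub <- subtract_ncrna(tags, ncrna_reference, min_tag_length)
  idc <- identify_conserved(sub$retained, mirna_reference,
                            species_prefix, min_count)
  candidates <- extract_novel_candidates(idc$unmatched, novel_min_length)
  other <- dplyr::filter(idc$unmatched,
                         nchar(.data$sequence) < novel_min_length)
  stage_counts <- bind_rows(
    sub$stage_counts,
    tibble(stage = "conserved_identification",
           entering = nrow(sub$retained),
           surviving = nrow(idc$annotations) + nrow(idc$below_abundance)),
    tibble(stage = "abundance_filter",
           entering = nrow(idc$annotations) + nrow(idc$below_abundance),
           surviving = nrow(idc$annotations)),
    tibble(stage = "novel_candidate_filter",
           entering = nrow(idc$unmatched),
           surviving = nrow(candidates)))
  list(short = sub$short,
       ncrna_removed = sub$removed,
       conserved = dplyr::semi_join(sub$retained, idc$annotations,
                                    by = "sequence"),
       below_abundance = sub$retained |>
         dplyr::semi_join(idc$below_abundance, by = "sequence"),
       candidate = candidates,
       other_unmatched = other,
       annotations = idc$annotations,
       stage_counts = stage_counts)
}
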