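#' Preprocessing parameters
#'
#' Defaults follow common small RNA practice: 3' adapter clipping with a
#' 5-base minimum anchor, Phred-20 end trimming, and a 15-nt post-trim
#' length floor below which inserts are discarded.
#'
#' @param adapter 3' adapter sequence (DNA or RNA alphabet).
#' @param min_length minimum insert length kept after trimming.
#' @param quality_threshold Phred score below which terminal bases are
#'   trimmed from either end.
#' @param min_adapter_overlap minimum number of adapter bases that must
#'   match at the read's 3' end for a partial adapter to be clipped.
#' @param keep_unclipped keep reads in which no adapter was found (the
#'   insert may simply fill the whole read).
#' @return a `seedmir_preprocess_params` list.
#' @export
preprocess_params <- function(adapter = "TGGAATTCTCGGGTGCCAAGG",
                              min_length = 15L,
                              quality_threshold = 20L,
                              min_adapter_overlap = 5L,
                              keep_unclipped = TRUE) {
  stopifnot(min_length >= 1, min_adapter_overlap >= 1)
  structure(list(adapter = adapter,
                 min_length = as.integer(min_length),
                 quality_threshold = as.integer(quality_threshold),
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 keep_unclipped = isTRUE(keep_unclipped)),
            class = "seedmir_preprocess_params")
}

#' Clip the 3' adapter from reads
#'
#' Exact matching with no mismatch tolerance. A read is truncated at the
#' leftmost position where the adapter matches for
#' `min(adapter length, bases remaining)` bases, provided that overlap is
#' at least `min_overlap` — i.e. either the full adapter occurs, or an
#' adapter prefix of at least `min_overlap` bases runs off the read's 3'
#' end. Reads with no such occurrence are returned unmodified and flagged
#' in the logical `clipped` column.
#'
#' @param reads tibble with `sequence` (and optionally `quality`) columns.
#' @param adapter adapter sequence.
#' @param min_overlap minimum anchor length.
#' @return `reads` with truncated `sequence`/`quality` and a `clipped` flag.
#' @export
clip_adapter <- function(reads, adapter, min_overlap = 5L) {
  ad <- normalize_sequence(adapter)
  alen <- nchar(ad)
  if (alen < min_overlap) {
    seedmir_abort("adapter is shorter than the minimum overlap", "config")
  }
  s <- reads$sequence
  len <- nchar(s)
  cut <- stringi::stri_locate_first_fixed(s, ad)[, 1]
  upper <- if (length(len)) min(alen - 1L, max(len)) else 0L
  if (upper >= min_overlap) {
    for (k in seq(upper, min_overlap)) {
      idx <- which(is.na(cut) & len >= k &
                     stringi::stri_endswith_fixed(s, stringi::stri_sub(ad, 1, k)))
      if (length(idx)) cut[idx] <- len[idx] - k + 1L
    }
  }
  clipped <- !is.na(cut)
  newlen <- ifelse(clipped, cut - 1L, len)
  reads$sequence <- stringi::stri_sub(s, 1, newlen)
  if ("quality" %in% names(reads)) {
    reads$quality <- stringi::stri_sub(reads$quality, 1, newlen)
  }
  reads$clipped <- clipped
  reads
}

#' Trim low-quality terminal bases
#'
#' Removes the longest run of bases with quality below `threshold` from
#' each end of the read; interior bases are never touched. Reads without
#' quality strings pass through with a warning.
#'
#' @param reads tibble with `sequence` and `quality` columns.
#' @param threshold Phred score; terminal bases strictly below it are
#'   trimmed.
#' @param phred_offset ASCII offset of the quality encoding (33 for
#'   Sanger/Illumina 1.8+).
#' @return `reads` with trimmed sequences and qualities.
#' @export
trim_quality <- function(reads, threshold = 20L, phred_offset = 33L) {
  if (!"quality" %in% names(reads) || all(is.na(reads$quality))) {
    warn("reads carry no quality scores; quality trimming skipped")
    return(reads)
  }
  trimmed <- mapply(function(sq, qu) {
    if (is.na(qu) || !nzchar(qu)) return(c(sq, qu))
    q <- utf8ToInt(qu) - phred_offset
    ok <- which(q >= threshold)
    if (!length(ok)) return(c("", ""))
    i <- ok[1]; j <- ok[length(ok)]
    c(substr(sq, i, j), substr(qu, i, j))
  }, reads$sequence, reads$quality, USE.NAMES = FALSE)
  reads$sequence <- trimmed[1, ]
  reads$quality <- trimmed[2, ]
  reads
}

#' Discard reads or tags shorter than a length floor
#'
#' The cutoff is inclusive: a 15-nt insert survives `min_len = 15`.
#'
#' @param x tibble with a `sequence` column (reads or collapsed tags).
#' @param min_len minimum length retained.
#' @return the surviving rows.
#' @export
filter_length <- function(x, min_len = 15L) {
  stopifnot(min_len >= 1)
  dplyr::filter(x, nchar(.data$sequence) >= min_len)
}

is_artifact_seq <- function(s) {
  vapply(s, function(x) {
    if (grepl("N", x, fixed = TRUE)) return(TRUE)
    n <- nchar(x)
    if (n == 0) return(FALSE)
    ch <- unique(strsplit(x, "", fixed = TRUE)[[1]])
    if (length(ch) == 1) return(TRUE)
    if (length(ch) == 2 && n >= 4) {
      unit <- substr(x, 1, 2)
      if (substr(unit, 1, 1) != substr(unit, 2, 2)) {
        rep2 <- substr(strrep(unit, ceiling(n / 2)), 1, n)
        return(identical(rep2, x))
      }
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' Remove sequencing artifacts
#'
#' Drops reads containing `N` and reads that are pure homopolymers or
#' dinucleotide repeats spanning the whole insert.
#'
#' @param reads tibble with a `sequence` column.
#' @return the surviving rows.
#' @export
remove_artifacts <- function(reads) {
  reads[!is_artifact_seq(reads$sequence), , drop = FALSE]
}

#' Collapse reads to unique tags
#'
#' One tag per distinct sequence with its multiplicity; the sum of counts
#' equals the number of input reads. Order is deterministic: descending
#' count, then lexicographic sequence.
#'
#' @param reads tibble with a `sequence` column.
#' @return tibble with columns `sequence`, `count`.
#' @export
collapse_reads <- function(reads) {
  reads |>
    count(.data$sequence, name = "count") |>
    arrange(dplyr::desc(.data$count), .data$sequence) |>
    as_tibble()
}

#' Run the read-preprocessing cascade
#'
#' Adapter clipping, optional removal of unclipped reads, quality end
#' trimming, inclusive length filtering, artifact removal, and collapsing
#' to unique tags, with per-stage survivor accounting.
#'
#' @param reads tibble of raw reads from [read_fastq()].
#' @param params a [preprocess_params()] list.
#' @return list with `tags` (unique tags), `reads` (surviving reads before
#'   collapsing), and `stage_counts` (tibble: stage, entering, surviving).
#' @export
preprocess_reads <- function(reads, params = preprocess_params()) {
  stages <- list()
  note <- function(stage, entering, surviving) {
    stages[[length(stages) + 1]] <<-
      tibble(stage = stage, entering = entering, surviving = surviving)
  }

  n0 <- nrow(reads)
  reads <- clip_adapter(reads, params$adapter, params$min_adapter_overlap)
  note("adapter_clip", n0, nrow(reads))
  if (!params$keep_unclipped) {
    n <- nrow(reads)
    reads <- dplyr::filter(reads, .data$clipped)
    note("unclipped_drop", n, nrow(reads))
  }
  if ("quality" %in% names(reads)) {
    n <- nrow(reads)
    reads <- trim_quality(reads, params$quality_threshold)
    note("quality_trim", n, nrow(reads))
  }
  n <- nrow(reads)
  reads <- filter_length(reads, params$min_length)
  note("length_filter", n, nrow(reads))
  n <- nrow(reads)
  reads <- remove_artifacts(reads)
  note("artifact_filter", n, nrow(reads))
  tags <- collapse_reads(reads)
  note("collapse", nrow(reads), nrow(tags))

  list(tags = tags, reads = reads, stage_counts = bind_rows(stages))
}
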