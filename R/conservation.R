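#' Cross-species conservation rate
#'
#' For each query miRNA, counts the mature reference entries from species
#' other than the query species whose sequence matches. The default mode
#' requires exact full-length equality; `containment_either_direction`
#' additionally counts entries where one sequence is a contiguous
#' substring of the other. The unit is reference *entries*, not distinct
#' species: miRBase carries many near-duplicate records per family across
#' species and the rate reflects that redundancy.
#'
#' @param queries tibble of annotated miRNAs (any of `mirna_name`,
#'   `assigned_name`, `name` or `member` as name column; `count` or
#'   `read_count` carried through as `seed_count`).
#' @param reference mature miRNA reference tibble.
#' @param query_species species code excluded from the reference scan.
#' @param mode matching mode.
#' @return tibble with `mirna_name`, `sequence`, `conservation_rate`,
#'   `seed_count`.
#' @export
conservation_rate <- function(queries, reference, query_species = "mol",
                              mode = c("exact_equal",
                                       "containment_either_direction")) {
  mode <- match.arg(mode)
  name_col <- intersect(c("mirna_name", "assigned_name", "name", "member"),
                        names(queries))[1]
  if (is.na(name_col)) seedmir_abort("no miRNA name column found", "config")
  count_col <- intersect(c("count", "read_count", "seed_count"),
                         names(queries))[1]
  seed_count <- if (is.na(count_col)) NA_integer_ else queries[[count_col]]

  ref <- reference |>
    dplyr::filter(.data$rna_class == "miRNA",
                  .data$species_code != query_species)
  if (nrow(ref) == 0) {
    warn("reference holds no other-species miRNA entries; all rates are 0")
    rate <- rep(0L, nrow(queries))
  } else if (mode == "exact_equal") {
    tab <- table(ref$sequence)
    rate <- as.integer(tab[queries$sequence])
    rate[is.na(rate)] <- 0L
  } else {
    rate <- vapply(queries$sequence, function(q) {
      sum(stringi::stri_detect_fixed(ref$sequence, q) |
            stringi::stri_detect_fixed(q, ref$sequence))
    }, integer(1), USE.NAMES = FALSE)
  }
  tibble(mirna_name = queries[[name_col]],
         sequence = queries$sequence,
         conservation_rate = rate,
         seed_count = seed_count)
}

#' Rank miRNAs by conservation rate
#'
#' Descending conservation rate; ties broken by descending read count in
#' the study tissue, then by name.
#'
#' @param results tibble from [conservation_rate()] (or the packaged
#'   conservation fixture with matching columns).
#' @param top_n number of rows kept.
#' @return ordered, truncated tibble.
#' @export
rank_by_conservation <- function(results, top_n = 20L) {
  stopifnot(top_n >= 1)
  results |>
    arrange(dplyr::desc(.data$conservation_rate),
            dplyr::desc(.data$seed_count), .data$mirna_name) |>
    slice_head(n = top_n)
}

#' Correlation between conservation and abundance
#'
#' Pearson correlation between the conservation rate and log10 read count;
#' the log axis linearizes abundances spanning several orders of
#' magnitude. Requires at least 3 results with positive counts and
#' non-degenerate variance on both axes.
#'
#' @param results tibble with `conservation_rate` and `seed_count` (or
#'   `read_count`) columns.
#' @return a `seedmir_cor` object with [tidy()], [glance()], [autoplot()]
#'   and print methods.
#' @export
conservation_abundance_correlation <- function(results) {
  count_col <- intersect(c("seed_count", "read_count", "count"),
                         names(results))[1]
  if (is.na(count_col)) seedmir_abort("no read count column found", "config")
  x <- results$conservation_rate
  y <- results[[count_col]]
  keep <- !is.na(x) & !is.na(y) & y > 0
  if (any(!keep)) {
    warn(sprintf("dropping %d result(s) with missing or non-positive counts",
                 sum(!keep)))
  }
  x <- x[keep]; y <- log10(y[keep])
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
    seedmir_abort(
      "correlation undefined: need >= 3 points with variance on both axes",
      "undefined_correlation")
  }
  ct <- cor.test(x, y, method = "pearson")
  structure(
    list(estimate = unname(ct$estimate), n = length(x),
         statistic = unname(ct$statistic), p.value = ct$p.value,
         conf.low = ct$conf.int[1], conf.high = ct$conf.int[2],
         data = tibble(conservation_rate = x, log10_count = y)),
    class = "seedmir_cor")
}

#' @export
print.seedmir_cor <- function(x, ...) {
  cat(sprintf(
    "Conservation-abundance correlation (Pearson, rate vs log10 count)\n  r = %.4f  [%.4f, %.4f], n = %d, p = %.3g\n",
    x$estimate, x$conf.low, x$conf.high, x$n, x$p.value))
  invisible(x)
}

#' @rdname conservation_abundance_correlation
#' @param x a `seedmir_cor` object.
#' @param ... unused.
#' @export
tidy.seedmir_cor <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic,
         p.value = x$p.value, conf.low = x$conf.low, conf.high = x$conf.high)
}

#' @rdname conservation_abundance_correlation
#' @export
glance.seedmir_cor <- function(x, ...) {
  tibble(r = x$estimate, n = x$n, p.value = x$p.value)
}
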