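#' Parse printed read counts
#'
#' Report tables print counts with locale formatting: thousands separators
#' (`65,243`, and occasionally period-grouped `4.007`), literal `NA`
#' markers, and blank cells for absent arms. Blank and `NA` cells parse to
#' `NA`, never zero; absent counts contribute nothing at aggregation time.
#'
#' @param x character vector of printed count cells.
#' @return integer vector with `NA` for absent values.
#' @export
parse_count <- function(x) {
  out <- rep(NA_integer_, length(x))
  v <- trimws(as.character(x))
  present <- !is.na(v) & nzchar(v) & v != "NA"
  w <- v[present]
  grouped <- grepl("^[0-9]{1,3}(\\.[0-9]{3})+$", w)
  w[grouped] <- gsub(".", "", w[grouped], fixed = TRUE)
  w <- gsub(",", "", w, fixed = TRUE)
  bad <- !grepl("^[0-9]+$", w)
  if (any(bad)) {
    seedmir_abort(sprintf("cannot parse count value '%s'", w[which(bad)[1]]),
                  "count_parse")
  }
  out[present] <- as.integer(w)
  out
}

fixture_manifest <- list(
  table1 = list(
    file = "table1_known_mirnas.tsv", n_rows = 94L,
    cols = c("family", "member", "mir_sequence", "mirstar_sequence",
             "mir_count", "mirstar_count"),
    count_cols = c("mir_count", "mirstar_count"),
    seq_cols = c("mir_sequence", "mirstar_sequence")),
  table3 = list(
    file = "table3_conservation.tsv", n_rows = 20L,
    cols = c("name", "sequence", "conservation_rate", "read_count"),
    count_cols = c("conservation_rate", "read_count"),
    seq_cols = "sequence"),
  table5 = list(
    file = "table5_mircompare.tsv", n_rows = 9L,
    cols = c("human_name", "plant_name", "r_value", "pattern"),
    count_cols = character(),
    seq_cols = character()))

#' Load a packaged report-table fixture
#'
#' Three transcribed report tables ship with the package: the known-miRNA
#' catalogue with per-arm read counts (`table1`, 94 member records),
#' the top-20 cross-species conservation ranking (`table3`), and the
#' plant-human overlay screen with alignment patterns (`table5`, 9 pairs).
#' Rows are kept in printed order; duplicate member labels (the catalogue
#' holds two distinct `mol-miR167c` sequences) stay distinct records.
#'
#' @param table_id one of `"table1"`, `"table3"`, `"table5"`.
#' @return tibble with parsed count columns and normalized sequences; the
#'   table id is attached as attribute `table_id`.
#' @export
load_fixture <- function(table_id = c("table1", "table3", "table5")) {
  table_id <- match.arg(table_id)
  spec <- fixture_manifest[[table_id]]
  path <- system.file("extdata", spec$file, package = "seedmir",
                      mustWork = TRUE)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       na = character(), progress = FALSE)
  if (!identical(names(x), spec$cols) || nrow(x) != spec$n_rows) {
    seedmir_abort(
      sprintf("fixture '%s' does not match its packaged shape (%d rows, %s)",
              table_id, spec$n_rows, paste(spec$cols, collapse = ", ")),
      "fixture_integrity")
  }
  for (cc in spec$count_cols) x[[cc]] <- parse_count(x[[cc]])
  for (sc in spec$seq_cols) {
    has <- !is.na(x[[sc]]) & nzchar(x[[sc]])
    x[[sc]][!has] <- NA_character_
    x[[sc]][has] <- normalize_sequence(x[[sc]][has])
  }
  if (table_id == "table5") x$r_value <- as.numeric(x$r_value)
  attr(x, "table_id") <- table_id
  x
}
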