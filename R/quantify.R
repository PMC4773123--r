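#' Relative expression by the 2^-ddCt method
#'
#' Classic comparative-Ct quantification: replicate Ct values are averaged
#' per (sample, assay); dCt subtracts the endogenous-control assay within
#' each sample; ddCt subtracts the calibrator sample's dCt for the same
#' assay; the fold change is `2^-ddCt`, so the calibrator sample's fold is
#' 1 by construction. Replicate SD is carried through for reporting; no
#' amplification-efficiency correction is applied.
#'
#' @param data long tibble of Ct measurements with columns `sample`,
#'   `assay`, `ct` (one row per replicate well).
#' @param reference_assay endogenous-control miRNA assay name.
#' @param calibrator_sample sample whose expression defines fold 1.
#' @return tibble with per-(sample, assay) `n_reps`, `mean_ct`, `sd_ct`,
#'   `delta_ct`, `delta_delta_ct`, `fold`.
#' @export
ddct <- function(data, reference_assay, calibrator_sample) {
  need <- setdiff(c("sample", "assay", "ct"), names(data))
  if (length(need)) {
    seedmir_abort(paste("missing column(s):", paste(need, collapse = ", ")),
                  "config")
  }
  if (any(!is.finite(data$ct) | data$ct <= 0)) {
    seedmir_abort("Ct values must be finite and positive", "config")
  }
  agg <- data |>
    group_by(.data$sample, .data$assay) |>
    summarise(n_reps = n(), mean_ct = mean(.data$ct),
              sd_ct = sd(.data$ct), .groups = "drop")

  refs <- agg |>
    dplyr::filter(.data$assay == reference_assay) |>
    select("sample", ref_ct = "mean_ct")
  missing_ref <- setdiff(unique(agg$sample), refs$sample)
  if (length(missing_ref)) {
    seedmir_abort(
      sprintf("sample(s) without the reference assay '%s': %s",
              reference_assay, paste(missing_ref, collapse = ", ")),
      "incomplete_design")
  }
  if (!calibrator_sample %in% agg$sample) {
    seedmir_abort(sprintf("calibrator sample '%s' not present",
                          calibrator_sample), "incomplete_design")
  }

  agg <- agg |>
    left_join(refs, by = "sample") |>
    mutate(delta_ct = .data$mean_ct - .data$ref_ct)
  cal <- agg |>
    dplyr::filter(.data$sample == calibrator_sample) |>
    select("assay", cal_delta_ct = "delta_ct")
  out <- agg |>
    left_join(cal, by = "assay") |>
    mutate(delta_delta_ct = .data$delta_ct - .data$cal_delta_ct,
           fold = 2^(-.data$delta_delta_ct)) |>
    select(-"ref_ct", -"cal_delta_ct")
  if (anyNA(out$delta_delta_ct)) {
    warn("assay(s) absent from the calibrator sample yield NA fold changes")
  }
  out
}

#' Rescale fold changes to an anchor assay
#'
#' Divides every fold change by the anchor assay's fold within the same
#' sample, so the anchor maps to 1 and other assays are expressed relative
#' to it (the presentation used when one miRNA is declared the within-panel
#' control). Rescaling twice by the same anchor is a no-op.
#'
#' @param folds tibble from [ddct()] (columns `sample`, `assay`, `fold`).
#' @param anchor_assay assay whose fold becomes 1 in every sample.
#' @return `folds` with rescaled `fold`.
#' @export
normalize_to_assay <- function(folds, anchor_assay) {
  anchors <- folds |>
    dplyr::filter(.data$assay == anchor_assay) |>
    select("sample", anchor_fold = "fold")
  if (nrow(anchors) == 0) {
    seedmir_abort(sprintf("anchor assay '%s' not present", anchor_assay),
                  "incomplete_design")
  }
  missing <- setdiff(unique(folds$sample), anchors$sample)
  if (length(missing)) {
    seedmir_abort(
      sprintf("sample(s) without the anchor assay: %s",
              paste(missing, collapse = ", ")), "incomplete_design")
  }
  if (any(anchors$anchor_fold == 0)) {
    seedmir_abort("anchor fold of 0 leaves the rescale undefined",
                  "undefined_rescale")
  }
  folds |>
    left_join(anchors, by = "sample") |>
    mutate(fold = .data$fold / .data$anchor_fold) |>
    select(-"anchor_fold")
}
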