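#' Cross-kingdom comparison parameters
#'
#' Screening thresholds for plant-animal miRNA overlays: a pair passes
#' when its best r-value reaches `r_min` and at least `seed_min` of the
#' animal seed-region positions match. The canonical animal seed region is
#' positions 2-8 of the mature sequence; the window is a parameter because
#' coordinate conventions differ between tools.
#'
#' @param r_min minimum r-value (matched positions / animal length).
#' @param seed_min minimum matched positions inside the seed window.
#' @param seed_window 1-based inclusive positions on the animal sequence.
#' @param min_overlap minimum number of overlapping bases for an offset to
#'   be evaluated.
#' @return a `seedmir_compare_params` list.
#' @export
compare_params <- function(r_min = 0.55, seed_min = 5L,
                           seed_window = c(2L, 8L), min_overlap = 10L) {
  stopifnot(r_min >= 0, r_min <= 1, length(seed_window) == 2,
            seed_window[1] >= 1, seed_window[1] <= seed_window[2],
            min_overlap >= 1)
  structure(list(r_min = r_min, seed_min = as.integer(seed_min),
                 seed_window = as.integer(seed_window),
                 min_overlap = as.integer(min_overlap)),
            class = "seedmir_compare_params")
}

# Ungapped overlay of a plant sequence onto the animal frame at a fixed
# offset: animal position i pairs with plant position i - offset.
overlay_core <- function(p, a, offset) {
  la <- length(a)
  j <- seq_len(la) - offset
  cover <- j >= 1 & j <= length(p)
  eq <- logical(la)
  eq[cover] <- p[j[cover]] == a[cover]
  list(eq = eq, cover = cover)
}

#' Overlay a plant miRNA on an animal miRNA at a fixed offset
#'
#' The alignment frame is the animal sequence: the pattern has one
#' character per animal position, holding the plant base where the plant
#' sequence covers that position and agrees with the animal base, and
#' `-` otherwise (mismatch or uncovered). The alignment length is the
#' animal sequence length. Ungapped; offset 0 aligns both 5' ends.
#'
#' @param plant_seq,animal_seq normalized RNA sequences.
#' @param offset signed shift of the plant sequence along the animal frame
#'   (positive values slide the plant 3'-ward).
#' @return list with `pattern`, `matches`, `alignment_length`.
#' @export
overlay <- function(plant_seq, animal_seq, offset = 0L) {
  p <- strsplit(normalize_sequence(plant_seq), "", fixed = TRUE)[[1]]
  a <- strsplit(normalize_sequence(animal_seq), "", fixed = TRUE)[[1]]
  oc <- overlay_core(p, a, offset)
  if (!any(oc$cover)) {
    seedmir_abort(sprintf("offset %d leaves no overlap", offset),
                  "invalid_offset")
  }
  pattern <- rep("-", length(a))
  pattern[oc$eq] <- a[oc$eq]
  list(pattern = paste(pattern, collapse = ""),
       matches = sum(oc$eq),
       alignment_length = length(a))
}

#' Score one plant-animal miRNA pair
#'
#' Evaluates the ungapped overlay at every offset with at least
#' `min_overlap` overlapping bases and keeps the offset maximizing the
#' number of matches (ties: smaller absolute offset, then smaller offset).
#' The r-value is matches divided by the animal sequence length; seed
#' matches are counted inside the animal-frame seed window.
#'
#' @param plant_seq,animal_seq RNA (or DNA) sequences.
#' @param params a [compare_params()] list.
#' @param plant_name,animal_name optional labels carried into the result.
#' @return one-row tibble: names, `offset`, `pattern`, `matches`,
#'   `alignment_length`, `r_value`, `r_value_rounded` (half-up, 2
#'   decimals, the reporting convention), `seed_matches`, `passes`.
#' @export
compare_pair <- function(plant_seq, animal_seq, params = compare_params(),
                         plant_name = NA_character_,
                         animal_name = NA_character_) {
  p <- strsplit(normalize_sequence(plant_seq), "", fixed = TRUE)[[1]]
  a <- strsplit(normalize_sequence(animal_seq), "", fixed = TRUE)[[1]]
  lp <- length(p); la <- length(a)
  sw <- params$seed_window
  if (la < sw[2] || lp < sw[2]) {
    seedmir_abort(
      sprintf("sequence shorter than the seed window end (%d)", sw[2]),
      "seed_window")
  }
  offsets <- seq(1L - lp, la - 1L)
  ov <- pmin(la, lp + offsets) - pmax(1L, 1L + offsets) + 1L
  offsets <- offsets[ov >= params$min_overlap]
  if (!length(offsets)) {
    seedmir_abort("no offset satisfies the minimum overlap", "min_overlap")
  }
  best <- NULL
  for (o in offsets) {
    oc <- overlay_core(p, a, o)
    m <- sum(oc$eq)
    if (is.null(best) || m > best$m ||
        (m == best$m && (abs(o) < abs(best$o) ||
                         (abs(o) == abs(best$o) && o < best$o)))) {
      best <- list(o = o, m = m, eq = oc$eq)
    }
  }
  pattern <- rep("-", la)
  pattern[best$eq] <- a[best$eq]
  r <- best$m / la
  seed_matches <- sum(best$eq[sw[1]:min(sw[2], la)])
  tibble(plant_name = plant_name, animal_name = animal_name,
         offset = best$o, pattern = paste(pattern, collapse = ""),
         matches = best$m, alignment_length = la, r_value = r,
         r_value_rounded = round_half_up(r, 2),
         seed_matches = seed_matches,
         passes = r >= params$r_min & seed_matches >= params$seed_min)
}

#' Score a printed alignment pattern
#'
#' Verification utility over pattern strings as they appear in report
#' tables: matches are the letter characters, the alignment length is the
#' total character count, and the reported r-value is their ratio rounded
#' half-up to 2 decimals (full precision retained alongside).
#'
#' @param pattern character vector of patterns over `A`, `C`, `G`, `U`,
#'   `-`.
#' @return tibble with `pattern`, `matches`, `alignment_length`,
#'   `r_value`, `r_value_rounded`.
#' @export
score_pattern <- function(pattern) {
  bad <- stringi::stri_detect_regex(pattern, "[^ACGU-]")
  if (any(bad)) {
    seedmir_abort(sprintf("malformed pattern '%s'", pattern[which(bad)[1]]),
                  "malformed_pattern")
  }
  m <- stringi::stri_count_regex(pattern, "[ACGU]")
  len <- nchar(pattern)
  r <- ifelse(len > 0, m / len, 0)
  tibble(pattern = pattern, matches = m, alignment_length = len,
         r_value = r, r_value_rounded = round_half_up(r, 2))
}

#' Screen a plant library against an animal library
#'
#' Scores every plant x animal pair and returns the pairs passing both
#' thresholds, sorted by descending r-value then plant name. Pairs whose
#' sequences are shorter than the seed window are skipped with a warning.
#'
#' @param plant_reference,animal_reference reference tibbles
#'   ([load_reference()]).
#' @param params a [compare_params()] list.
#' @return tibble of passing comparison results.
#' @export
compare_libraries <- function(plant_reference, animal_reference,
                              params = compare_params()) {
  if (nrow(plant_reference) == 0 || nrow(animal_reference) == 0) {
    seedmir_abort("both libraries must be non-empty", "config")
  }
  skipped <- 0L
  rows <- vector("list", nrow(plant_reference) * nrow(animal_reference))
  k <- 0L
  for (i in seq_len(nrow(plant_reference))) {
    for (j in seq_len(nrow(animal_reference))) {
      k <- k + 1L
      rows[[k]] <- tryCatch(
        compare_pair(
          plant_reference$sequence[i], animal_reference$sequence[j], params,
          plant_name = paste0(plant_reference$species_code[i], "-",
                              plant_reference$name[i]),
          animal_name = paste0(animal_reference$species_code[j], "-",
                               animal_reference$name[j])),
        seedmir_seed_window = function(e) { skipped <<- skipped + 1L; NULL },
        seedmir_min_overlap = function(e) { skipped <<- skipped + 1L; NULL })
    }
  }
  if (skipped > 0) {
    warn(sprintf("skipped %d pair(s): sequence shorter than the seed window or no admissible offset",
                 skipped))
  }
  res <- bind_rows(rows)
  if (nrow(res) == 0) return(res)
  res |>
    dplyr::filter(.data$passes) |>
    arrange(dplyr::desc(.data$r_value), .data$plant_name)
}
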