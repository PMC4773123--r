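#' Normalize a nucleotide sequence to the internal RNA alphabet
#'
#' Sequences are carried internally as uppercase RNA (`A`, `C`, `G`, `U`,
#' with `N` retained so downstream artifact filters can act on it). DNA
#' input is accepted and `T` is mapped to `U`; case is folded to upper.
#'
#' @param x character vector of sequences.
#' @return character vector of normalized RNA sequences.
#' @examples
#' normalize_sequence("acgt")
#' @export
normalize_sequence <- function(x) {
  if (!is.character(x)) {
    seedmir_abort("sequences must be a character vector", "malformed_sequence")
  }
  if (any(is.na(x)) || any(!nzchar(x))) {
    seedmir_abort("sequences must be non-empty and non-missing",
                  "malformed_sequence")
  }
  up <- chartr("T", "U", toupper(x))
  bad <- stringi::stri_locate_first_regex(up, "[^ACGUN]")[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    seedmir_abort(
      sprintf("malformed sequence '%s': invalid character '%s' at position %d",
              x[i], substr(up[i], bad[i], bad[i]), bad[i]),
      "malformed_sequence")
  }
  up
}

rna_to_dna <- function(x) chartr("U", "T", x)

reverse_complement <- function(x) {
  stringi::stri_reverse(chartr("ACGU", "UGCA", x))
}

#' Derive a miRNA family name from a member name
#'
#' Strips, in order: a 3-4 letter species prefix (`mol-`), a trailing arm
#' suffix (`-5p`/`-3p`), a trailing `.N` sequence-variant suffix, and
#' trailing lowercase member letters after the family number. So
#' `mol-miR159b.1` and `miR159f` both map to family `miR159`, and
#' `mol-miR156f-5p` maps to `miR156`.
#'
#' @param name character vector of miRNA member names.
#' @return character vector of family names.
#' @examples
#' derive_family(c("mol-miR156f-5p", "miR159b.1", "miR1310"))
#' @export
derive_family <- function(name) {
  x <- sub("^[A-Za-z]{3,4}-", "", name)
  x <- sub("-(3p|5p)$", "", x)
  x <- sub("\\.[0-9]+$", "", x)
  sub("([0-9])[a-z]+$", "\\1", x)
}

# Arm encoded in a member name: -5p is the predominantly loaded (mature)
# arm, -3p the passenger (star) arm; unadorned names are unspecified.
arm_from_name <- function(name) {
  dplyr::case_when(
    grepl("-5p$", name) ~ "mature",
    grepl("-3p$", name) ~ "star",
    TRUE ~ "unspecified")
}
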