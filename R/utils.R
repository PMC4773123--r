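seedmir_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = paste0("seedmir_", class), ...)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed report tables in this field
#' conventionally round half up, so 0.675 reports as 0.68.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# Integer apportionment by largest remainder: returns non-negative integers
# summing exactly to `total`, proportional to `w`.
largest_remainder <- function(w, total) {
  stopifnot(all(w >= 0), sum(w) > 0, total >= 0)
  exact <- w / sum(w) * total
  base <- floor(exact)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    extra <- order(-(exact - base), seq_along(w))[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
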