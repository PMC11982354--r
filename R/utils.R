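# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Clamp values to an interval
#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half away from zero to `digits` decimals
#'
#' Base `round()` rounds half to even; printed report percentages use the
#' conventional half-away-from-zero rule so that e.g. 62.15 -> 62.2.
#' @noRd
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of part in total, rounded half-away-from-zero to one decimal
#'
#' @param part,total non-negative counts. A zero `total` yields `NA_real_`
#'   (undefined), never 0.
#' @param digits decimal places (default 1, as printed in summary tables).
#' @return numeric percentage on the 0-100 scale.
#' @examples
#' percent_of(3073, 4941)  # 62.2
#' @export
percent_of <- function(part, total, digits = 1) {
  stopifnot(is.numeric(part), is.numeric(total), part >= 0, total >= 0)
  ifelse(total == 0, NA_real_, round_half_away(100 * part / total, digits))
}

#' Stop unless condition holds, with sprintf-style message
#' @noRd
assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

#' Check a scalar numeric in a closed interval
#' @noRd
is_scalar_in <- function(x, lo, hi) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lo && x <= hi
}
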