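#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used for report formatting
#' (base [round()] rounds half to even). Stored results are always kept at
#' full precision; this is applied only when printing percentages or
#' report-style numbers.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.275, 2) # 0.28, not 0.27
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_prob <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort(sprintf("`%s` must be in [0, 1].", name))
  }
  invisible(x)
}
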