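#' Round half away from zero
#'
#' Rounding rule used for all reported quantities: ties are resolved away from
#' zero (so 0.18315 -> 0.1832 at 4 decimals), matching the convention of the
#' published tables this package reproduces, rather than the IEC 60559
#' round-half-even rule of [base::round()].
#'
#' A small representation-error guard is applied before the tie rule so that
#' decimal values that land exactly on a half (but are stored as the nearest
#' binary double just below it) still round up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places; `NULL` or non-finite returns `x`
#'   unchanged (full precision).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_away(0.18315, 4) # 0.1832
#' round_half_away(-2.52035, 4) # -2.5204
#' @export
round_half_away <- function(x, digits = 4) {
  if (is.null(digits) || !is.finite(digits)) {
    return(x)
  }
  p <- 10^digits
  z <- abs(x) * p
  # guard: lift binary representation dust below a decimal half back onto it
  z <- z + sqrt(.Machine$double.eps) * pmax(1, z)
  sign(x) * floor(z + 0.5) / p
}

# shared stop() wrapper so every error carries a subclass testable with
# expect_error(class = ...)
swot_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "swotahp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# format a number for reports: fixed notation, "." decimal mark regardless of
# locale, no grouping
fmt_num <- function(x, digits = 4) {
  formatC(x, format = "f", digits = digits, decimal.mark = ".", big.mark = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
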