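#' The Saaty fundamental scale
#'
#' The 17 admissible pairwise-judgment values of the analytic hierarchy
#' process: the integers 1..9 ("equal" through "extreme" importance) and their
#' reciprocals.
#'
#' @return sorted numeric vector of length 17.
#' @examples
#' saaty_scale()
#' @export
saaty_scale <- function() {
  sort(unique(c(1 / (9:1), 1:9)))
}

#' Parse a single pairwise judgment
#'
#' Accepts the notation used on AHP questionnaires: an integer 1..9, a
#' reciprocal fraction such as `"1/3"`, or (for generality) any positive
#' decimal. Fractions are parsed exactly, so `"1/3"` gives the full-precision
#' value rather than a truncated decimal.
#'
#' @param text character or numeric vector of judgments.
#' @param where optional label (e.g. a matrix cell) used in error messages.
#' @return numeric vector of positive judgment values.
#' @examples
#' parse_judgment("1/3")
#' parse_judgment(c("5", "1/7", "2.5"))
#' @export
parse_judgment <- function(text, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(" at ", where)
  if (is.numeric(text)) {
    vals <- as.numeric(text)
  } else {
    txt <- trimws(as.character(text))
    vals <- vapply(txt, function(s) {
      if (is.na(s) || !nzchar(s)) {
        swot_abort(paste0("empty judgment", ctx), "swotahp_input_error")
      }
      if (grepl("/", s, fixed = TRUE)) {
        parts <- strsplit(s, "/", fixed = TRUE)[[1]]
        if (length(parts) != 2L) {
          swot_abort(
            paste0("unparseable judgment '", s, "'", ctx),
            "swotahp_input_error"
          )
        }
        num <- suppressWarnings(as.numeric(parts[1]))
        den <- suppressWarnings(as.numeric(parts[2]))
        if (is.na(num) || is.na(den)) {
          swot_abort(
            paste0("unparseable judgment '", s, "'", ctx),
            "swotahp_input_error"
          )
        }
        if (den == 0) {
          swot_abort(
            paste0("zero denominator in judgment '", s, "'", ctx),
            "swotahp_input_error"
          )
        }
        num / den
      } else {
        v <- suppressWarnings(as.numeric(s))
        if (is.na(v)) {
          swot_abort(
            paste0("unparseable judgment '", s, "'", ctx),
            "swotahp_input_error"
          )
        }
        v
      }
    }, numeric(1), USE.NAMES = FALSE)
  }
  bad <- which(!is.finite(vals) | vals <= 0)
  if (length(bad)) {
    swot_abort(
      paste0(
        "judgment must be strictly positive; got '",
        as.character(text)[bad[1]], "'", ctx
      ),
      "swotahp_input_error"
    )
  }
  vals
}

#' Test membership of the Saaty scale
#'
#' @param x numeric vector.
#' @param tol relative tolerance for matching a scale value.
#' @return logical vector: is each value one of the 17 scale values?
#' @export
is_saaty_value <- function(x, tol = 1e-6) {
  scale <- saaty_scale()
  vapply(x, function(v) any(abs(v - scale) <= tol * scale), logical(1))
}
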