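#' Signed intensity of a SWOT factor
#'
#' A factor's intensity is its estimated strength (actual level on a 0-5
#' scale) multiplied by its within-group AHP weight, with the sign given by
#' group membership: strengths (S) and opportunities (O) count positive,
#' weaknesses (W) and threats (T) negative.
#'
#' @param weight within-group AHP weight(s) in \[0, 1\].
#' @param strength estimated strength magnitude(s) in \[0, 5\]. For W/T
#'   groups, values supplied already negative are accepted as magnitudes with
#'   a warning.
#' @param group group code(s): `"S"`, `"W"`, `"O"`, or `"T"` (recycled).
#' @return signed numeric intensity vector.
#' @examples
#' factor_intensity(0.4915, 5, "S") # 2.4575
#' factor_intensity(0.6301, 4, "W") # -2.5204
#' @export
factor_intensity <- function(weight, strength, group) {
  group <- toupper(as.character(group))
  if (!all(group %in% c("S", "W", "O", "T"))) {
    swot_abort("group must be one of S, W, O, T", "swotahp_domain_error")
  }
  k <- max(length(weight), length(strength), length(group))
  weight <- rep_len(weight, k)
  strength <- rep_len(strength, k)
  group <- rep_len(group, k)
  sgn <- ifelse(group %in% c("S", "O"), 1, -1)

  presigned <- strength < 0 & group %in% c("W", "T")
  if (any(presigned)) {
    warning(
      "negative strengths for W/T factors interpreted as magnitudes; ",
      "the group sign is applied by the package",
      call. = FALSE
    )
    strength[presigned] <- abs(strength[presigned])
  }
  if (any(strength < 0 | strength > 5)) {
    swot_abort("estimated strength must lie in [0, 5]", "swotahp_domain_error")
  }
  if (any(weight < 0 | weight > 1)) {
    swot_abort("weight must lie in [0, 1]", "swotahp_domain_error")
  }
  sgn * strength * weight
}

#' Factor intensities and signed total of one SWOT group
#'
#' @param weights within-group AHP weights; must sum to 1 within
#'   `weight_tol`.
#' @param strengths estimated strength magnitudes in \[0, 5\], same length.
#' @param group group code `"S"`, `"W"`, `"O"`, or `"T"`.
#' @param ids optional factor identifiers (default `S1..Sn` style).
#' @param labels optional factor descriptions.
#' @param weight_tol tolerance on `sum(weights) - 1`; loosen when weights were
#'   rounded for reporting (n rounded weights can miss 1 by up to n/2 units in
#'   the last place).
#' @param digits optional rounding (half away from zero) applied to each
#'   factor intensity before summing, for fixed-precision reproduction of
#'   published tables.
#' @return a `swot_group` object: list with `group`, `factors` (data frame
#'   id / label / weight / strength / intensity) and `total_intensity`.
#' @examples
#' g <- group_total(c(0.2184, 0.1515, 0.6301), c(3, 2, 4), "W",
#'   weight_tol = 1e-3
#' )
#' g$total_intensity # -3.4786
#' @export
group_total <- function(weights, strengths, group, ids = NULL, labels = NULL,
                        weight_tol = 1e-9, digits = NULL) {
  group <- toupper(group[1])
  if (length(weights) < 1L) {
    swot_abort(sprintf("group %s is empty", group), "swotahp_input_error")
  }
  if (length(strengths) != length(weights)) {
    swot_abort(
      sprintf("group %s: %d weights but %d strengths",
              group, length(weights), length(strengths)),
      "swotahp_shape_error"
    )
  }
  if (abs(sum(weights) - 1) > weight_tol) {
    swot_abort(
      sprintf("group %s: weights sum to %.6g, not 1 (tolerance %g)",
              group, sum(weights), weight_tol),
      "swotahp_validation_error"
    )
  }
  ids <- ids %||% paste0(group, seq_along(weights))
  labels <- labels %||% ids
  intensity <- round_half_away(
    factor_intensity(weights, strengths, group),
    digits
  )
  structure(
    list(
      group = group,
      factors = data.frame(
        id = ids, label = labels, weight = weights,
        strength = abs(strengths), intensity = intensity,
        stringsAsFactors = FALSE
      ),
      total_intensity = round_half_away(sum(intensity), digits)
    ),
    class = "swot_group"
  )
}

#' @export
print.swot_group <- function(x, ...) {
  cat(sprintf("SWOT group %s: total intensity %.4f\n", x$group,
              x$total_intensity))
  print(x$factors, row.names = FALSE, ...)
  invisible(x)
}
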