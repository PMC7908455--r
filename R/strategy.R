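#' Build the SWOT strategic quadrilateral
#'
#' The four signed group totals are drawn on four semi-axes — strengths on
#' +x, weaknesses on -x, opportunities on +y, threats on -y — giving a
#' quadrilateral whose shape summarises the strategic position.
#'
#' @param totals named numeric vector with elements `S`, `W`, `O`, `T`:
#'   the signed group totals (`S`, `O` >= 0; `W`, `T` <= 0).
#' @return a `strategic_quadrilateral`: list with `vertices` (4 x 2 matrix,
#'   rows S', W', O', T'), `totals`, and a `degenerate` flag (all totals 0).
#' @examples
#' build_quadrilateral(c(S = 4.2112, W = -3.4786, O = 4.2901, T = -3.3144))
#' @export
build_quadrilateral <- function(totals) {
  totals <- unlist(totals)
  if (!all(c("S", "W", "O", "T") %in% names(totals))) {
    if (length(totals) == 4L && is.null(names(totals))) {
      names(totals) <- c("S", "W", "O", "T")
    } else {
      swot_abort("totals must be named S, W, O, T", "swotahp_input_error")
    }
  }
  totals <- totals[c("S", "W", "O", "T")]
  if (totals[["S"]] < 0 || totals[["O"]] < 0 ||
      totals[["W"]] > 0 || totals[["T"]] > 0) {
    swot_abort(
      "sign convention violated: need S, O >= 0 and W, T <= 0",
      "swotahp_validation_error"
    )
  }
  vertices <- rbind(
    "S'" = c(totals[["S"]], 0),
    "W'" = c(totals[["W"]], 0),
    "O'" = c(0, totals[["O"]]),
    "T'" = c(0, totals[["T"]])
  )
  colnames(vertices) <- c("x", "y")
  structure(
    list(
      vertices = vertices,
      totals = totals,
      degenerate = all(totals == 0)
    ),
    class = "strategic_quadrilateral"
  )
}

#' Centroid of the strategic quadrilateral
#'
#' The centre of gravity of the four vertices:
#' `X = (S + W) / 4`, `Y = (O + T) / 4` (W and T being negative).
#'
#' @param quad a [build_quadrilateral()] result.
#' @param digits optional rounding (half away from zero) of the coordinates.
#' @return named numeric `c(X =, Y =)`.
#' @export
centroid <- function(quad, digits = NULL) {
  stopifnot(inherits(quad, "strategic_quadrilateral"))
  cc <- colMeans(quad$vertices)
  round_half_away(stats::setNames(cc, c("X", "Y")), digits)
}

#' Strategic azimuth angle
#'
#' Direction of the centroid from the positive x-axis, as the two-argument
#' arctangent mapped to degrees in \[0, 360): the full four-quadrant form, so
#' the angle always identifies the strategy quadrant (the single-argument
#' arctan of Y/X cannot separate quadrants I/III or II/IV).
#'
#' @param x,y centroid coordinates (or `x` a length-2 vector).
#' @return angle in degrees in \[0, 360).
#' @examples
#' azimuth(0.1832, 0.2439) # ~53.09
#' @export
azimuth <- function(x, y = NULL) {
  if (is.null(y)) {
    y <- x[[2]]
    x <- x[[1]]
  }
  if (x == 0 && y == 0) {
    swot_abort("azimuth undefined at the origin", "swotahp_domain_error")
  }
  (atan2(y, x) * 180 / pi) %% 360
}

#' Strategic positive and negative intensities
#'
#' `U = |O total| * |S total|` measures the joint pull of the positive side,
#' `V = |T total| * |W total|` of the negative side. Magnitudes are used, so
#' both are non-negative.
#'
#' @inheritParams build_quadrilateral
#' @param digits optional rounding of U and V.
#' @return named numeric `c(U =, V =)`.
#' @export
strategic_intensities <- function(totals, digits = NULL) {
  quad <- if (inherits(totals, "strategic_quadrilateral")) {
    totals
  } else {
    build_quadrilateral(totals)
  }
  t <- quad$totals
  round_half_away(
    c(U = abs(t[["O"]]) * abs(t[["S"]]), V = abs(t[["T"]]) * abs(t[["W"]])),
    digits
  )
}

#' Strategic intensity coefficient
#'
#' `rho = U / (U + V)`, in \[0, 1\]: the share of total strategic intensity
#' carried by the positive (strengths-opportunities) side. Values above 0.5
#' indicate the positive side dominates.
#'
#' @param U,V non-negative strategic intensities (or `U` a length-2 vector).
#' @return scalar in \[0, 1\].
#' @export
intensity_coefficient <- function(U, V = NULL) {
  if (is.null(V)) {
    V <- U[[2]]
    U <- U[[1]]
  }
  if (U < 0 || V < 0) {
    swot_abort("intensities must be non-negative", "swotahp_domain_error")
  }
  if (U + V == 0) {
    swot_abort(
      "intensity coefficient undefined: U + V = 0 (degenerate analysis)",
      "swotahp_degenerate_error"
    )
  }
  U / (U + V)
}

#' Classify the strategy type
#'
#' Maps the centroid quadrant to the conventional SWOT strategy taxonomy —
#' SO (growth: X > 0, Y > 0), WO (turnaround: X < 0, Y > 0), WT (defensive:
#' X < 0, Y < 0), ST (diversification: X > 0, Y < 0) — and splits each into
#' aggressive (rho > 0.5) versus conservative (rho <= 0.5). A centroid on an
#' axis is reported as a boundary case naming both adjacent types.
#'
#' @param centroid numeric `c(X, Y)`.
#' @param rho intensity coefficient from [intensity_coefficient()].
#' @return a `strategy_call`: list with `quadrant_type` (or `"boundary"`),
#'   `adjacent` (the two candidate types for boundary cases), `intensity_class`,
#'   `theta_deg`, `rho`, `note`.
#' @examples
#' classify_strategy(c(0.1832, 0.2439), 0.6104)
#' @export
classify_strategy <- function(centroid, rho) {
  x <- centroid[[1]]
  y <- centroid[[2]]
  if (!is.null(rho) && (rho < 0 || rho > 1)) {
    swot_abort("rho must lie in [0, 1]", "swotahp_domain_error")
  }
  quadrant <- function(x, y) {
    if (x > 0 && y > 0) "SO" else if (x < 0 && y > 0) "WO"
    else if (x < 0 && y < 0) "WT" else "ST"
  }
  note <- NULL
  adjacent <- NULL
  theta <- NA_real_
  if (x == 0 && y == 0) {
    type <- "boundary"
    adjacent <- c("SO", "WO", "WT", "ST")
    note <- "centroid at the origin: no strategic direction is defined"
  } else {
    theta <- azimuth(x, y)
    if (x == 0 || y == 0) {
      type <- "boundary"
      adjacent <- switch(
        paste(sign(x), sign(y)),
        "0 1" = c("SO", "WO"), "0 -1" = c("WT", "ST"),
        "1 0" = c("ST", "SO"), "-1 0" = c("WO", "WT")
      )
      note <- sprintf("centroid on an axis: between %s and %s",
                      adjacent[1], adjacent[2])
    } else {
      type <- quadrant(x, y)
    }
  }
  structure(
    list(
      quadrant_type = type,
      adjacent = adjacent,
      intensity_class = if (is.null(rho) || is.na(rho)) {
        NA_character_
      } else if (rho > 0.5) "aggressive" else "conservative",
      theta_deg = theta,
      rho = rho,
      note = note
    ),
    class = "strategy_call"
  )
}

#' @export
print.strategy_call <- function(x, ...) {
  if (x$quadrant_type == "boundary") {
    cat("Strategy call: boundary (", paste(x$adjacent, collapse = "/"),
        ")\n", sep = "")
  } else {
    cat(sprintf("Strategy call: %s, %s (theta = %.2f deg, rho = %.4f)\n",
                x$quadrant_type, x$intensity_class, x$theta_deg, x$rho))
  }
  if (!is.null(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

#' Full strategic vector from group totals
#'
#' Computes, in order: the quadrilateral, its centroid, the azimuth theta,
#' the intensities U and V, and the coefficient rho. With `digits` set, each
#' stage consumes the previous stage's rounded value (centroid rounded before
#' theta; U, V rounded before rho), reproducing fixed-precision published
#' chains; theta is reported to 2 decimals, everything else to `digits`.
#'
#' @inheritParams build_quadrilateral
#' @param digits optional stage-rounding precision (`NULL` = full precision).
#' @return a `strategic_vector`: list with `totals`, `centroid`, `theta_deg`,
#'   `U`, `V`, `rho`, `call` (a [classify_strategy()] result), `digits`.
#' @examples
#' strategic_vector(c(S = 4.2112, W = -3.4786, O = 4.2901, T = -3.3144),
#'   digits = 4
#' )
#' @export
strategic_vector <- function(totals, digits = NULL) {
  quad <- build_quadrilateral(totals)
  cc <- centroid(quad, digits = digits)
  uv <- strategic_intensities(quad, digits = digits)
  rho <- round_half_away(intensity_coefficient(uv), digits)
  theta <- round_half_away(
    azimuth(cc),
    if (is.null(digits)) NULL else 2
  )
  call <- classify_strategy(cc, rho)
  structure(
    list(
      totals = quad$totals, quadrilateral = quad, centroid = cc,
      theta_deg = theta, U = uv[["U"]], V = uv[["V"]], rho = rho,
      call = call, digits = digits
    ),
    class = "strategic_vector"
  )
}

#' @export
print.strategic_vector <- function(x, ...) {
  cat(sprintf(
    paste0("Strategic vector: centroid (%.4f, %.4f), theta = %.2f deg, ",
           "U = %.4f, V = %.4f, rho = %.4f\n"),
    x$centroid[["X"]], x$centroid[["Y"]], x$theta_deg, x$U, x$V, x$rho
  ))
  print(x$call)
  invisible(x)
}
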