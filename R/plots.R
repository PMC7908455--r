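#' Plot the SWOT strategic quadrilateral
#'
#' Draws the four semi-axes, the quadrilateral through the vertices S', O',
#' W', T' (each annotated with its coordinates to 4 decimals), and the
#' centroid. Base graphics; styling is fixed so output is deterministic.
#'
#' @param analysis a `swot_analysis` (or a `strategic_vector`).
#' @return invisibly, the character vector of vertex/centroid annotations
#'   drawn on the plot.
#' @export
plot_quadrilateral <- function(analysis) {
  vec <- if (inherits(analysis, "swot_analysis")) analysis$vector else analysis
  stopifnot(inherits(vec, "strategic_vector"))
  v <- vec$quadrilateral$vertices
  cc <- vec$centroid
  lim <- max(abs(v)) * 1.25
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 xlab = "Internal axis (W  <->  S)",
                 ylab = "External axis (T  <->  O)",
                 main = "SWOT strategic quadrilateral")
  graphics::abline(h = 0, v = 0, col = "grey60")
  ord <- c("S'", "O'", "W'", "T'")
  graphics::polygon(v[ord, 1], v[ord, 2], border = "steelblue4",
                    col = grDevices::adjustcolor("steelblue1", 0.3), lwd = 2)
  ann <- sprintf("%s (%s, %s)", rownames(v), fmt_num(v[, 1]), fmt_num(v[, 2]))
  pos <- c(4, 2, 3, 1)[match(rownames(v), c("S'", "W'", "O'", "T'"))]
  graphics::points(v[, 1], v[, 2], pch = 19, col = "steelblue4")
  graphics::text(v[, 1], v[, 2], ann, pos = pos, cex = 0.8)
  cann <- sprintf("P (%s, %s)", fmt_num(cc[["X"]]), fmt_num(cc[["Y"]]))
  graphics::points(cc[["X"]], cc[["Y"]], pch = 17, col = "firebrick")
  graphics::text(cc[["X"]], cc[["Y"]], cann, pos = 4, cex = 0.8,
                 col = "firebrick")
  invisible(c(ann, cann))
}

#' Plot the polar strategy spectrum
#'
#' Unit circle divided into the four strategy quadrants (SO, WO, WT, ST),
#' with the strategic vector drawn at azimuth theta with length rho and an
#' annotation giving (theta, rho). rho = 1 corresponds to the circle's rim.
#'
#' @inheritParams plot_quadrilateral
#' @return invisibly, the annotation string drawn on the plot.
#' @export
plot_strategy_spectrum <- function(analysis) {
  vec <- if (inherits(analysis, "swot_analysis")) analysis$vector else analysis
  stopifnot(inherits(vec, "strategic_vector"))
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Strategy type and intensity spectrum")
  ang <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(cos(ang), sin(ang), col = "grey40")
  for (r in c(0.25, 0.5, 0.75)) {
    graphics::lines(r * cos(ang), r * sin(ang), col = "grey85", lty = 3)
  }
  graphics::segments(c(-1, 0), c(0, -1), c(1, 0), c(0, 1), col = "grey60")
  lab_ang <- c(45, 135, 225, 315) * pi / 180
  graphics::text(1.15 * cos(lab_ang), 1.15 * sin(lab_ang),
                 c("SO", "WO", "WT", "ST"), font = 2)
  th <- vec$theta_deg * pi / 180
  graphics::arrows(0, 0, vec$rho * cos(th), vec$rho * sin(th),
                   length = 0.1, lwd = 2, col = "firebrick")
  ann <- sprintf("(theta = %s deg, rho = %s)",
                 fmt_num(vec$theta_deg, 2), fmt_num(vec$rho))
  graphics::text(vec$rho * cos(th), vec$rho * sin(th), ann, pos = 3,
                 cex = 0.8, col = "firebrick")
  invisible(ann)
}

#' Render the analysis plots to files
#'
#' Writes the strategic-quadrilateral and the polar strategy-spectrum figures
#' into `out_dir` as `strategic_quadrilateral.<fmt>` and
#' `strategy_spectrum.<fmt>`. Runs on a file device, so no display is ever
#' required. A degenerate analysis (all totals zero) is refused.
#'
#' @param analysis a `swot_analysis`.
#' @param out_dir output directory (created if missing).
#' @param format `"svg"` or `"png"`.
#' @return named character vector of the two file paths (invisibly), with the
#'   drawn annotation strings attached as the `"annotations"` attribute.
#' @export
render_plots <- function(analysis, out_dir, format = c("svg", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(analysis, "swot_analysis"))
  if (analysis$vector$quadrilateral$degenerate) {
    swot_abort("cannot plot a degenerate (all-zero) quadrilateral",
               "swotahp_degenerate_error")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      swot_abort(paste0("cannot create output directory: ", out_dir),
                 "swotahp_io_error")
    }
  }
  open_dev <- function(file) {
    if (format == "svg") {
      grDevices::svg(file, width = 7, height = 7)
    } else {
      grDevices::png(file, width = 700, height = 700)
    }
  }
  files <- c(
    quadrilateral = file.path(out_dir,
                              paste0("strategic_quadrilateral.", format)),
    spectrum = file.path(out_dir, paste0("strategy_spectrum.", format))
  )
  open_dev(files[["quadrilateral"]])
  ann1 <- plot_quadrilateral(analysis)
  grDevices::dev.off()
  open_dev(files[["spectrum"]])
  ann2 <- plot_strategy_spectrum(analysis)
  grDevices::dev.off()
  attr(files, "annotations") <- c(ann1, ann2)
  invisible(files)
}
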