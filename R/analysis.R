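#' Run the full SWOT-AHP analysis
#'
#' End-to-end pipeline over a validated configuration: per-group AHP weights
#' by the product-square-root method with the lambda-max/CI/CR consistency
#' check, signed factor intensities (weight x estimated strength), group
#' totals, and the strategic vector (quadrilateral centroid, azimuth theta,
#' intensities U/V, coefficient rho) with the SO/WO/WT/ST strategy call.
#'
#' With `digits` set (the default, 4), every stage consumes the previous
#' stage's values rounded half away from zero to that many decimals — the
#' fixed-precision arithmetic of a desk calculation, which is what published
#' AHP tables contain. `digits = NULL` runs the whole chain in full double
#' precision; results then differ from fixed-precision tables in the last
#' decimal.
#'
#' @param config a `swot_config` from [load_config()], [swot_config()] or
#'   [generate_swot_config()].
#' @param digits stage-rounding precision (default from the config options,
#'   normally 4); `NULL` for full precision.
#' @param cr_gate `"error"` (default) to fail when any group's CR >= 0.1,
#'   `"warn"` to proceed with a warning.
#' @return a `swot_analysis`: list with `metadata`, `groups` (per group:
#'   `weights` \[ahp_weights\], `consistency` \[consistency_report\],
#'   `factors` data frame with intensities, `total_intensity`), `totals`,
#'   `vector` (a [strategic_vector()]), `strategy` (a [classify_strategy()]
#'   call), `digits`.
#' @examples
#' res <- run_full_analysis(load_config(home_exercise_path()))
#' res$totals
#' res$strategy$quadrant_type
#' @export
run_full_analysis <- function(config,
                              digits = config$options$digits,
                              cr_gate = config$options$cr_gate) {
  stopifnot(inherits(config, "swot_config"))
  cr_gate <- match.arg(cr_gate, c("error", "warn"))
  groups <- list()
  totals <- c(S = 0, W = 0, O = 0, T = 0)
  for (g in c("S", "W", "O", "T")) {
    block <- config$groups[[g]]
    A <- block$matrix
    w <- geometric_mean_weights(A, digits = digits)
    rep <- consistency_check(A, digits = digits)
    if (!rep$passes) {
      msg <- sprintf(
        "group %s fails the consistency check: CR = %.4f >= 0.1", g, rep$cr
      )
      if (cr_gate == "error") {
        swot_abort(msg, "swotahp_consistency_error")
      }
      warning(msg, call. = FALSE)
    }
    wr <- round_half_away(w$weights, digits)
    # rounded weights may miss 1 by up to n/2 units in the last place
    wtol <- if (is.null(digits)) 1e-9 else rep$n * 10^(-digits)
    gt <- group_total(
      wr, block$factors$strength, g,
      ids = block$factors$id, labels = block$factors$label,
      weight_tol = wtol, digits = digits
    )
    totals[[g]] <- gt$total_intensity
    groups[[g]] <- list(
      weights = w,
      consistency = rep,
      factors = gt$factors,
      total_intensity = gt$total_intensity
    )
  }
  vec <- strategic_vector(totals, digits = digits)
  structure(
    list(
      metadata = config$metadata,
      groups = groups,
      totals = totals,
      vector = vec,
      strategy = vec$call,
      digits = digits
    ),
    class = "swot_analysis"
  )
}

#' @export
print.swot_analysis <- function(x, ...) {
  cat("SWOT-AHP analysis:", x$metadata$title, "\n\n")
  for (g in c("S", "W", "O", "T")) {
    blk <- x$groups[[g]]
    rep <- blk$consistency
    cat(sprintf(
      "Group %s  (lambda_max %.4f, CI %.4f, CR %.4f, %s)\n",
      g, rep$lambda_max, rep$ci, rep$cr,
      if (rep$passes) "consistent" else "INCONSISTENT"
    ))
    fac <- blk$factors
    for (i in seq_len(nrow(fac))) {
      cat(sprintf("  %-4s weight %.4f  strength %g  intensity %8.4f\n",
                  fac$id[i], fac$weight[i], fac$strength[i], fac$intensity[i]))
    }
    cat(sprintf("  total intensity %.4f\n", blk$total_intensity))
  }
  cat(sprintf(
    "\nTotals: S %.4f, W %.4f, O %.4f, T %.4f\n",
    x$totals[["S"]], x$totals[["W"]], x$totals[["O"]], x$totals[["T"]]
  ))
  print(x$vector)
  invisible(x)
}
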