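#' Random consistency index table
#'
#' Expected consistency index of random reciprocal matrices of order 1..10,
#' used to normalise CI into the consistency ratio CR = CI / RI.
#'
#' @return named numeric vector, names `"1"`..`"10"`.
#' @export
saaty_ri <- function() {
  stats::setNames(
    c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49),
    as.character(1:10)
  )
}

#' Priority weights by the product-square-root (geometric mean) method
#'
#' Each row's geometric mean \eqn{\bar W_i = (\prod_j a_{ij})^{1/n}} is
#' normalised to sum 1, giving the priority weight vector. For a perfectly
#' consistent matrix (\eqn{a_{ij} = w_i / w_j}) this recovers w exactly, and
#' for order 3 it coincides with the principal-eigenvector weights.
#'
#' @param A a [comparison_matrix()] (a plain numeric reciprocal matrix is
#'   validated on the fly).
#' @param digits optional decimal precision at which the row geometric means
#'   are rounded (half away from zero) before normalisation. This emulates a
#'   fixed-precision desk calculation and is what published AHP tables
#'   typically contain; `NULL` (default) keeps full double precision.
#' @return an `ahp_weights` object: list with `geometric_means`, `weights`
#'   (normalised, summing to 1), `labels`, `digits`.
#' @examples
#' A <- comparison_matrix(rbind(c(1, 2, 1 / 4), c(1 / 2, 1, 1 / 3), c(4, 3, 1)))
#' geometric_mean_weights(A)$weights
#' @export
geometric_mean_weights <- function(A, digits = NULL) {
  A <- ensure_comparison_matrix(A)
  n <- nrow(A)
  # log-space product for numerical robustness at larger orders
  gm <- exp(rowMeans(log(unclass(A))))
  gm <- round_half_away(gm, digits)
  w <- gm / sum(gm)
  structure(
    list(
      geometric_means = stats::setNames(gm, rownames(A)),
      weights = stats::setNames(w, rownames(A)),
      labels = rownames(A),
      digits = digits
    ),
    class = "ahp_weights"
  )
}

#' @export
print.ahp_weights <- function(x, ...) {
  cat("AHP priority weights (product-square-root method)\n")
  print(round(x$weights, 4), ...)
  invisible(x)
}

#' Estimate the maximum eigenvalue of a comparison matrix
#'
#' The row-wise estimator
#' \eqn{\lambda_{max} = \frac{1}{n}\sum_i \frac{(A w)_i}{w_i}} evaluated at
#' the geometric-mean weights. For a consistent matrix it equals n exactly;
#' for any positive reciprocal matrix it is at least n.
#'
#' @inheritParams geometric_mean_weights
#' @param weights optional weight vector (or `ahp_weights` object) to evaluate
#'   at; defaults to [geometric_mean_weights()] of `A`.
#' @return the scalar eigenvalue estimate.
#' @export
estimate_lambda_max <- function(A, weights = NULL) {
  A <- ensure_comparison_matrix(A)
  if (is.null(weights)) weights <- geometric_mean_weights(A)
  w <- if (inherits(weights, "ahp_weights")) weights$weights else as.numeric(weights)
  if (length(w) != nrow(A)) {
    swot_abort("weight vector length does not match matrix order",
               "swotahp_shape_error")
  }
  if (any(w <= 0)) {
    swot_abort("weights must be strictly positive", "swotahp_domain_error")
  }
  mean((unclass(A) %*% w) / w)
}

#' Consistency check of a comparison matrix
#'
#' Computes the consistency index \eqn{CI = (\lambda_{max} - n)/(n - 1)} and
#' the consistency ratio \eqn{CR = CI / RI}, with RI from [saaty_ri()]. The
#' conventional acceptability threshold is CR < 0.1. For n <= 2 a reciprocal
#' matrix is always consistent (RI = 0), so CR is defined as 0 and passes.
#'
#' @inheritParams geometric_mean_weights
#' @param digits optional decimal precision propagated through the chain:
#'   weights from `digits`-rounded geometric means, \eqn{\lambda_{max}}
#'   rounded before CI, CR rounded for the report. `NULL` keeps full
#'   precision.
#' @param ri_table optional replacement/extension of the RI lookup (named
#'   numeric vector indexed by order as in [saaty_ri()]); required for n > 10.
#' @return a `consistency_report`: list with `n`, `lambda_max`, `ci`, `ri`,
#'   `cr`, `passes`.
#' @examples
#' A <- comparison_matrix(rbind(c(1, 2, 1 / 4), c(1 / 2, 1, 1 / 3), c(4, 3, 1)))
#' consistency_check(A, digits = 4)
#' @export
consistency_check <- function(A, digits = NULL, ri_table = saaty_ri()) {
  A <- ensure_comparison_matrix(A)
  n <- nrow(A)
  w <- geometric_mean_weights(A, digits = digits)
  lambda_max <- round_half_away(estimate_lambda_max(A, w), digits)
  if (n <= 2) {
    rep <- list(n = n, lambda_max = lambda_max, ci = 0, ri = 0, cr = 0,
                passes = TRUE)
    return(structure(rep, class = "consistency_report"))
  }
  key <- as.character(n)
  if (!key %in% names(ri_table)) {
    swot_abort(
      sprintf("no random index for order %d; supply ri_table to extend", n),
      "swotahp_unsupported_order_error"
    )
  }
  ri <- unname(ri_table[key])
  ci <- (lambda_max - n) / (n - 1)
  cr <- round_half_away(ci / ri, digits)
  structure(
    list(n = n, lambda_max = lambda_max, ci = ci, ri = ri, cr = cr,
         passes = cr < 0.1),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "Consistency: lambda_max = %.4f, CI = %.4f, RI = %.2f, CR = %.4f -> %s\n",
    x$lambda_max, x$ci, x$ri, x$cr,
    if (x$passes) "pass (CR < 0.1)" else "FAIL (CR >= 0.1)"
  ))
  invisible(x)
}

#' Aggregate expert judgment matrices
#'
#' Combines several experts' comparison matrices over the same factors into a
#' consensus matrix by the element-wise geometric mean (aggregation of
#' individual judgments, AIJ). The result is reciprocal by construction.
#'
#' @param matrices list of [comparison_matrix()] objects with identical order
#'   and labels.
#' @return the aggregated [comparison_matrix()].
#' @export
aggregate_judgments <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1L) {
    swot_abort("need at least one matrix to aggregate", "swotahp_input_error")
  }
  matrices <- lapply(matrices, ensure_comparison_matrix)
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(dim(m), dim(ref)) ||
        !identical(rownames(m), rownames(ref))) {
      swot_abort("matrices differ in order or labels", "swotahp_shape_error")
    }
  }
  logs <- lapply(matrices, function(m) log(unclass(m)))
  agg <- exp(Reduce(`+`, logs) / length(logs))
  comparison_matrix(agg, labels = rownames(ref), check_saaty = "none")
}

# accept either a validated comparison_matrix or a raw matrix (validated with
# the Saaty check silenced, since callers pass arbitrary positive reciprocal
# matrices)
ensure_comparison_matrix <- function(A) {
  if (inherits(A, "comparison_matrix")) return(A)
  comparison_matrix(A, check_saaty = "none")
}
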