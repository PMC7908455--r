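#' Specification of a synthetic expert panel
#'
#' Parameters for simulating AHP questionnaire responses: each expert's
#' judgment matrix is the consistent ratio matrix of `true_weights` with
#' independent multiplicative log-normal noise on the upper triangle (the
#' standard elicitation-error model for reciprocal matrices: sign-safe and
#' reciprocal by construction), optionally snapped to the Saaty scale.
#'
#' @param true_weights strictly positive weight vector (normalised to sum 1).
#' @param n_experts number of simulated experts (>= 1).
#' @param sigma standard deviation of the noise on the log judgment
#'   (`sigma = 0` with `quantize = FALSE` gives perfectly consistent
#'   matrices).
#' @param quantize snap entries to the nearest Saaty value in log space?
#' @param seed master seed; per-expert sub-seeds are derived from it
#'   deterministically.
#' @return a `synthetic_panel_spec` list.
#' @export
synthetic_panel_spec <- function(true_weights, n_experts = 10, sigma = 0.2,
                                 quantize = FALSE, seed = NULL) {
  true_weights <- as.numeric(true_weights)
  if (any(!is.finite(true_weights)) || any(true_weights <= 0)) {
    swot_abort("true_weights must be strictly positive",
               "swotahp_domain_error")
  }
  if (sigma < 0) {
    swot_abort("sigma must be non-negative", "swotahp_domain_error")
  }
  if (n_experts < 1) {
    swot_abort("n_experts must be >= 1", "swotahp_domain_error")
  }
  structure(
    list(
      true_weights = true_weights / sum(true_weights),
      n_experts = as.integer(n_experts),
      sigma = sigma,
      quantize = isTRUE(quantize),
      seed = seed
    ),
    class = "synthetic_panel_spec"
  )
}

#' Consistent comparison matrix from a weight vector
#'
#' Builds the idealised ratio matrix `a_ij = w_i / w_j`, which is exactly
#' reciprocal and consistent: its geometric-mean weights recover `w` and its
#' CI and CR are zero.
#'
#' @param true_weights strictly positive weights (normalised internally).
#' @param labels optional factor labels.
#' @return a [comparison_matrix()].
#' @examples
#' make_consistent_matrix(c(0.5, 0.3, 0.2))
#' @export
make_consistent_matrix <- function(true_weights, labels = NULL) {
  w <- as.numeric(true_weights)
  if (any(!is.finite(w)) || any(w <= 0)) {
    swot_abort("true_weights must be strictly positive",
               "swotahp_domain_error")
  }
  A <- outer(w, w, `/`)
  comparison_matrix(A, labels = labels, check_saaty = "none")
}

# nearest Saaty value in log space; ties broken toward 1 (the "equal
# importance" end)
snap_to_saaty <- function(x) {
  scale <- saaty_scale()
  ls <- log(scale)
  vapply(x, function(v) {
    d <- abs(log(v) - ls)
    cand <- which(d <= min(d) + 1e-12)
    if (length(cand) > 1L) cand <- cand[which.min(abs(ls[cand]))]
    scale[cand]
  }, numeric(1))
}

#' Perturb a comparison matrix with multiplicative judgment noise
#'
#' Each upper-triangle entry is multiplied by `exp(e)` with
#' `e ~ N(0, sigma^2)` drawn independently; the lower triangle is reset to
#' the reciprocals and the diagonal stays 1, so the result is always a valid
#' reciprocal matrix. With `quantize = TRUE` the noisy entries are snapped to
#' the nearest Saaty value in log space (ties toward 1). `sigma = 0` without
#' quantization returns the input unchanged.
#'
#' @param A a [comparison_matrix()].
#' @param sigma non-negative noise scale on the log judgment.
#' @param seed optional seed for reproducibility.
#' @param quantize snap to the Saaty scale?
#' @return a perturbed [comparison_matrix()].
#' @export
perturb_matrix <- function(A, sigma, seed = NULL, quantize = FALSE) {
  A <- ensure_comparison_matrix(A)
  if (sigma < 0) {
    swot_abort("sigma must be non-negative", "swotahp_domain_error")
  }
  if (sigma == 0 && !quantize) {
    return(A)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(A)
  up <- upper.tri(m)
  vals <- m[up]
  if (sigma > 0) {
    vals <- vals * exp(stats::rnorm(length(vals), 0, sigma))
  }
  if (quantize) {
    vals <- snap_to_saaty(vals)
  }
  m[up] <- vals
  m[lower.tri(m)] <- (1 / t(m))[lower.tri(m)]
  diag(m) <- 1
  comparison_matrix(m, labels = rownames(A), check_saaty = "none")
}

#' Simulate an expert panel of judgment matrices
#'
#' Generates `n_experts` independently perturbed copies of the consistent
#' matrix built from `true_weights` (see [synthetic_panel_spec()] for the
#' noise model). Sub-seeds for each expert are derived deterministically from
#' the master seed, so a seeded panel is fully reproducible.
#'
#' @param spec a [synthetic_panel_spec()], or a weight vector (in which case
#'   the remaining arguments are forwarded to the spec constructor).
#' @param ... forwarded to [synthetic_panel_spec()] when `spec` is a plain
#'   weight vector.
#' @param labels optional factor labels.
#' @return list of [comparison_matrix()] objects, one per expert.
#' @examples
#' panel <- generate_panel(c(0.5, 0.3, 0.2), n_experts = 5, sigma = 0.2, seed = 1)
#' consensus <- aggregate_judgments(panel)
#' @export
generate_panel <- function(spec, ..., labels = NULL) {
  if (!inherits(spec, "synthetic_panel_spec")) {
    spec <- synthetic_panel_spec(spec, ...)
  }
  base <- make_consistent_matrix(spec$true_weights, labels = labels)
  if (!is.null(spec$seed)) {
    set.seed(spec$seed)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_experts)
  } else {
    sub_seeds <- rep(list(NULL), spec$n_experts)
  }
  lapply(seq_len(spec$n_experts), function(e) {
    perturb_matrix(base, spec$sigma, seed = sub_seeds[[e]],
                   quantize = spec$quantize)
  })
}

#' Generate a complete synthetic SWOT configuration
#'
#' Builds a full analysis input with no external data: per group, a true
#' weight vector is drawn (independent standard-exponential variates,
#' normalised — a flat Dirichlet), the consistent ratio matrix is perturbed
#' with the panel noise model (aggregated over `n_experts` by element-wise
#' geometric mean when more than one), and integer estimated strengths are
#' drawn uniformly from 0..5.
#'
#' @param group_sizes four integers (factors per group, order S, W, O, T),
#'   each in 1..10 (the RI table caps supported orders).
#' @param sigma judgment noise scale (see [perturb_matrix()]).
#' @param n_experts experts per group; their matrices are aggregated.
#' @param quantize snap judgments to the Saaty scale?
#' @param seed master seed: the whole config is a deterministic function of
#'   it.
#' @return a `swot_config` ready for [run_full_analysis()].
#' @examples
#' cfg <- generate_swot_config(c(4, 3, 3, 3), sigma = 0, seed = 1)
#' run_full_analysis(cfg)$strategy$quadrant_type
#' @export
generate_swot_config <- function(group_sizes = c(4, 3, 3, 3), sigma = 0.2,
                                 n_experts = 1, quantize = FALSE,
                                 seed = NULL) {
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) != 4L || any(group_sizes < 1L)) {
    swot_abort("group_sizes must be four integers >= 1", "swotahp_input_error")
  }
  if (any(group_sizes > 10L)) {
    swot_abort("group sizes above 10 are unsupported (RI table range)",
               "swotahp_unsupported_order_error")
  }
  if (!is.null(seed)) set.seed(seed)
  gnames <- c("S", "W", "O", "T")
  groups <- list()
  for (k in seq_along(gnames)) {
    g <- gnames[k]
    n <- group_sizes[k]
    w <- stats::rexp(n)
    w <- w / sum(w)
    ids <- paste0(g, seq_len(n))
    panel_seed <- if (is.null(seed)) NULL else
      sample.int(.Machine$integer.max - 1L, 1)
    panel <- generate_panel(
      synthetic_panel_spec(w, n_experts = n_experts, sigma = sigma,
                           quantize = quantize, seed = panel_seed),
      labels = ids
    )
    A <- if (length(panel) == 1L) panel[[1]] else aggregate_judgments(panel)
    strengths <- sample(0:5, n, replace = TRUE)
    groups[[g]] <- list(
      factors = data.frame(
        id = ids,
        label = paste0("Synthetic factor ", ids),
        description = "",
        strength = strengths,
        stringsAsFactors = FALSE
      ),
      matrix = A
    )
  }
  swot_config(
    groups,
    metadata = list(
      title = "Synthetic SWOT-AHP configuration",
      analyst = "swotahp::generate_swot_config",
      date = ""
    )
  )
}
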