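# study fixtures built in code: the four expert comparison matrices and the
# 0-5 estimated strengths of the bundled home-based-exercise case study

study_matrices <- function() {
  list(
    S = comparison_matrix(rbind(
      c(1, 2, 4, 5),
      c(1 / 2, 1, 3, 4),
      c(1 / 4, 1 / 3, 1, 2),
      c(1 / 5, 1 / 4, 1 / 2, 1)
    ), labels = paste0("S", 1:4)),
    W = comparison_matrix(rbind(
      c(1, 2, 1 / 4),
      c(1 / 2, 1, 1 / 3),
      c(4, 3, 1)
    ), labels = paste0("W", 1:3)),
    O = comparison_matrix(rbind(
      c(1, 3, 1 / 4),
      c(1 / 3, 1, 1 / 6),
      c(4, 6, 1)
    ), labels = paste0("O", 1:3)),
    T = comparison_matrix(rbind(
      c(1, 1 / 3, 1 / 4),
      c(3, 1, 1 / 2),
      c(4, 2, 1)
    ), labels = paste0("T", 1:3))
  )
}

study_strengths <- function() {
  list(S = c(5, 4, 3, 2), W = c(3, 2, 4), O = c(3, 2, 5), T = c(1, 3, 4))
}

# independent oracle: principal eigenvector weights via a direct eigen solve
eigen_weights <- function(A) {
  e <- eigen(unclass(A))
  k <- which.max(Re(e$values))
  v <- abs(Re(e$vectors[, k]))
  v / sum(v)
}

# independent oracle: exact principal eigenvalue
eigen_lambda_max <- function(A) {
  max(Re(eigen(unclass(A))$values))
}

# random valid reciprocal matrix for property tests
random_reciprocal <- function(n, sigma = 0.5, seed = NULL) {
  w <- stats::rexp(n)
  perturb_matrix(make_consistent_matrix(w), sigma = sigma, seed = seed)
}
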