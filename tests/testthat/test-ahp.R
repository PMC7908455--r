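test_that("parse_judgment handles questionnaire notation and rejects junk", {
  expect_equal(parse_judgment("1/3"), 1 / 3)
  expect_equal(parse_judgment("5"), 5)
  expect_equal(parse_judgment("2.5"), 2.5)
  expect_equal(parse_judgment(c("1/7", "9")), c(1 / 7, 9))
  expect_error(parse_judgment("0"), class = "swotahp_input_error")
  expect_error(parse_judgment("-2"), class = "swotahp_input_error")
  expect_error(parse_judgment("1/0"), class = "swotahp_input_error")
  expect_error(parse_judgment("abc"), class = "swotahp_input_error")
  expect_error(
    parse_judgment("x", where = "cell (2, 3)"),
    "cell \\(2, 3\\)",
    class = "swotahp_input_error"
  )
})

test_that("comparison_matrix validates shape, positivity and reciprocity", {
  W <- study_matrices()$W
  expect_s3_class(W, "comparison_matrix")
  expect_equal(nrow(W), 3)
  expect_equal(diag(unclass(W)), rep(1, 3), ignore_attr = TRUE)

  ones <- comparison_matrix(matrix(1, 3, 3))
  expect_true(all(unclass(ones) == 1))

  expect_error(
    comparison_matrix(rbind(c(1, 2), c(3, 1))),
    class = "swotahp_reciprocity_error"
  )
  expect_error(
    comparison_matrix(matrix(1, 2, 3)),
    class = "swotahp_shape_error"
  )
  expect_error(
    comparison_matrix(matrix(1)),
    class = "swotahp_shape_error"
  )
  expect_error(
    comparison_matrix(rbind(c(1, -2), c(-1 / 2, 1))),
    class = "swotahp_domain_error"
  )
})

test_that("missing mirror cells are filled by reciprocity; fractions parse", {
  m <- matrix(c("1", "3", "1/5",
                NA, "1", "1/2",
                NA, NA, "1"), 3, 3, byrow = TRUE)
  A <- comparison_matrix(m)
  expect_equal(A[2, 1], 1 / 3)
  expect_equal(A[3, 1], 5)
  expect_equal(A[3, 2], 2)
})

test_that("off-scale judgments warn by default and error under strict", {
  m <- rbind(c(1, 3.5), c(1 / 3.5, 1))
  expect_warning(comparison_matrix(m), "Saaty")
  expect_error(
    comparison_matrix(m, check_saaty = "strict"),
    class = "swotahp_domain_error"
  )
  expect_silent(comparison_matrix(m, check_saaty = "none"))
})

test_that("geometric-mean weights reproduce the study table and sum to 1", {
  mats <- study_matrices()
  expect_equal(
    round_half_away(geometric_mean_weights(mats$W, digits = 4)$weights, 4),
    c(W1 = 0.2184, W2 = 0.1515, W3 = 0.6301)
  )
  # full precision agrees at this order's printed precision too
  expect_equal(
    unname(round_half_away(geometric_mean_weights(mats$W)$weights, 4)),
    c(0.2184, 0.1515, 0.6301)
  )
  uni <- geometric_mean_weights(comparison_matrix(matrix(1, 4, 4)))
  expect_equal(unname(uni$weights), rep(0.25, 4))

  for (A in mats) {
    expect_equal(sum(geometric_mean_weights(A)$weights), 1, tolerance = 1e-12)
    expect_true(all(geometric_mean_weights(A)$weights > 0))
  }
})

test_that("weights are recovered exactly from a consistent ratio matrix", {
  w <- c(0.5, 0.3, 0.2)
  A <- comparison_matrix(outer(w, w, `/`), check_saaty = "none")
  expect_equal(unname(geometric_mean_weights(A)$weights), w,
               tolerance = 1e-14)
})

test_that("lambda-max estimator matches the study and the eigen oracle", {
  mats <- study_matrices()
  expect_equal(round_half_away(estimate_lambda_max(mats$W), 4), 3.1078)
  # consistent matrix: exactly n
  w <- c(0.4, 0.35, 0.15, 0.1)
  A <- make_consistent_matrix(w)
  expect_equal(estimate_lambda_max(A), 4, tolerance = 1e-12)
  # order-4 strengths matrix: estimator within 0.01 of the exact principal
  # eigenvalue from a direct solver
  expect_equal(
    estimate_lambda_max(mats$S), eigen_lambda_max(mats$S),
    tolerance = 0.01 / eigen_lambda_max(mats$S)
  )
})

test_that("lambda-max >= n for reciprocal matrices, equality iff consistent", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    A <- random_reciprocal(n, sigma = stats::runif(1, 0.1, 0.8))
    lm <- estimate_lambda_max(A)
    expect_gte(lm, n - 1e-10)
    if (lm < n + 1e-9) {
      # equality implies a_ij = w_i/w_j throughout
      w <- geometric_mean_weights(A)$weights
      expect_equal(unclass(A), outer(w, w, `/`), tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  }
  expect_equal(estimate_lambda_max(make_consistent_matrix(c(2, 1, 1))), 3,
               tolerance = 1e-12)
})

test_that("consistency check reproduces the study diagnostics", {
  mats <- study_matrices()
  repW <- consistency_check(mats$W, digits = 4)
  expect_equal(repW$ci, 0.0539, tolerance = 1e-4)
  expect_equal(repW$cr, 0.0929)
  expect_true(repW$passes)

  repO <- consistency_check(mats$O, digits = 4)
  expect_equal(repO$cr, 0.0462)

  cons <- consistency_check(make_consistent_matrix(c(0.6, 0.3, 0.1)))
  expect_equal(cons$ci, 0, tolerance = 1e-12)
  expect_equal(cons$cr, 0, tolerance = 1e-12)
})

test_that("orders 2 and >10 follow the RI-table rules", {
  A2 <- comparison_matrix(rbind(c(1, 3), c(1 / 3, 1)))
  rep2 <- consistency_check(A2)
  expect_equal(rep2$cr, 0)
  expect_true(rep2$passes)

  set.seed(7)
  A11 <- random_reciprocal(11, sigma = 0.2)
  expect_error(consistency_check(A11),
               class = "swotahp_unsupported_order_error")
  ext <- c(saaty_ri(), "11" = 1.51)
  expect_s3_class(consistency_check(A11, ri_table = ext),
                  "consistency_report")
})

test_that("order-3 geometric-mean weights equal eigenvector weights", {
  mats <- study_matrices()
  for (g in c("W", "O", "T")) {
    expect_equal(
      unname(geometric_mean_weights(mats[[g]])$weights),
      unname(eigen_weights(mats[[g]])),
      tolerance = 1e-6
    )
  }
})

test_that("aggregation is the element-wise geometric mean and stays reciprocal", {
  A <- study_matrices()$W
  expect_equal(unclass(aggregate_judgments(list(A, A, A))), unclass(A),
               tolerance = 1e-12)

  m1 <- comparison_matrix(rbind(c(1, 2), c(1 / 2, 1)))
  m2 <- comparison_matrix(rbind(c(1, 8), c(1 / 8, 1)))
  expect_equal(aggregate_judgments(list(m1, m2))[1, 2], 4)

  m3 <- comparison_matrix(rbind(c(1, 3), c(1 / 3, 1)))
  m4 <- comparison_matrix(rbind(c(1, 1 / 3), c(3, 1)))
  expect_equal(aggregate_judgments(list(m3, m4))[1, 2], 1)

  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    mats <- replicate(3, random_reciprocal(n, 0.4), simplify = FALSE)
    agg <- aggregate_judgments(mats)
    expect_equal(unclass(agg) * t(unclass(agg)), matrix(1, n, n),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }

  bad <- comparison_matrix(rbind(c(1, 2), c(1 / 2, 1)), labels = c("a", "b"))
  expect_error(aggregate_judgments(list(m1, bad)),
               class = "swotahp_shape_error")
  expect_error(
    aggregate_judgments(list(m1, study_matrices()$W)),
    class = "swotahp_shape_error"
  )
})

test_that("permuting factors permutes weights and leaves diagnostics alone", {
  A <- study_matrices()$S
  perm <- c(3, 1, 4, 2)
  Ap <- comparison_matrix(unclass(A)[perm, perm],
                          labels = rownames(A)[perm])
  w <- geometric_mean_weights(A)$weights
  wp <- geometric_mean_weights(Ap)$weights
  expect_equal(unname(wp), unname(w[perm]), tolerance = 1e-12)
  r <- consistency_check(A)
  rp <- consistency_check(Ap)
  expect_equal(rp$lambda_max, r$lambda_max, tolerance = 1e-12)
  expect_equal(rp$ci, r$ci, tolerance = 1e-12)
  expect_equal(rp$cr, r$cr, tolerance = 1e-12)
})
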