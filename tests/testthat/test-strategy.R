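study_totals <- c(S = 4.2112, W = -3.4786, O = 4.2901, T = -3.3144)

test_that("quadrilateral vertices sit on their semi-axes", {
  q <- build_quadrilateral(study_totals)
  expect_equal(q$vertices["S'", ], c(x = 4.2112, y = 0))
  expect_equal(q$vertices["W'", ], c(x = -3.4786, y = 0))
  expect_equal(q$vertices["O'", ], c(x = 0, y = 4.2901))
  expect_equal(q$vertices["T'", ], c(x = 0, y = -3.3144))
  expect_false(q$degenerate)

  q0 <- build_quadrilateral(c(S = 0, W = 0, O = 0, T = 0))
  expect_true(q0$degenerate)

  qb <- build_quadrilateral(c(S = 1, W = -1, O = 1, T = -1))
  expect_equal(unname(colMeans(qb$vertices)), c(0, 0))

  expect_error(
    build_quadrilateral(c(S = -1, W = -1, O = 1, T = -1)),
    class = "swotahp_validation_error"
  )
})

test_that("centroid averages the four vertex coordinates", {
  cc <- centroid(build_quadrilateral(study_totals), digits = 4)
  expect_equal(cc, c(X = 0.1832, Y = 0.2439))
  expect_equal(
    centroid(build_quadrilateral(c(S = 2, W = -2, O = 3, T = -3))),
    c(X = 0, Y = 0)
  )
  expect_equal(
    centroid(build_quadrilateral(c(S = 4, W = 0, O = 0, T = 0))),
    c(X = 1, Y = 0)
  )
})

test_that("azimuth is the four-quadrant angle in [0, 360)", {
  expect_equal(round_half_away(azimuth(0.1832, 0.2439), 2), 53.09)
  expect_equal(azimuth(1, 1), 45)
  expect_equal(azimuth(-1, 1), 135)
  expect_equal(azimuth(-1, -1), 225)
  expect_equal(azimuth(1, -1), 315)
  expect_equal(azimuth(1, 0), 0)
  expect_error(azimuth(0, 0), class = "swotahp_domain_error")
})

test_that("strategic intensities and coefficient match the study", {
  uv <- strategic_intensities(study_totals, digits = 4)
  expect_equal(uv, c(U = 18.0665, V = 11.5295))
  expect_equal(round_half_away(intensity_coefficient(uv), 4), 0.6104)

  expect_equal(
    unname(strategic_intensities(c(S = 2, W = 0, O = 3, T = 0))),
    c(6, 0)
  )
  expect_equal(intensity_coefficient(3, 3), 0.5)
  expect_equal(intensity_coefficient(2, 0), 1)
  expect_error(intensity_coefficient(0, 0),
               class = "swotahp_degenerate_error")
})

test_that("strategy classification covers quadrants and boundaries", {
  so <- classify_strategy(c(0.1832, 0.2439), 0.6104)
  expect_equal(so$quadrant_type, "SO")
  expect_equal(so$intensity_class, "aggressive")

  wt <- classify_strategy(c(-1, -1), 0.2)
  expect_equal(wt$quadrant_type, "WT")
  expect_equal(wt$intensity_class, "conservative")

  b <- classify_strategy(c(0, 1), 0.7)
  expect_equal(b$quadrant_type, "boundary")
  expect_setequal(b$adjacent, c("SO", "WO"))

  origin <- classify_strategy(c(0, 0), 0.5)
  expect_equal(origin$quadrant_type, "boundary")
  expect_match(origin$note, "origin")
})

test_that("theta, rho and the call are invariant to positive scaling", {
  set.seed(5)
  for (rep in 1:15) {
    totals <- c(S = stats::runif(1, 0.1, 5), W = -stats::runif(1, 0.1, 5),
                O = stats::runif(1, 0.1, 5), T = -stats::runif(1, 0.1, 5))
    v1 <- strategic_vector(totals)
    cc <- stats::runif(1, 0.2, 4)
    v2 <- strategic_vector(cc * totals)
    expect_equal(v2$theta_deg, v1$theta_deg, tolerance = 1e-9)
    expect_equal(v2$rho, v1$rho, tolerance = 1e-9)
    expect_equal(v2$call$quadrant_type, v1$call$quadrant_type)
    expect_equal(unname(v2$centroid), cc * unname(v1$centroid),
                 tolerance = 1e-9)
    expect_equal(v2$U, cc^2 * v1$U, tolerance = 1e-9)
    expect_true(v1$rho >= 0 && v1$rho <= 1)
    expect_true(v1$theta_deg >= 0 && v1$theta_deg < 360)
  }
})

test_that("swapping S/W and O/T magnitudes rotates theta 180 and flips rho", {
  set.seed(6)
  for (rep in 1:10) {
    s <- stats::runif(1, 0.1, 5); w <- stats::runif(1, 0.1, 5)
    o <- stats::runif(1, 0.1, 5); t <- stats::runif(1, 0.1, 5)
    if (abs(s - w) < 1e-3 || abs(o - t) < 1e-3) next
    v1 <- strategic_vector(c(S = s, W = -w, O = o, T = -t))
    v2 <- strategic_vector(c(S = w, W = -s, O = t, T = -o))
    expect_equal(v2$theta_deg, (v1$theta_deg + 180) %% 360,
                 tolerance = 1e-9)
    expect_equal(v2$rho, 1 - v1$rho, tolerance = 1e-9)
  }
})

test_that("the full pipeline reproduces the bundled study end to end", {
  res <- run_full_analysis(load_config(home_exercise_path()))
  expect_equal(unname(res$totals), c(4.2112, -3.4786, 4.2901, -3.3144))
  expect_equal(res$vector$centroid, c(X = 0.1832, Y = 0.2439))
  expect_equal(res$vector$theta_deg, 53.09)
  expect_equal(res$vector$rho, 0.6104)
  expect_equal(res$strategy$quadrant_type, "SO")
  expect_equal(res$strategy$intensity_class, "aggressive")
})

test_that("the consistency gate names the failing group and is demotable", {
  cfg <- load_config(home_exercise_path())
  # strongly cyclic judgments: far beyond the CR < 0.1 threshold
  bad <- comparison_matrix(
    rbind(c(1, 9, 1 / 9), c(1 / 9, 1, 9), c(9, 1 / 9, 1)),
    labels = paste0("W", 1:3)
  )
  cfg$groups$W$matrix <- bad
  expect_error(
    run_full_analysis(cfg),
    "group W",
    class = "swotahp_consistency_error"
  )
  expect_warning(
    res <- run_full_analysis(cfg, cr_gate = "warn"),
    "group W"
  )
  expect_s3_class(res, "swot_analysis")
})

test_that("an all-zero-strength config is rejected as degenerate", {
  cfg <- load_config(home_exercise_path())
  for (g in names(cfg$groups)) cfg$groups[[g]]$factors$strength <- 0
  expect_error(run_full_analysis(cfg), class = "swotahp_degenerate_error")
})

test_that("full-precision and published-precision chains agree closely", {
  cfg <- load_config(home_exercise_path())
  full <- run_full_analysis(cfg, digits = NULL)
  pub <- run_full_analysis(cfg, digits = 4)
  expect_equal(unname(full$totals), unname(pub$totals), tolerance = 5e-4)
  expect_equal(full$vector$rho, pub$vector$rho, tolerance = 1e-3)
  expect_equal(full$vector$theta_deg, pub$vector$theta_deg, tolerance = 0.05)
  expect_equal(full$strategy$quadrant_type, pub$strategy$quadrant_type)
})
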