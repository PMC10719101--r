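test_that("the two uncertainty intervals coincide without heterogeneity and nest with it", {
  u <- compute_uis(log(2), var_fixed = 0.01, gamma_hat = 0, sd_gamma = 0)
  expect_equal(u$ui_no_gamma, u$ui_with_gamma)
  expect_equal(u$gamma_star, 0)

  # gamma* = 0.03 on top of var_fixed = 0.01 gives total sd 0.2 at the null
  u2 <- compute_uis(0, var_fixed = 0.01, gamma_hat = 0.03, sd_gamma = 0)
  expect_equal(u2$ui_with_gamma, exp(c(-1, 1) * qnorm(0.975) * 0.2),
               tolerance = 1e-12)

  set.seed(1)
  for (i in 1:25) {
    u3 <- compute_uis(rnorm(1), var_fixed = runif(1, 0.001, 0.1),
                      gamma_hat = runif(1, 0, 0.2), sd_gamma = runif(1, 0, 0.1))
    expect_gte(u3$ui_no_gamma[1], u3$ui_with_gamma[1])
    expect_lte(u3$ui_no_gamma[2], u3$ui_with_gamma[2])
  }
})

test_that("BPRF is the heterogeneity-inclusive fifth quantile nearest the null", {
  # degenerate: no uncertainty at all collapses the BPRF onto the RR
  expect_equal(compute_bprf(log(2), 0, 0), 2)

  # published IPV rows: back-solve sd_total from the printed wide UI
  sd_mdd <- (log(2.83) - log(1.55)) / (2 * qnorm(0.975))
  expect_equal(compute_bprf(log(2.1), sd_mdd^2, 0), 1.63, tolerance = 0.005)
  sd_ab <- (log(3.31) - log(1.25)) / (2 * qnorm(0.975))
  expect_equal(compute_bprf(log(2.03), sd_ab^2, 0), 1.35, tolerance = 0.005)

  # harmful and protective quantiles are symmetric about the point estimate
  b_h <- compute_bprf(log(2), 0.01, 0.02, "harmful")
  b_p <- compute_bprf(log(2), 0.01, 0.02, "protective")
  expect_equal(b_h * b_p, 4, tolerance = 1e-10)

  # conservatism: BPRF below the RR whenever total variance is positive
  expect_lt(compute_bprf(log(2), 0.001, 0), 2)
})

test_that("ROS is signed log(BPRF)/2 and increases with the BPRF", {
  expect_equal(round(compute_ros(1.63), 2), 0.24)
  expect_equal(compute_ros(1.0), 0)
  expect_equal(round(compute_ros(0.40), 2), -0.46)
  expect_equal(compute_ros(1.5, "protective"), -log(1.5) / 2)
  expect_error(compute_ros(0), class = "bop_validation_error")

  b <- seq(0.2, 3, by = 0.1)
  expect_true(all(diff(vapply(b, compute_ros, numeric(1))) > 0))
})

test_that("star ratings follow the published bins with half-open boundaries", {
  expect_equal(star_rating(0.24, TRUE), 3L)
  expect_equal(star_rating(0.14, TRUE), 2L)   # upper edge belongs to the lower bin
  expect_equal(star_rating(0.41, TRUE), 3L)
  expect_equal(star_rating(0.62, TRUE), 4L)
  expect_equal(star_rating(0.63, TRUE), 5L)
  expect_equal(star_rating(0, TRUE), 1L)
  expect_equal(star_rating(-0.42, TRUE), 1L)
  expect_equal(star_rating(NA_real_, FALSE), 0L)
  expect_error(star_rating(0.2, FALSE), "must not be supplied")
  expect_error(star_rating(NA_real_, TRUE), "required")

  ros_grid <- seq(-0.5, 1, by = 0.01)
  stars <- vapply(ros_grid, star_rating, integer(1), significant_no_gamma = TRUE)
  expect_true(all(diff(stars) >= 0))
})

test_that("excess risk reads the BPRF as a lower bound on percent increase", {
  expect_equal(excess_risk_percent(1.63), 63)
  expect_equal(excess_risk_percent(1.0), 0)
  expect_equal(excess_risk_percent(1.45), 45)
  expect_error(excess_risk_percent(-1), class = "bop_validation_error")
})

test_that("evidence_score suppresses BPRF and ROS for non-significant pairs", {
  s <- evidence_score(log(1.32), var_fixed = 0.05, gamma_hat = 0.2,
                      sd_gamma = 0.1, n_studies_val = 3L)
  expect_false(s$significant_no_gamma)
  expect_equal(s$stars, 0L)
  expect_true(is.na(s$bprf) && is.na(s$ros) && is.na(s$excess_risk_pct))
  expect_output(print(s), "N/A")

  s2 <- evidence_score(log(2.1), var_fixed = 0.0038, gamma_hat = 0.01,
                       sd_gamma = 0.005, n_studies_val = 12L, pub_bias = FALSE)
  expect_true(s2$significant_no_gamma)
  expect_equal(s2$stars, 3L)
  expect_lt(s2$bprf, s2$rr)
})
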