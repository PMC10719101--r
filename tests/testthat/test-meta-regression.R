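test_that("equal-weight fixed-effect fit is the arithmetic mean", {
  d <- make_dataset(log_rr = c(0.2, 0.4, 0.9), se = rep(0.15, 3))
  fit <- bop_model(d, trim = 0, fix_gamma = 0)
  expect_equal(unname(coef(fit)[1]), mean(d$log_rr), tolerance = 1e-10)
})

test_that("fixed-effect fit equals the closed-form inverse-variance mean", {
  set.seed(42)
  d <- make_dataset(log_rr = rnorm(10, 0.5, 0.3), se = runif(10, 0.05, 0.4))
  fit <- bop_model(d, trim = 0, fix_gamma = 0)
  expect_equal(unname(coef(fit)[1]), ivw_mean(d$log_rr, d$se_log_rr),
               tolerance = 1e-8)
  expect_equal(unname(vcov(fit)[1, 1]), ivw_var(d$se_log_rr), tolerance = 1e-8)
})

test_that("random-effects fit agrees with an independent ML meta-analysis", {
  skip_if_not_installed("metafor")
  set.seed(11)
  d <- simulate_ro_dataset(ro_truth(beta0 = 0.6, gamma = 0.05,
                                    n_studies = 25, seed = 11))
  fit <- bop_model(d, trim = 0)
  ref <- metafor::rma(yi = d$log_rr, sei = d$se_log_rr, method = "ML")
  expect_equal(unname(coef(fit)[1]), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$gamma, ref$tau2, tolerance = 1e-4)
})

test_that("gamma is invariant to row order and to shifting all effects", {
  set.seed(3)
  d <- simulate_ro_dataset(ro_truth(beta0 = 0.4, gamma = 0.06, n_studies = 20,
                                    obs_per_study = 2, seed = 3))
  fit <- bop_model(d, trim = 0)

  perm <- sample(nrow(d))
  fit_perm <- bop_model(d[perm, ], trim = 0)
  expect_equal(fit_perm$gamma, fit$gamma, tolerance = 1e-7)
  expect_equal(coef(fit_perm), coef(fit), tolerance = 1e-7)

  d_shift <- d
  d_shift$log_rr <- d$log_rr + 1.3
  fit_shift <- bop_model(d_shift, trim = 0)
  expect_equal(unname(coef(fit_shift)[1]), unname(coef(fit)[1]) + 1.3,
               tolerance = 1e-7)
  expect_equal(fit_shift$gamma, fit$gamma, tolerance = 1e-7)
})

test_that("Fisher-information sd of gamma matches the equal-information closed form", {
  # m studies, one observation each, common sigma: per-study marginal
  # variance v = sigma^2 + gamma and sd(gamma_hat) = v * sqrt(2 / m)
  set.seed(5)
  m <- 40
  d <- make_dataset(log_rr = rnorm(m, 0.3, sqrt(0.1^2 + 0.04)),
                    se = rep(0.1, m))
  fit <- bop_model(d, trim = 0)
  v <- 0.1^2 + fit$gamma
  expect_equal(fit$sd_gamma, v * sqrt(2 / m), tolerance = 1e-10)
})

test_that("sd of gamma shrinks as the number of studies grows", {
  mean_sd <- function(m) {
    mean(vapply(1:30, function(i) {
      d <- simulate_ro_dataset(ro_truth(beta0 = 0, gamma = 0.04,
                                        se_range = c(0.1, 0.1),
                                        n_studies = m, seed = 1000 + i))
      bop_model(d, trim = 0)$sd_gamma
    }, numeric(1)))
  }
  expect_gt(mean_sd(10), mean_sd(40))
})

test_that("trimming removes the planted outlier and matches the exhaustive oracle", {
  for (s in 1:5) {
    set.seed(200 + s)
    d <- simulate_ro_dataset(ro_truth(beta0 = 0.5, gamma = 0,
                                      se_range = c(0.05, 0.3),
                                      n_studies = 10, seed = 200 + s))
    planted <- sample(10, 1)
    d$log_rr[planted] <- d$log_rr[planted] + 3
    fit <- bop_model(d, trim = 0.1)
    expect_equal(fit$n_obs - fit$n_retained, 1L)         # ceil(0.1 * 10)
    expect_equal(which(!fit$retained), planted)
    expect_equal(loo_trim_oracle(d), planted)
  }
})

test_that("trimming is inactive below the observation threshold", {
  set.seed(9)
  d <- simulate_ro_dataset(ro_truth(beta0 = 0.5, n_studies = 8, seed = 9))
  fit <- bop_model(d, trim = 0.1, trim_min_obs = 10)
  expect_equal(fit$n_retained, 8L)
  expect_equal(fit$trim, 0)
})

test_that("trimmed fit beats random subsets of the same size", {
  set.seed(77)
  d <- simulate_ro_dataset(ro_truth(beta0 = 0.4, gamma = 0,
                                    se_range = c(0.05, 0.25),
                                    n_studies = 12, seed = 77))
  d$log_rr[4] <- d$log_rr[4] + 2.5
  fit <- bop_model(d, trim = 0.25)          # retains ceiling(0.75 * 12) = 9
  k <- fit$n_retained
  for (i in 1:200) {
    keep <- sort(sample(12, k))
    ll <- bop_model(d[keep, ], trim = 0)$logLik
    expect_lte(ll, fit$logLik + 1e-8)
  }
})

test_that("a strong bias covariate is selected, pure noise rarely is", {
  set.seed(15)
  d <- simulate_ro_dataset(ro_truth(beta0 = 0.3, gamma = 0,
                                    beta_cov = c(cv_bias = 0.5),
                                    cov_prevalence = 0.5,
                                    se_range = c(0.08, 0.12),
                                    n_studies = 30, seed = 15))
  expect_true("cv_bias" %in% select_bias_covariates(d))

  hits <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    dn <- simulate_ro_dataset(ro_truth(beta0 = 0.3, gamma = 0,
                                       beta_cov = c(cv_noise = 0),
                                       cov_prevalence = 0.5,
                                       se_range = c(0.05, 0.3),
                                       n_studies = 30, seed = 5000 + i))
    hits <- hits + ("cv_noise" %in% select_bias_covariates(dn))
  }
  expect_lte(hits / n_rep, 0.10)
})

test_that("covariate selection handles empty and invalid candidate sets", {
  d <- make_dataset(log_rr = rnorm(6), se = rep(0.1, 6))
  expect_identical(select_bias_covariates(d), character(0))

  d2 <- make_dataset(log_rr = rnorm(6), se = rep(0.1, 6),
                     cv_rare = c(1, 0, 0, 0, 0, 0))
  expect_error(select_bias_covariates(d2, candidates = "cv_rare"),
               "not testable", class = "bop_validation_error")
})

test_that("reference prediction removes the covariate-driven shift", {
  x <- rep(c(0, 1), each = 5)
  d <- make_dataset(log_rr = log(2) + 0.3 * x, se = rep(0.1, 10), cv_def = x)
  fit <- bop_model(d, covariates = "cv_def", trim = 0, fix_gamma = 0)
  ref <- predict_reference_risk(fit)
  expect_equal(ref$log_rr, log(2), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(ref$log_rr, mean(d$log_rr), tolerance = 0.05)))

  fit0 <- bop_model(d, trim = 0, fix_gamma = 0)
  ref0 <- predict_reference_risk(fit0)
  expect_equal(ref0$log_rr, unname(coef(fit0)[1]))
  expect_equal(ref0$var, unname(vcov(fit0)[1, 1]))
})

test_that("the three-study gate and degenerate designs raise structured errors", {
  d2 <- make_dataset(log_rr = c(0.1, 0.2, 0.3), se = rep(0.1, 3),
                     study = c("a", "a", "b"))
  expect_error(bop_model(d2), "at least three studies",
               class = "bop_gate_error")

  d <- make_dataset(log_rr = rnorm(6), se = rep(0.1, 6),
                    cv_a = c(0, 0, 1, 1, 1, 0), cv_b = c(0, 0, 1, 1, 1, 0))
  expect_error(bop_model(d, covariates = c("cv_a", "cv_b"), trim = 0),
               "collinear", class = "bop_fit_error")
})

test_that("parameter recovery on synthetic data (coverage and gamma)", {
  covered <- 0L
  gammas <- numeric(20)
  for (s in 1:20) {
    d <- simulate_ro_dataset(ro_truth(beta0 = log(2), gamma = 0.04,
                                      n_studies = 50, seed = s))
    fit <- bop_model(d, trim = 0)
    ci <- coef(fit)[1] + c(-1, 1) * qnorm(0.975) * sqrt(vcov(fit)[1, 1])
    covered <- covered + (ci[1] <= log(2) && log(2) <= ci[2])
    gammas[s] <- fit$gamma
  }
  expect_gte(covered, 17L)
  expect_gte(median(gammas), 0.02)
  expect_lte(median(gammas), 0.06)
})
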