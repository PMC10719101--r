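test_that("raw extraction rows convert to the log scale with CI-derived SEs", {
  path <- write_raw_extraction(data.frame(
    study_id = c("s1", "s2", "s3"),
    estimate = c(2.0, 1.5, 3.0),
    lower = c(1.5, 1.1, 2.0),
    upper = c(2.67, 2.05, 4.5),
    measure = c("RR", "OR", "RR")
  ))
  d <- read_extraction_table(path)
  expect_s3_class(d, "ro_dataset")
  expect_equal(d$log_rr[1], log(2.0), tolerance = 1e-12)
  # reconstructed ratio matches the reported one to machine precision
  expect_equal(exp(d$log_rr), c(2.0, 1.5, 3.0), tolerance = 1e-12)
  expect_equal(d$se_log_rr[1], (log(2.67) - log(1.5)) / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(d$se_log_rr[1], 0.1470, tolerance = 1e-3)
  expect_equal(d$measure_type, c("RR", "OR", "RR"))
})

test_that("malformed extraction tables are rejected with row-level diagnostics", {
  base <- data.frame(study_id = c("a", "b", "c"), estimate = c(2, 1.5, 1.2),
                     lower = c(1.5, 1.2, 1.0), upper = c(2.7, 1.9, 1.5))

  zero_width <- base
  zero_width$lower[2] <- zero_width$upper[2] <- 1.4
  expect_error(read_extraction_table(write_raw_extraction(zero_width)),
               "row\\(s\\): 2", class = "bop_validation_error")

  neg <- base
  neg$estimate[3] <- -0.5
  expect_error(read_extraction_table(write_raw_extraction(neg)),
               "must be > 0.*3", class = "bop_validation_error")

  missing_ci <- base
  missing_ci$upper[1] <- NA
  expect_error(read_extraction_table(write_raw_extraction(missing_ci)),
               "missing estimate or CI", class = "bop_validation_error")

  empty <- tempfile(fileext = ".csv")
  writeLines("study_id,estimate,lower,upper", empty)
  expect_error(read_extraction_table(empty), "empty",
               class = "bop_parse_error")

  expect_error(read_extraction_table(tempfile(fileext = ".csv")),
               "not found", class = "bop_validation_error")
})

test_that("write/read round-trip is the identity on validated datasets", {
  d <- make_dataset(log_rr = c(0.693147180559945, -0.105360515657826, 0.4),
                    se = c(0.147, 0.21, 0.09),
                    study = c("a", "a", "b"),
                    cv_odds = c(0, 1, 0), cv_rep = c(1, 1, 0))
  d <- ro_dataset(rbind(as.data.frame(d),
                        data.frame(study_id = "c", log_rr = 0.1,
                                   se_log_rr = 0.3, n_repeats = 2L,
                                   measure_type = "RR", cv_odds = 1, cv_rep = 0)))
  path <- tempfile(fileext = ".csv")
  write_extraction_table(d, path)
  d2 <- read_extraction_table(path)
  for (col in c("log_rr", "se_log_rr")) {
    expect_equal(d2[[col]], d[[col]], tolerance = 1e-12)
  }
  expect_identical(d2$study_id, d$study_id)
  expect_equal(d2$n_repeats, d$n_repeats)
  expect_equal(d2$cv_odds, d$cv_odds)
})

test_that("repeated-measurement SE adjustment conserves inverse-variance weight", {
  d <- make_dataset(log_rr = c(0.5, 0.4, 0.3, 0.2),
                    se = c(0.1, 0.1, 0.05, 0.2),
                    n_repeats = c(4L, 1L, 2L, 3L))
  adj <- adjust_se_for_repeats(d)
  expect_equal(adj$se_log_rr[1], 0.2)                 # se 0.1, 4 repeats
  expect_equal(adj$se_log_rr[2], 0.1)                 # identity at 1 repeat
  expect_equal(adj$se_log_rr[3], 0.05 * sqrt(2))      # ~0.0707
  # the k adjusted repeats jointly carry the weight of one raw observation
  expect_equal(d$n_repeats / adj$se_log_rr^2, 1 / d$se_log_rr^2)
  expect_equal(adj$n_repeats, d$n_repeats)            # preserved for audit

  lin <- adjust_se_for_repeats(d, method = "linear")
  expect_equal(lin$se_log_rr[1], 0.4)
})

test_that("covariate testability requires two observations per level", {
  d <- make_dataset(log_rr = rnorm(5), se = rep(0.1, 5),
                    cv_ok = c(0, 0, 1, 1, 1),
                    cv_one_zero = c(0, 1, 1, 1, 1),
                    cv_all_zero = c(0, 0, 0, 0, 0))
  tab <- derive_testable_covariates(d)
  expect_equal(setNames(tab$testable, tab$covariate),
               c(cv_ok = TRUE, cv_one_zero = FALSE, cv_all_zero = FALSE))
  expect_error(derive_testable_covariates(d, "cv_missing"),
               "unknown covariate", class = "bop_validation_error")
})

test_that("dataset validation enforces the observation invariants", {
  expect_error(make_dataset(log_rr = c(0.1, Inf, 0.2), se = rep(0.1, 3)),
               "non-finite log_rr", class = "bop_validation_error")
  expect_error(make_dataset(log_rr = rnorm(3), se = c(0.1, 0, 0.2)),
               "se_log_rr", class = "bop_validation_error")
  expect_error(make_dataset(log_rr = rnorm(3), se = rep(0.1, 3),
                            cv_bad = c(0, 2, 1)),
               "0/1", class = "bop_validation_error")
  expect_error(make_dataset(log_rr = rnorm(3), se = rep(0.1, 3),
                            n_repeats = c(1L, 0L, 1L)),
               "positive integer", class = "bop_validation_error")
})
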