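#' Ground-truth parameters for a synthetic evidence table
#'
#' Describes the generative model the analysis pipeline assumes: each study
#' `i` carries a random effect `u_i ~ N(0, gamma)` (`gamma` is a variance on
#' the log-RR scale); each observation `j` within it has a sampling standard
#' error `sigma_ij` drawn uniformly from `se_range`, binary bias covariates
#' drawn Bernoulli(`cov_prevalence`), and
#' `y_ij = beta0 + x' beta_cov + u_i + egger_slope * sigma_ij + e_ij` with
#' `e_ij ~ N(0, sigma_ij^2)`. A fraction `outlier_fraction` of observations
#' is additionally shifted by `outlier_shift` (mean-shift contamination, the
#' kind of gross outlier that likelihood-based trimming is designed to
#' remove). A non-zero `egger_slope` couples effect size to its standard
#' error, the small-study asymmetry that Egger's regression detects.
#'
#' @param beta0 true pooled log relative risk.
#' @param beta_cov named numeric vector of true log-scale bias-covariate
#'   effects; names become `cv_*` columns (a `cv_` prefix is added when
#'   absent).
#' @param gamma true between-study variance, `>= 0`.
#' @param se_range length-2 positive range for sampled observation SEs.
#' @param n_studies number of studies.
#' @param obs_per_study observations per study: a single count or a
#'   length-2 range sampled uniformly per study.
#' @param cov_prevalence Bernoulli prevalence of each covariate's value 1,
#'   recycled across covariates.
#' @param outlier_fraction proportion of observations contaminated, in
#'   `[0, 0.3]`.
#' @param outlier_shift log-scale displacement added to contaminated
#'   observations.
#' @param egger_slope coefficient linking SE to expected effect (0 = no
#'   publication bias).
#' @param seed integer RNG seed; generation is reproducible from it.
#' @return an object of class `ro_truth`.
#' @seealso [simulate_ro_dataset()], [simulate_null_ensemble()]
#' @export
ro_truth <- function(beta0 = 0,
                     beta_cov = numeric(0),
                     gamma = 0,
                     se_range = c(0.05, 0.5),
                     n_studies = 12L,
                     obs_per_study = 1L,
                     cov_prevalence = 0.3,
                     outlier_fraction = 0,
                     outlier_shift = 0,
                     egger_slope = 0,
                     seed = 1L) {
  stopifnot(is.numeric(beta0), length(beta0) == 1L, is.finite(beta0))
  if (gamma < 0) .stop_validation("gamma must be >= 0")
  if (length(se_range) != 2L || se_range[1] <= 0 || se_range[2] < se_range[1]) {
    .stop_validation("se_range must be (low, high) with low > 0")
  }
  if (outlier_fraction < 0 || outlier_fraction > 0.3) {
    .stop_validation("outlier_fraction must lie in [0, 0.3]")
  }
  if (n_studies < 1) .stop_validation("n_studies must be >= 1")
  if (length(beta_cov)) {
    nm <- names(beta_cov)
    if (is.null(nm) || any(nm == "")) .stop_validation("beta_cov must be named")
    names(beta_cov) <- ifelse(grepl("^cv_", nm), nm, paste0("cv_", nm))
  }
  structure(list(beta0 = beta0, beta_cov = beta_cov, gamma = gamma,
                 se_range = se_range, n_studies = as.integer(n_studies),
                 obs_per_study = obs_per_study,
                 cov_prevalence = cov_prevalence,
                 outlier_fraction = outlier_fraction,
                 outlier_shift = outlier_shift,
                 egger_slope = egger_slope,
                 seed = as.integer(seed)),
            class = "ro_truth")
}

#' Simulate a risk-outcome dataset from ground truth
#'
#' Draws an evidence table from the generative model described in
#' [ro_truth()]. The truth object is attached to the result as attribute
#' `"truth"` (with the indices of contaminated observations recorded in its
#' `outlier_idx` field) so downstream recovery tests can compare estimates
#' against the parameters that generated the data.
#'
#' @param truth an [ro_truth()] object.
#' @param risk_name,outcome_name labels for the generated dataset.
#' @return a `ro_dataset` with attribute `"truth"`.
#' @examples
#' d <- simulate_ro_dataset(ro_truth(beta0 = log(2), gamma = 0.04,
#'                                   n_studies = 20, seed = 42))
#' attr(d, "truth")$beta0
#' @export
simulate_ro_dataset <- function(truth, risk_name = "synthetic_risk",
                                outcome_name = "synthetic_outcome") {
  stopifnot(inherits(truth, "ro_truth"))
  set.seed(truth$seed)

  k <- if (length(truth$obs_per_study) == 2L) {
    sample(seq(truth$obs_per_study[1], truth$obs_per_study[2]),
           truth$n_studies, replace = TRUE)
  } else {
    rep.int(as.integer(truth$obs_per_study), truth$n_studies)
  }
  study <- rep(sprintf("S%03d", seq_len(truth$n_studies)), times = k)
  n <- length(study)
  u <- rep(rnorm(truth$n_studies, 0, sqrt(truth$gamma)), times = k)
  sigma <- runif(n, truth$se_range[1], truth$se_range[2])

  p <- length(truth$beta_cov)
  X <- matrix(0, n, p)
  if (p) {
    prev <- rep_len(truth$cov_prevalence, p)
    for (j in seq_len(p)) X[, j] <- rbinom(n, 1L, prev[j])
    colnames(X) <- names(truth$beta_cov)
  }

  y <- truth$beta0 + (if (p) drop(X %*% truth$beta_cov) else 0) + u +
    truth$egger_slope * sigma + rnorm(n, 0, sigma)

  outlier_idx <- integer(0)
  n_out <- round(truth$outlier_fraction * n)
  if (n_out > 0) {
    outlier_idx <- sort(sample.int(n, n_out))
    y[outlier_idx] <- y[outlier_idx] + truth$outlier_shift
  }

  df <- data.frame(study_id = study, log_rr = y, se_log_rr = sigma,
                   n_repeats = 1L, stringsAsFactors = FALSE)
  if (p) for (j in seq_len(p)) df[[colnames(X)[j]]] <- X[, j]
  out <- ro_dataset(df, risk_name = risk_name, outcome_name = outcome_name)
  truth$outlier_idx <- outlier_idx
  attr(out, "truth") <- truth
  out
}

#' Simulate an ensemble of null datasets
#'
#' Generates independent replicate datasets from a template truth with
#' `beta0 = 0`, each with a distinct seed derived deterministically from the
#' template seed. Intended for type-I-error and calibration studies of the
#' downstream estimators.
#'
#' @param truth an [ro_truth()] template with `beta0 = 0`.
#' @param n_replicates number of datasets (0 gives an empty list).
#' @return list of `ro_dataset` objects.
#' @export
simulate_null_ensemble <- function(truth, n_replicates) {
  stopifnot(inherits(truth, "ro_truth"))
  if (truth$beta0 != 0) .stop_validation("null ensemble requires beta0 = 0")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 0) .stop_validation("n_replicates must be >= 0")
  lapply(seq_len(n_replicates), function(i) {
    t_i <- truth
    t_i$seed <- as.integer((truth$seed + 104729 * i) %% 2147483647)
    simulate_ro_dataset(t_i)
  })
}

#' Write / read a ground-truth sidecar file
#'
#' Plain key-value text (one `key = value` per line) recording the
#' parameters of a synthetic dataset, for use next to the table written by
#' [write_extraction_table()].
#'
#' @param truth an `ro_truth` object.
#' @param path file to write or read.
#' @return `write_truth` returns `path` invisibly; `read_truth` returns an
#'   `ro_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ro_truth"))
  fmt <- function(x) paste(format(x, digits = 15), collapse = ",")
  keys <- c("beta0", "gamma", "se_range", "n_studies", "obs_per_study",
            "cov_prevalence", "outlier_fraction", "outlier_shift",
            "egger_slope", "seed")
  lines <- vapply(keys, function(k) paste0(k, " = ", fmt(truth[[k]])), "")
  if (length(truth$beta_cov)) {
    lines <- c(lines, paste0("beta_cov_names = ",
                             paste(names(truth$beta_cov), collapse = ",")),
               paste0("beta_cov_values = ", fmt(unname(truth$beta_cov))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- setNames(lapply(kv, function(x) strsplit(x[2], ",")[[1]]),
                   vapply(kv, `[[`, "", 1))
  num <- function(k, default = NULL) {
    if (is.null(vals[[k]])) default else as.numeric(vals[[k]])
  }
  beta_cov <- numeric(0)
  if (!is.null(vals$beta_cov_names)) {
    beta_cov <- setNames(as.numeric(vals$beta_cov_values), vals$beta_cov_names)
  }
  ro_truth(beta0 = num("beta0"), beta_cov = beta_cov, gamma = num("gamma"),
           se_range = num("se_range"), n_studies = num("n_studies"),
           obs_per_study = num("obs_per_study"),
           cov_prevalence = num("cov_prevalence", 0.3),
           outlier_fraction = num("outlier_fraction", 0),
           outlier_shift = num("outlier_shift", 0),
           egger_slope = num("egger_slope", 0),
           seed = num("seed", 1))
}

#' @export
print.ro_truth <- function(x, ...) {
  cat("Synthetic ground truth\n")
  cat(sprintf("  beta0 = %.4f (RR %.3f), gamma = %.4f\n",
              x$beta0, exp(x$beta0), x$gamma))
  if (length(x$beta_cov)) {
    cat("  covariate effects:",
        paste(sprintf("%s = %.3f", names(x$beta_cov), x$beta_cov),
              collapse = ", "), "\n")
  }
  cat(sprintf("  %d studies, obs/study %s, SE range [%.3g, %.3g], seed %d\n",
              x$n_studies, paste(x$obs_per_study, collapse = "-"),
              x$se_range[1], x$se_range[2], x$seed))
  if (x$outlier_fraction > 0) {
    cat(sprintf("  outliers: %.0f%% shifted by %+.2f\n",
                100 * x$outlier_fraction, x$outlier_shift))
  }
  if (x$egger_slope != 0) {
    cat(sprintf("  publication-bias slope: %.2f\n", x$egger_slope))
  }
  invisible(x)
}
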