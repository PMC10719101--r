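#' Uncertainty intervals with and without between-study heterogeneity
#'
#' The interval without heterogeneity is the usual fixed-effect 95% interval,
#' `exp(log_rr_ref +/- 1.96 sqrt(var_fixed))`. The interval with
#' heterogeneity widens the variance by the 95th quantile of the
#' heterogeneity estimate, `gamma* = gamma_hat + 1.645 sd_gamma` (normal
#' approximation on the gamma estimator, floored at 0), so small evidence
#' bases with poorly determined gamma are penalized: the fewer the studies,
#' the larger `sd_gamma` and the wider the interval.
#'
#' @param log_rr_ref pooled log relative risk at the reference covariate
#'   level.
#' @param var_fixed its fixed-effect variance (> 0).
#' @param gamma_hat estimated between-study variance (>= 0).
#' @param sd_gamma standard deviation of the gamma estimate (>= 0).
#' @param gamma_quantile quantile of gamma folded into the wide interval
#'   (default 0.95).
#' @param level interval coverage (default 0.95).
#' @return list with `ui_no_gamma`, `ui_with_gamma` (each `c(lower, upper)`
#'   on the RR scale) and `gamma_star`.
#' @export
compute_uis <- function(log_rr_ref, var_fixed, gamma_hat, sd_gamma,
                        gamma_quantile = 0.95, level = 0.95) {
  stopifnot(var_fixed > 0, gamma_hat >= 0, sd_gamma >= 0)
  z <- qnorm(1 - (1 - level) / 2)
  gamma_star <- max(0, gamma_hat + qnorm(gamma_quantile) * sd_gamma)
  list(
    ui_no_gamma = exp(log_rr_ref + c(-1, 1) * z * sqrt(var_fixed)),
    ui_with_gamma = exp(log_rr_ref + c(-1, 1) * z * sqrt(var_fixed + gamma_star)),
    gamma_star = gamma_star
  )
}

#' Burden-of-proof risk function for a dichotomous risk
#'
#' The BPRF is the 5th-quantile estimate of the relative risk closest to the
#' null, inclusive of between-study heterogeneity: the most conservative
#' effect consistent with the data. For a harmful risk this is
#' `exp(log_rr_ref - 1.645 sqrt(var_fixed + gamma_star))`; for a protective
#' risk the sign flips (the quantile nearest 1 from below).
#'
#' @inheritParams compute_uis
#' @param gamma_star 95th-quantile-adjusted heterogeneity variance, as
#'   returned by [compute_uis()].
#' @param direction `"harmful"` or `"protective"`.
#' @return the BPRF on the relative-risk scale.
#' @export
compute_bprf <- function(log_rr_ref, var_fixed, gamma_star,
                         direction = c("harmful", "protective")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(log_rr_ref), var_fixed >= 0, gamma_star >= 0)
  sgn <- if (direction == "harmful") -1 else 1
  exp(log_rr_ref + sgn * .z90u() * sqrt(var_fixed + gamma_star))
}

#' Risk-outcome score
#'
#' Signed `log(BPRF) / 2`: positive when the conservative (burden-of-proof)
#' effect still indicates an association in the stated direction, negative
#' when heterogeneity pushes the conservative estimate across the null.
#'
#' @param bprf burden-of-proof relative risk (> 0).
#' @param direction `"harmful"` or `"protective"`.
#' @return the ROS (dimensionless).
#' @export
compute_ros <- function(bprf, direction = c("harmful", "protective")) {
  direction <- match.arg(direction)
  if (!is.finite(bprf) || bprf <= 0) .stop_validation("bprf must be > 0")
  if (direction == "harmful") log(bprf) / 2 else -log(bprf) / 2
}

#' Star rating of a risk-outcome score
#'
#' Discretizes the ROS into the published 0-5 star bins: zero stars when the
#' relationship is not significant without heterogeneity (the 95% UI without
#' gamma spans the null RR of 1, in which case no ROS is computed at all);
#' otherwise one star for ROS <= 0, two for (0, 0.14], three for
#' (0.14, 0.41], four for (0.41, 0.62] and five above 0.62.
#'
#' @param ros the risk-outcome score, or `NA` when `significant_no_gamma`
#'   is `FALSE`.
#' @param significant_no_gamma whether the 95% UI without heterogeneity
#'   excludes 1.
#' @param thresholds the four upper bin edges.
#' @return integer star count, 0-5.
#' @export
star_rating <- function(ros, significant_no_gamma,
                        thresholds = c(0, 0.14, 0.41, 0.62)) {
  stopifnot(length(thresholds) == 4L, !is.unsorted(thresholds, strictly = TRUE))
  if (!significant_no_gamma) {
    if (!is.na(ros)) {
      stop("a ROS must not be supplied for a non-significant (zero-star) pair")
    }
    return(0L)
  }
  if (is.na(ros)) stop("ros is required when significant_no_gamma is TRUE")
  if (ros <= thresholds[1]) 1L
  else if (ros <= thresholds[2]) 2L
  else if (ros <= thresholds[3]) 3L
  else if (ros <= thresholds[4]) 4L
  else 5L
}

#' Excess risk implied by a burden-of-proof relative risk
#'
#' `(bprf - 1) * 100`, read as "exposure is associated with at least an x%
#' increase in risk" for harmful associations.
#'
#' @param bprf burden-of-proof relative risk (> 0).
#' @return percentage excess risk.
#' @export
excess_risk_percent <- function(bprf) {
  if (!is.finite(bprf) || bprf <= 0) .stop_validation("bprf must be > 0")
  (bprf - 1) * 100
}

#' Evidence score for a risk-outcome pair
#'
#' Assembles the full evidence-table row from a fitted model (or from its
#' summary statistics): pooled RR, 95% UIs with and without between-study
#' heterogeneity, BPRF, ROS, star rating, and the publication-bias flag.
#' For pairs whose no-heterogeneity UI spans the null, the relationship is
#' not significant at the 0.05 level: the pair is rated zero stars and BPRF
#' and ROS are suppressed (`NA`, rendered "N/A" in reports).
#'
#' @param x a [bop_model()] fit, or the reference log relative risk as a
#'   single number.
#' @param ... passed to methods.
#' @return an object of class `bop_score`.
#' @export
evidence_score <- function(x, ...) UseMethod("evidence_score")

#' @rdname evidence_score
#' @param var_fixed fixed-effect variance of `x` (numeric method).
#' @param gamma_hat,sd_gamma heterogeneity estimate and its uncertainty.
#' @param n_studies_val number of studies behind the estimate.
#' @param pub_bias logical publication-bias flag (from [eggers_test()]).
#' @param direction `"harmful"` or `"protective"`.
#' @param gamma_quantile,thresholds tuning constants, see [compute_uis()]
#'   and [star_rating()].
#' @export
evidence_score.numeric <- function(x, var_fixed, gamma_hat = 0, sd_gamma = 0,
                                   n_studies_val = NA_integer_,
                                   pub_bias = NA,
                                   direction = c("harmful", "protective"),
                                   gamma_quantile = 0.95,
                                   thresholds = c(0, 0.14, 0.41, 0.62), ...) {
  direction <- match.arg(direction)
  log_rr <- x
  uis <- compute_uis(log_rr, var_fixed, gamma_hat, sd_gamma, gamma_quantile)
  significant <- if (direction == "harmful") {
    uis$ui_no_gamma[1] > 1
  } else {
    uis$ui_no_gamma[2] < 1
  }
  if (significant) {
    bprf <- compute_bprf(log_rr, var_fixed, uis$gamma_star, direction)
    ros <- compute_ros(bprf, direction)
    stars <- star_rating(ros, TRUE, thresholds)
  } else {
    bprf <- NA_real_
    ros <- NA_real_
    stars <- star_rating(NA_real_, FALSE, thresholds)
  }
  structure(list(
    rr = exp(log_rr), log_rr = log_rr, var_fixed = var_fixed,
    gamma_hat = gamma_hat, sd_gamma = sd_gamma, gamma_star = uis$gamma_star,
    ui_no_gamma = uis$ui_no_gamma, ui_with_gamma = uis$ui_with_gamma,
    significant_no_gamma = significant,
    bprf = bprf, ros = ros, stars = stars,
    excess_risk_pct = if (is.na(bprf)) NA_real_ else excess_risk_percent(bprf),
    pub_bias = pub_bias, n_studies = n_studies_val, direction = direction
  ), class = "bop_score")
}

#' @rdname evidence_score
#' @param egger optional [eggers_test()] result supplying the
#'   publication-bias flag.
#' @export
evidence_score.bop_model <- function(x, egger = NULL,
                                     direction = c("harmful", "protective"),
                                     gamma_quantile = 0.95,
                                     thresholds = c(0, 0.14, 0.41, 0.62), ...) {
  direction <- match.arg(direction)
  ref <- predict_reference_risk(x)
  evidence_score(ref$log_rr, var_fixed = ref$var,
                 gamma_hat = x$gamma, sd_gamma = x$sd_gamma,
                 n_studies_val = x$n_studies,
                 pub_bias = if (is.null(egger)) NA else egger$flagged,
                 direction = direction, gamma_quantile = gamma_quantile,
                 thresholds = thresholds)
}

#' @export
print.bop_score <- function(x, digits = 2, ...) {
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  na_fmt <- function(v) if (is.na(v)) "N/A" else fmt(v)
  cat("Evidence score\n")
  cat(sprintf("  RR %s (95%% UI without gamma: %s, %s; with gamma: %s, %s)\n",
              fmt(x$rr), fmt(x$ui_no_gamma[1]), fmt(x$ui_no_gamma[2]),
              fmt(x$ui_with_gamma[1]), fmt(x$ui_with_gamma[2])))
  cat(sprintf("  BPRF %s   ROS %s   stars %d   pub. bias %s   studies %s\n",
              na_fmt(x$bprf), na_fmt(x$ros), x$stars,
              if (is.na(x$pub_bias)) "untested" else if (x$pub_bias) "Yes" else "No",
              ifelse(is.na(x$n_studies), "?", x$n_studies)))
  if (!is.na(x$bprf)) {
    cat(sprintf("  conservative reading: at least a %.0f%% %s in risk\n",
                abs(x$excess_risk_pct),
                if (x$direction == "harmful") "increase" else "decrease"))
  } else {
    cat("  insufficient evidence of an association (zero stars)\n")
  }
  invisible(x)
}
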