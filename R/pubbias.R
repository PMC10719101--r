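#' Egger's regression test for publication bias
#'
#' Regresses model residuals on their standard errors by weighted least
#' squares (weights `1/SE^2`, intercept included). A slope significantly
#' different from zero indicates that smaller (noisier) studies report
#' systematically different effects — the funnel-plot asymmetry signature of
#' publication or small-study bias. The p-value is two-sided from the t
#' distribution with `n - 2` degrees of freedom.
#'
#' @param resid per-observation residuals on the log-RR scale (observed
#'   minus covariate-adjusted fit).
#' @param ses per-observation standard errors (> 0).
#' @param alpha flagging threshold, default 0.05.
#' @return object of class `egger_test` with `slope`, `se_slope`, `p_value`,
#'   `flagged` and `n`. When all SEs are identical the slope is undefined;
#'   the result is not flagged and carries a diagnostic `note`.
#' @seealso [funnel_data()]
#' @export
eggers_test <- function(resid, ses, alpha = 0.05) {
  stopifnot(length(resid) == length(ses))
  if (length(resid) < 3L) .stop_validation("Egger's test needs >= 3 observations")
  if (any(ses <= 0)) .stop_validation("standard errors must be > 0")
  out <- list(slope = NA_real_, se_slope = NA_real_, p_value = NA_real_,
              flagged = FALSE, n = length(resid), note = NULL)
  if (var(ses) == 0) {
    out$note <- "all standard errors identical: zero design variance, slope undefined"
    return(structure(out, class = "egger_test"))
  }
  fit <- lm(resid ~ ses, weights = 1 / ses^2)
  ct <- summary(fit)$coefficients
  out$slope <- ct["ses", "Estimate"]
  out$se_slope <- ct["ses", "Std. Error"]
  out$p_value <- ct["ses", "Pr(>|t|)"]
  out$flagged <- is.finite(out$p_value) && out$p_value < alpha
  structure(out, class = "egger_test")
}

#' Funnel-plot data for a fitted model
#'
#' One row per observation (trimmed observations included and flagged):
#' residual against the covariate-adjusted fit, the observation's standard
#' error, and the trim flag. Suitable for plotting residual vs SE with a
#' vertical null reference line at 0.
#'
#' @param fit a [bop_model()] fit.
#' @return data frame with columns `study_id`, `residual`, `se`, `trimmed`.
#' @export
funnel_data <- function(fit) {
  stopifnot(inherits(fit, "bop_model"))
  data.frame(study_id = fit$data$study_id,
             residual = residuals(fit, type = "raw"),
             se = fit$data$se_log_rr,
             trimmed = !fit$retained,
             stringsAsFactors = FALSE)
}

#' @export
print.egger_test <- function(x, ...) {
  cat("Egger's regression test for publication bias\n")
  if (!is.null(x$note)) {
    cat("  ", x$note, "\n", sep = "")
  } else {
    cat(sprintf("  slope %.4f (SE %.4f), p = %.4g on %d observations\n",
                x$slope, x$se_slope, x$p_value, x$n))
  }
  cat(sprintf("  publication bias detected: %s\n", if (x$flagged) "Yes" else "No"))
  invisible(x)
}
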