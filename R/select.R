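#' Select significant bias covariates along a Lasso path
#'
#' Implements the two-stage covariate-selection strategy: candidate bias
#' covariates are ordered by their entry into an L1-regularization path, and
#' then admitted one at a time into an unregularized weighted refit, keeping
#' a candidate only when its Wald test is significant at `alpha` given the
#' covariates already retained.
#'
#' The path is computed on the design standardized by the observation
#' standard errors (each row of `(1, x)` and the response divided by its
#' `se_log_rr`), so entry order is decided on the same inverse-variance
#' scale the likelihood uses; the intercept column is never penalized. The
#' confirmation step is the fixed-effect weighted least-squares fit with
#' known variances, so the Wald statistic is a z-test. The whole procedure
#' is deterministic given the dataset.
#'
#' @param dataset a [ro_dataset()].
#' @param candidates covariate names to consider; defaults to the testable
#'   covariates of the dataset (see [derive_testable_covariates()]).
#'   Supplying a non-testable candidate is an error.
#' @param alpha two-sided significance threshold, default 0.05.
#' @param nlambda number of points on the logarithmic lambda path.
#' @return character vector of selected covariate names, in path-entry
#'   order (possibly empty).
#' @export
select_bias_covariates <- function(dataset, candidates = NULL, alpha = 0.05,
                                   nlambda = 100L) {
  stopifnot(inherits(dataset, "ro_dataset"))
  if (alpha <= 0 || alpha >= 1) .stop_validation("alpha must lie in (0, 1)")
  test_tab <- derive_testable_covariates(dataset)
  if (is.null(candidates)) {
    candidates <- test_tab$covariate[test_tab$testable]
  } else {
    unknown <- setdiff(candidates, test_tab$covariate)
    if (length(unknown)) {
      .stop_validation(paste0("unknown covariate(s): ",
                              paste(unknown, collapse = ", ")))
    }
    bad <- candidates[!test_tab$testable[match(candidates, test_tab$covariate)]]
    if (length(bad)) {
      .stop_validation(paste0(
        "candidate covariate(s) not testable (need >= 2 observations per level): ",
        paste(bad, collapse = ", ")))
    }
  }
  if (!length(candidates)) return(character(0))

  se <- dataset$se_log_rr
  ys <- dataset$log_rr / se
  Xs <- cbind(intercept = 1 / se,
              as.matrix(as.data.frame(dataset)[candidates]) / se)

  path <- glmnet::glmnet(Xs, ys, family = "gaussian", intercept = FALSE,
                         standardize = FALSE, nlambda = nlambda,
                         lambda.min.ratio = 1e-4,
                         penalty.factor = c(0, rep(1, length(candidates))))
  B <- as.matrix(path$beta)[candidates, , drop = FALSE]
  entry <- apply(B != 0, 1L, function(z) if (any(z)) which(z)[1] else Inf)
  # ties (same lambda step) and never-entering covariates fall back to input order
  ord <- candidates[order(entry, seq_along(candidates))]

  selected <- character(0)
  for (cand in ord) {
    cols <- c("intercept", selected, cand)
    Xc <- cbind(intercept = 1 / se,
                as.matrix(as.data.frame(dataset)[c(selected, cand)]) / se)
    XtX <- crossprod(Xc)
    est <- tryCatch(solve(XtX, crossprod(Xc, ys)), error = function(e) NULL)
    if (is.null(est)) next  # collinear with already-retained set
    v <- solve(XtX)
    j <- length(cols)
    z <- est[j] / sqrt(v[j, j])
    if (2 * pnorm(-abs(z)) < alpha) selected <- c(selected, cand)
  }
  selected
}
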