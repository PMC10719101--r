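# Marginal model: y_ij = x_ij' beta + u_i + e_ij, u_i ~ N(0, gamma),
# e_ij ~ N(0, se_ij^2). Per study g the marginal covariance is
# V_g = D_g + gamma * 1 1' with D_g = diag(se^2); all linear algebra below
# uses the rank-one Woodbury identities so a fit costs O(n p^2) per gamma
# evaluation, and gamma is profiled out by one-dimensional optimization.

.study_blocks <- function(study) {
  split(seq_along(study), factor(study, levels = unique(study)))
}

# GLS fit of beta at a fixed gamma; returns beta, its covariance, the exact
# negative marginal log-likelihood and per-study weight sums.
.gls_fit <- function(y, X, se2, blocks, gamma, covariates = colnames(X)) {
  p <- ncol(X)
  A <- matrix(0, p, p)
  b <- numeric(p)
  logdet <- 0
  for (idx in blocks) {
    d <- 1 / se2[idx]
    w <- sum(d)
    cc <- gamma / (1 + gamma * w)
    Xg <- X[idx, , drop = FALSE]
    Xd <- colSums(Xg * d)
    A <- A + crossprod(Xg * sqrt(d)) - cc * tcrossprod(Xd)
    b <- b + colSums(Xg * (d * y[idx])) - cc * Xd * sum(d * y[idx])
    logdet <- logdet + sum(log(se2[idx])) + log1p(gamma * w)
  }
  beta <- tryCatch(solve(A, b), error = function(e) {
    .stop_fit(paste0("singular design; check collinearity among covariates: ",
                     paste(covariates, collapse = ", ")))
  })
  quad <- 0
  for (idx in blocks) {
    d <- 1 / se2[idx]
    cc <- gamma / (1 + gamma * sum(d))
    r <- y[idx] - drop(X[idx, , drop = FALSE] %*% beta)
    quad <- quad + sum(d * r^2) - cc * sum(d * r)^2
  }
  nll <- 0.5 * (logdet + quad + length(y) * log(2 * pi))
  list(beta = beta, vcov = solve(A), nll = nll, gamma = gamma)
}

# Profile the marginal likelihood over gamma >= 0 (Brent), with an explicit
# boundary check at 0 and automatic expansion of the search interval.
.fit_core <- function(y, X, se2, study, fix_gamma = NULL,
                      covariates = colnames(X)) {
  blocks <- .study_blocks(study)
  if (!is.null(fix_gamma)) {
    if (fix_gamma < 0) .stop_validation("fix_gamma must be >= 0")
    fit <- .gls_fit(y, X, se2, blocks, fix_gamma, covariates)
    gamma_hat <- fix_gamma
  } else {
    prof <- function(g) .gls_fit(y, X, se2, blocks, g, covariates)$nll
    upper <- max(0.1, 4 * var(y))
    for (i in 1:6) {
      opt <- optimize(prof, c(0, upper), tol = 1e-10)
      if (opt$minimum < 0.95 * upper) break
      upper <- upper * 4
    }
    gamma_hat <- if (prof(0) <= opt$objective) 0 else opt$minimum
    fit <- .gls_fit(y, X, se2, blocks, gamma_hat, covariates)
  }
  if (!is.finite(fit$nll)) .stop_fit("non-finite likelihood at the optimum",
                                     last = fit)
  # Fisher information for gamma: I = 1/2 sum_g tr[(V_g^-1 dV/dgamma)^2]
  # with dV/dgamma = 1 1', which reduces to (1' V_g^-1 1)^2 per study.
  s <- vapply(blocks, function(idx) {
    w <- sum(1 / se2[idx])
    w / (1 + gamma_hat * w)
  }, numeric(1))
  info <- 0.5 * sum(s^2)
  fit$sd_gamma <- if (info > 0) sqrt(1 / info) else Inf
  fit$gamma <- gamma_hat
  fit
}

#' Fit a trimmed mixed-effects meta-regression on log relative risks
#'
#' Maximizes the marginal likelihood of
#' \deqn{y_{ij} = \beta_0 + x_{ij}^T \beta + u_i + \epsilon_{ij}, \quad
#'       u_i \sim N(0, \gamma), \; \epsilon_{ij} \sim N(0, \sigma_{ij}^2)}
#' where `i` indexes studies (one shared random intercept per study, which
#' is how within-study correlation of its observations is accounted for) and
#' \eqn{\sigma_{ij}} are the reported sampling standard errors. \eqn{\gamma}
#' is the between-study heterogeneity variance, constrained non-negative;
#' its standard deviation is obtained from the Fisher information
#' \eqn{I(\gamma) = \frac12 \sum_g \mathrm{tr}[(V_g^{-1} \partial V_g /
#' \partial\gamma)^2]} evaluated at the optimum (one-sided when the estimate
#' sits on the boundary \eqn{\gamma = 0}).
#'
#' When the dataset holds at least `trim_min_obs` observations and
#' `trim > 0`, likelihood-based trimming removes the
#' `n - ceiling((1 - trim) n)` observations least consistent with the model:
#' the fit and the retained set are iterated to a fixed point, ranking
#' observations at each step by their marginal log-likelihood contribution
#' (normal density with variance \eqn{\sigma_{ij}^2 + \gamma}), ties broken
#' in favour of retaining the smaller standard error, then input order.
#'
#' @param dataset a [ro_dataset()] with at least three distinct studies.
#' @param covariates names of `cv_` columns to adjust for (typically the
#'   output of [select_bias_covariates()]).
#' @param trim trimming proportion in `[0, 0.5]`; 0.1 removes the 10% least
#'   self-coherent observations.
#' @param trim_min_obs minimum number of observations for trimming to
#'   activate (default 10); below it the fit is untrimmed.
#' @param fix_gamma optional fixed value for the heterogeneity variance
#'   (e.g. 0 for a fixed-effect fit); `NULL` estimates it.
#' @param max_iter cap on trimming iterations.
#' @return an object of class `bop_model` with components `coefficients`,
#'   `vcov`, `gamma`, `sd_gamma`, `retained` (logical trim mask, `TRUE` =
#'   kept), `logLik`, `n_retained`, and the input data. Standard methods
#'   (`print`, `summary`, `coef`, `vcov`, `logLik`, `residuals`, `fitted`,
#'   `predict`, `simulate`, `plot`) apply.
#' @examples
#' d <- simulate_ro_dataset(ro_truth(beta0 = log(2), gamma = 0.02,
#'                                   n_studies = 15, seed = 3))
#' fit <- bop_model(d, trim = 0.1)
#' summary(fit)
#' @export
bop_model <- function(dataset, covariates = character(),
                      trim = 0.10, trim_min_obs = 10L,
                      fix_gamma = NULL, max_iter = 100L) {
  if (!inherits(dataset, "ro_dataset")) dataset <- ro_dataset(dataset)
  if (trim < 0 || trim > 0.5) .stop_validation("trim must lie in [0, 0.5]")
  if (n_studies(dataset) < 3L) {
    .stop_gate(paste0("model fitting requires at least three studies; got ",
                      n_studies(dataset)))
  }
  unknown <- setdiff(covariates, covariate_names(dataset))
  if (length(unknown)) {
    .stop_validation(paste0("unknown covariate(s): ",
                            paste(unknown, collapse = ", ")))
  }

  y <- dataset$log_rr
  se2 <- dataset$se_log_rr^2
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (length(covariates)) {
    X <- cbind(X, as.matrix(as.data.frame(dataset)[covariates]))
  }
  if (qr(X)$rank < ncol(X)) {
    .stop_fit(paste0("singular design; check collinearity among covariates: ",
                     paste(covariates, collapse = ", ")))
  }

  do_trim <- trim > 0 && n >= trim_min_obs
  k_retain <- if (do_trim) as.integer(ceiling((1 - trim) * n)) else n
  retained <- rep(TRUE, n)
  iter <- 0L
  trim_converged <- TRUE
  repeat {
    keep <- which(retained)
    fit <- .fit_core(y[keep], X[keep, , drop = FALSE], se2[keep],
                     dataset$study_id[keep], fix_gamma, covariates)
    if (!do_trim) break
    mu <- drop(X %*% fit$beta)
    ll <- dnorm(y, mu, sqrt(se2 + fit$gamma), log = TRUE)
    ord <- order(-ll, dataset$se_log_rr, seq_len(n))
    new_retained <- rep(FALSE, n)
    new_retained[ord[seq_len(k_retain)]] <- TRUE
    iter <- iter + 1L
    if (identical(new_retained, retained)) break
    retained <- new_retained
    if (iter >= max_iter) {
      trim_converged <- FALSE
      warning("trimming did not reach a fixed point; using last mask")
      break
    }
  }

  beta <- setNames(fit$beta, colnames(X))
  structure(list(
    coefficients = beta,
    vcov = structure(fit$vcov, dimnames = list(colnames(X), colnames(X))),
    gamma = fit$gamma,
    sd_gamma = fit$sd_gamma,
    gamma_fixed = !is.null(fix_gamma),
    retained = retained,
    logLik = -fit$nll,
    trim = if (do_trim) trim else 0,
    trim_iterations = iter,
    trim_converged = trim_converged,
    n_obs = n,
    n_retained = sum(retained),
    n_studies = n_studies(dataset),
    covariates = covariates,
    data = dataset,
    call = match.call()
  ), class = "bop_model")
}

#' Bias-adjusted pooled effect at the gold-standard covariate level
#'
#' Evaluates the fitted model with every selected bias covariate at its
#' reference level 0, i.e. the pooled log relative risk a gold-standard
#' study would be expected to report, together with its fixed-effect
#' variance.
#'
#' @param fit a [bop_model()] fit.
#' @return named list with `log_rr` (the reference prediction), `var` (its
#'   variance) and `rr` (`exp(log_rr)`).
#' @export
predict_reference_risk <- function(fit) {
  stopifnot(inherits(fit, "bop_model"))
  list(log_rr = unname(fit$coefficients[1]),
       var = unname(fit$vcov[1, 1]),
       rr = exp(unname(fit$coefficients[1])))
}

#' @export
coef.bop_model <- function(object, ...) object$coefficients

#' @export
vcov.bop_model <- function(object, ...) object$vcov

#' @export
logLik.bop_model <- function(object, ...) {
  structure(object$logLik,
            df = length(object$coefficients) + !object$gamma_fixed,
            nobs = object$n_retained, class = "logLik")
}

#' @export
fitted.bop_model <- function(object, ...) {
  X <- cbind(1, as.matrix(as.data.frame(object$data)[object$covariates]))
  drop(X %*% object$coefficients)
}

#' Residuals of a fitted meta-regression
#'
#' Raw residuals are observed `log_rr` minus the covariate-adjusted fixed
#' effect prediction, for every observation including trimmed ones;
#' standardized residuals divide by the marginal standard deviation
#' `sqrt(se^2 + gamma)`.
#'
#' @param object a `bop_model`.
#' @param type `"raw"` or `"standardized"`.
#' @param ... unused.
#' @export
residuals.bop_model <- function(object, type = c("raw", "standardized"), ...) {
  type <- match.arg(type)
  r <- object$data$log_rr - fitted(object)
  if (type == "standardized") {
    r <- r / sqrt(object$data$se_log_rr^2 + object$gamma)
  }
  r
}

#' Predictions from a fitted meta-regression
#'
#' @param object a `bop_model`.
#' @param type `"reference"` (default) returns the bias-adjusted pooled
#'   effect as in [predict_reference_risk()]; `"link"` returns per-observation
#'   fitted log RRs; `"response"` the same on the RR scale.
#' @param ... unused.
#' @export
predict.bop_model <- function(object, type = c("reference", "link", "response"), ...) {
  type <- match.arg(type)
  switch(type,
         reference = predict_reference_risk(object),
         link = fitted(object),
         response = exp(fitted(object)))
}

#' Simulate datasets from a fitted model
#'
#' Draws new evidence tables from the generative model implied by the fit:
#' fitted coefficients, estimated heterogeneity, and the observed standard
#' errors reused as-is (design held fixed).
#'
#' @param object a `bop_model`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `ro_dataset` objects of the same shape as the original.
#' @export
simulate.bop_model <- function(object, nsim = 1, seed = 1L, ...) {
  set.seed(seed)
  d <- object$data
  mu <- fitted(object)
  blocks <- .study_blocks(d$study_id)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    u <- rnorm(length(blocks), 0, sqrt(object$gamma))
    y <- mu + rnorm(nrow(d), 0, d$se_log_rr)
    for (g in seq_along(blocks)) y[blocks[[g]]] <- y[blocks[[g]]] + u[g]
    d_s <- d
    d_s$log_rr <- y
    out[[s]] <- d_s
  }
  out
}

#' @export
print.bop_model <- function(x, digits = 4, ...) {
  cat("Mixed-effects meta-regression (marginal ML)\n")
  ref <- predict_reference_risk(x)
  cat(sprintf("  pooled RR (reference level): %.*f  [log RR %.*f, SE %.*f]\n",
              digits, ref$rr, digits, ref$log_rr, digits, sqrt(ref$var)))
  cat(sprintf("  between-study variance gamma: %.*f (sd %.*f)%s\n",
              digits, x$gamma, digits, x$sd_gamma,
              if (x$gamma_fixed) " [fixed]" else ""))
  cat(sprintf("  %d/%d observations retained (%d studies)",
              x$n_retained, x$n_obs, x$n_studies))
  if (x$trim > 0) cat(sprintf(", %.0f%% trimming", 100 * x$trim))
  cat("\n")
  if (length(x$covariates)) {
    cat("  bias covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.bop_model <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(coefficients = tab, gamma = object$gamma,
                 sd_gamma = object$sd_gamma, logLik = object$logLik,
                 n_obs = object$n_obs, n_retained = object$n_retained,
                 n_studies = object$n_studies, trim = object$trim,
                 call = object$call),
            class = "summary.bop_model")
}

#' @export
print.summary.bop_model <- function(x, ...) {
  cat("Call: ")
  print(x$call)
  cat("\nFixed effects (log RR scale):\n")
  printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nBetween-study variance gamma: %.5f (sd %.5f)\n",
              x$gamma, x$sd_gamma))
  cat(sprintf("Log-likelihood %.3f on %d retained of %d observations (%d studies)\n",
              x$logLik, x$n_retained, x$n_obs, x$n_studies))
  invisible(x)
}

#' Forest and funnel plots for a fitted model
#'
#' `type = "forest"` draws per-observation RRs with 95% CIs, marking trimmed
#' observations, with the pooled estimate and the null line. `type =
#' "funnel"` plots residuals against standard errors with the pseudo 95%
#' funnel.
#'
#' @param x a `bop_model`.
#' @param type `"forest"` or `"funnel"`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.bop_model <- function(x, type = c("forest", "funnel"), ...) {
  type <- match.arg(type)
  d <- x$data
  if (type == "forest") {
    n <- nrow(d)
    rr <- exp(d$log_rr)
    lo <- exp(d$log_rr - .z95() * d$se_log_rr)
    hi <- exp(d$log_rr + .z95() * d$se_log_rr)
    ypos <- rev(seq_len(n))
    plot(rr, ypos, log = "x", xlim = range(lo, hi, 1), pch = 19,
         col = ifelse(x$retained, "black", "red"),
         xlab = "Relative risk (log scale)", ylab = "", yaxt = "n", ...)
    segments(lo, ypos, hi, ypos, col = ifelse(x$retained, "black", "red"))
    axis(2, at = ypos, labels = d$study_id, las = 1, cex.axis = 0.7)
    abline(v = 1, lty = 2)
    abline(v = predict_reference_risk(x)$rr, col = "blue")
  } else {
    r <- residuals(x)
    plot(r, d$se_log_rr, ylim = rev(range(d$se_log_rr, 0)),
         pch = ifelse(x$retained, 19, 4),
         xlab = "Residual (log RR)", ylab = "Standard error", ...)
    smax <- max(d$se_log_rr)
    polygon(c(0, -.z95() * smax, .z95() * smax), c(0, smax, smax),
            border = NA, col = grDevices::adjustcolor("grey", 0.3))
    abline(v = 0, lty = 2)
  }
  invisible(x)
}
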