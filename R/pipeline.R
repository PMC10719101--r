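#' Pipeline configuration
#'
#' Collects every tunable constant of the per-pair analysis so none is
#' hard-coded in the pipeline: trimming proportion and its activation
#' threshold, the covariate-selection significance level, the heterogeneity
#' quantile folded into wide intervals, the ROS star bin edges, the modeled
#' direction, and the seed. The theoretical minimum risk exposure level for
#' a dichotomous exposure is zero (no exposure) and is recorded as metadata.
#'
#' @param trim_proportion proportion of observations removed by
#'   likelihood-based trimming, in `[0, 0.5]`.
#' @param trim_min_obs minimum observations before trimming activates.
#' @param alpha_selection significance level for bias-covariate selection.
#' @param gamma_quantile quantile of the heterogeneity estimate used in the
#'   wide uncertainty interval and the BPRF.
#' @param star_thresholds the four ROS cut points separating 1-5 stars.
#' @param direction `"harmful"` or `"protective"`.
#' @param repeat_adjustment `"sqrt"` or `"linear"`, see
#'   [adjust_se_for_repeats()].
#' @param select_on_trimmed whether covariate selection runs on the trimmed
#'   dataset (default `FALSE`: selection on all observations, trimming in
#'   the final fit only).
#' @param egger_on_trimmed run Egger's test on the retained residuals only
#'   (default `TRUE`).
#' @param tmrel theoretical minimum risk exposure level (metadata).
#' @param seed integer seed for any stochastic step.
#' @return an object of class `bop_config`.
#' @export
bop_config <- function(trim_proportion = 0.10,
                       trim_min_obs = 10L,
                       alpha_selection = 0.05,
                       gamma_quantile = 0.95,
                       star_thresholds = c(0, 0.14, 0.41, 0.62),
                       direction = c("harmful", "protective"),
                       repeat_adjustment = c("sqrt", "linear"),
                       select_on_trimmed = FALSE,
                       egger_on_trimmed = TRUE,
                       tmrel = 0,
                       seed = 1L) {
  direction <- match.arg(direction)
  repeat_adjustment <- match.arg(repeat_adjustment)
  if (trim_proportion < 0 || trim_proportion > 0.5) {
    .stop_validation("trim_proportion must lie in [0, 0.5]")
  }
  if (length(star_thresholds) != 4L ||
      is.unsorted(star_thresholds, strictly = TRUE)) {
    .stop_validation("star_thresholds must be four strictly increasing values")
  }
  if (alpha_selection <= 0 || alpha_selection >= 1) {
    .stop_validation("alpha_selection must lie in (0, 1)")
  }
  structure(list(trim_proportion = trim_proportion,
                 trim_min_obs = as.integer(trim_min_obs),
                 alpha_selection = alpha_selection,
                 gamma_quantile = gamma_quantile,
                 star_thresholds = star_thresholds,
                 direction = direction,
                 repeat_adjustment = repeat_adjustment,
                 select_on_trimmed = select_on_trimmed,
                 egger_on_trimmed = egger_on_trimmed,
                 tmrel = tmrel,
                 seed = as.integer(seed)),
            class = "bop_config")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' One `key = value` per line; vector values (the star thresholds) are
#' comma-separated. Unknown keys are an error. Keys not present keep their
#' [bop_config()] defaults.
#'
#' @param path file to read.
#' @return a `bop_config`.
#' @export
read_bop_config <- function(path) {
  if (!file.exists(path)) .stop_validation(paste0("config file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "\\s*=\\s*")[[1]]
    if (length(kv) != 2L) .stop_validation(paste0("malformed config line: ", ln))
    key <- trimws(kv[1])
    val <- trimws(strsplit(kv[2], ",")[[1]])
    args[[key]] <- if (key %in% c("direction", "repeat_adjustment")) {
      val
    } else if (key %in% c("select_on_trimmed", "egger_on_trimmed")) {
      as.logical(val)
    } else {
      as.numeric(val)
    }
  }
  unknown <- setdiff(names(args), names(formals(bop_config)))
  if (length(unknown)) {
    .stop_validation(paste0("unknown config key(s): ",
                            paste(unknown, collapse = ", ")))
  }
  do.call(bop_config, args)
}

#' Run the full evidence-scoring pipeline on one risk-outcome pair
#'
#' Executes, in order: the minimum-evidence gate (at least three distinct
#' studies), the repeated-measurement SE adjustment, bias-covariate
#' testability, Lasso-guided covariate selection, the trimmed mixed-effects
#' fit, the reference-level (bias-adjusted) prediction, Egger's regression
#' on the retained residuals, and the evidence score (UIs, BPRF, ROS,
#' stars).
#'
#' @param dataset a [ro_dataset()].
#' @param config a [bop_config()].
#' @return an object of class `bop_result`: a list with `score`
#'   (`bop_score`), `fit` (`bop_model`), `egger` (`egger_test`), `testable`
#'   (the covariate testability table), `selected` (selected covariate
#'   names) and `funnel` (funnel-plot data).
#' @examples
#' d <- simulate_ro_dataset(ro_truth(beta0 = log(2), gamma = 0.02,
#'                                   n_studies = 12, seed = 11))
#' res <- run_pair(d, bop_config())
#' res$score
#' @export
run_pair <- function(dataset, config = bop_config()) {
  stopifnot(inherits(config, "bop_config"))
  if (!inherits(dataset, "ro_dataset")) dataset <- ro_dataset(dataset)
  if (n_studies(dataset) < 3L) {
    .stop_gate(paste0(
      "refusing to score this pair: at least three studies are required, found ",
      n_studies(dataset)))
  }
  dataset <- adjust_se_for_repeats(dataset, method = config$repeat_adjustment)
  testable <- derive_testable_covariates(dataset)

  selection_data <- dataset
  if (config$select_on_trimmed && nrow(dataset) >= config$trim_min_obs &&
      config$trim_proportion > 0) {
    pre <- bop_model(dataset, trim = config$trim_proportion,
                     trim_min_obs = config$trim_min_obs)
    selection_data <- dataset[pre$retained, ]
  }
  selected <- select_bias_covariates(selection_data,
                                     alpha = config$alpha_selection)

  fit <- bop_model(dataset, covariates = selected,
                   trim = config$trim_proportion,
                   trim_min_obs = config$trim_min_obs)
  egger_resid <- residuals(fit, type = "raw")
  keep <- if (config$egger_on_trimmed) fit$retained else rep(TRUE, fit$n_obs)
  egger <- eggers_test(egger_resid[keep], dataset$se_log_rr[keep])
  score <- evidence_score(fit, egger = egger, direction = config$direction,
                          gamma_quantile = config$gamma_quantile,
                          thresholds = config$star_thresholds)
  structure(list(score = score, fit = fit, egger = egger,
                 testable = testable, selected = selected,
                 funnel = funnel_data(fit),
                 risk_name = attr(dataset, "risk_name"),
                 outcome_name = attr(dataset, "outcome_name"),
                 config = config),
            class = "bop_result")
}

#' @export
print.bop_result <- function(x, ...) {
  cat(sprintf("Risk-outcome pair: %s -> %s\n", x$risk_name, x$outcome_name))
  cat(sprintf("  selected bias covariates: %s\n",
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "none"))
  cat(sprintf("  trimmed observations: %d of %d\n",
              x$fit$n_obs - x$fit$n_retained, x$fit$n_obs))
  print(x$score)
  invisible(x)
}

#' Run a sensitivity analysis for one pair
#'
#' Re-runs [run_pair()] under a modified configuration or dataset and
#' reports the main and sensitivity scores side by side. Supported
#' specifications: `no_trim = TRUE` (disable likelihood-based trimming);
#' `exclude_covariate = "cv_x"` (drop rows where the named covariate is 1,
#' e.g. restricting to gold-standard exposure definitions); or `filter`, a
#' function mapping the dataset to a logical keep-vector.
#'
#' @param dataset a [ro_dataset()].
#' @param config the main [bop_config()].
#' @param spec named list with `name` and one of `no_trim`,
#'   `exclude_covariate`, `filter`.
#' @param main optional pre-computed main [run_pair()] result (recomputed
#'   when missing).
#' @return object of class `bop_sensitivity` with the sensitivity
#'   `bop_result`, the main result and a small comparison table.
#' @export
run_sensitivity <- function(dataset, config = bop_config(), spec, main = NULL) {
  stopifnot(is.list(spec), !is.null(spec$name))
  if (is.null(main)) main <- run_pair(dataset, config)
  sens_data <- dataset
  sens_config <- config
  if (isTRUE(spec$no_trim)) {
    sens_config$trim_proportion <- 0
  } else if (!is.null(spec$exclude_covariate)) {
    cv <- spec$exclude_covariate
    if (!cv %in% covariate_names(dataset)) {
      .stop_validation(paste0("unknown covariate in sensitivity filter: ", cv))
    }
    drop <- dataset[[cv]] == 1
    if (!any(drop)) {
      warning("sensitivity filter matched no rows; dataset unchanged")
    } else {
      sens_data <- dataset[!drop, ]
    }
  } else if (!is.null(spec$filter)) {
    keep <- spec$filter(dataset)
    stopifnot(is.logical(keep), length(keep) == nrow(dataset))
    if (all(keep)) warning("sensitivity filter matched no rows; dataset unchanged")
    sens_data <- dataset[keep, ]
  } else {
    .stop_validation("spec must set no_trim, exclude_covariate or filter")
  }
  if (n_studies(sens_data) < 3L) {
    .stop_gate(paste0(
      "sensitivity '", spec$name, "' leaves fewer than three studies (",
      n_studies(sens_data), "); refusing to fit"))
  }
  sens <- run_pair(sens_data, sens_config)
  comparison <- data.frame(
    analysis = c("main", spec$name),
    rr = c(main$score$rr, sens$score$rr),
    ros = c(main$score$ros, sens$score$ros),
    stars = c(main$score$stars, sens$score$stars),
    gamma = c(main$fit$gamma, sens$fit$gamma),
    n_obs = c(main$fit$n_obs, sens$fit$n_obs),
    stringsAsFactors = FALSE
  )
  structure(list(name = spec$name, main = main, sensitivity = sens,
                 comparison = comparison),
            class = "bop_sensitivity")
}

#' @export
print.bop_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %s\n", x$name))
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}

.fmt_ui <- function(rr, ui, digits = 2) {
  sprintf("%.*f (%.*f, %.*f)", digits, rr, digits, ui[1], digits, ui[2])
}

#' Render report tables for a set of scored pairs
#'
#' Builds the master evidence table (one row per pair, ordered by descending
#' ROS with zero-star pairs last, BPRF/ROS rendered "N/A" when suppressed)
#' plus per-pair forest-plot and funnel-plot data. When `dir` is given the
#' three artifacts are written as tab-separated text with deterministic
#' ordering, so identical inputs yield byte-identical files.
#'
#' @param results list of [run_pair()] results (at least one).
#' @param dir optional output directory.
#' @return invisibly, a list with `summary` (data frame), `forest` and
#'   `funnel` (data frames keyed by risk and outcome).
#' @export
render_reports <- function(results, dir = NULL) {
  if (!length(results)) .stop_validation("no results to report")
  if (inherits(results, "bop_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    s <- r$score
    data.frame(
      risk = r$risk_name,
      outcome = r$outcome_name,
      rr_ui_no_gamma = .fmt_ui(s$rr, s$ui_no_gamma),
      rr_ui_with_gamma = .fmt_ui(s$rr, s$ui_with_gamma),
      bprf = if (is.na(s$bprf)) "N/A" else sprintf("%.2f", s$bprf),
      ros = if (is.na(s$ros)) "N/A" else sprintf("%.2f", s$ros),
      stars = s$stars,
      pub_bias = if (is.na(s$pub_bias)) "untested" else if (s$pub_bias) "Yes" else "No",
      n_studies = s$n_studies,
      selected_covariates = if (length(r$selected)) {
        paste(r$selected, collapse = "; ")
      } else "None",
      n_trimmed = r$fit$n_obs - r$fit$n_retained,
      ros_numeric = ifelse(is.na(s$ros), -Inf, s$ros),
      stringsAsFactors = FALSE
    )
  })
  summary_tab <- do.call(rbind, rows)
  summary_tab <- summary_tab[order(-summary_tab$ros_numeric,
                                   summary_tab$risk, summary_tab$outcome), ]
  summary_tab$ros_numeric <- NULL
  rownames(summary_tab) <- NULL

  forest <- do.call(rbind, lapply(results, function(r) {
    d <- r$fit$data
    data.frame(risk = r$risk_name, outcome = r$outcome_name,
               study_id = d$study_id,
               rr = exp(d$log_rr),
               ci_lower = exp(d$log_rr - .z95() * d$se_log_rr),
               ci_upper = exp(d$log_rr + .z95() * d$se_log_rr),
               trimmed = !r$fit$retained,
               stringsAsFactors = FALSE)
  }))
  funnel <- do.call(rbind, lapply(results, function(r) {
    cbind(risk = r$risk_name, outcome = r$outcome_name, r$funnel)
  }))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write.table(summary_tab, file.path(dir, "evidence_table.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(forest, file.path(dir, "forest_data.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(funnel, file.path(dir, "funnel_data.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(list(summary = summary_tab, forest = forest, funnel = funnel))
}

#' Serialize a fitted model as structured text
#'
#' Writes a key-value header (estimates, heterogeneity, trim settings)
#' followed by a per-observation table with trim flags, residuals and
#' inverse-variance weights, for audit trails alongside report tables.
#'
#' @param fit a [bop_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  stopifnot(inherits(fit, "bop_model"))
  con <- file(path, "w")
  on.exit(close(con))
  kv <- c(
    sprintf("beta0 = %.15g", fit$coefficients[1]),
    sprintf("var_beta0 = %.15g", fit$vcov[1, 1]),
    vapply(seq_along(fit$covariates), function(j) {
      sprintf("beta_%s = %.15g", fit$covariates[j], fit$coefficients[j + 1])
    }, ""),
    sprintf("gamma = %.15g", fit$gamma),
    sprintf("sd_gamma = %.15g", fit$sd_gamma),
    sprintf("loglik = %.15g", fit$logLik),
    sprintf("n_obs = %d", fit$n_obs),
    sprintf("n_retained = %d", fit$n_retained),
    sprintf("n_studies = %d", fit$n_studies),
    sprintf("trim = %.15g", fit$trim),
    ""
  )
  writeLines(kv, con)
  tab <- data.frame(study_id = fit$data$study_id,
                    log_rr = fit$data$log_rr,
                    se_log_rr = fit$data$se_log_rr,
                    residual = residuals(fit),
                    weight = 1 / (fit$data$se_log_rr^2 + fit$gamma),
                    retained = fit$retained)
  write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
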