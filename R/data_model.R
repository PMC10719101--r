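#' Construct a risk-outcome dataset of effect observations
#'
#' A `ro_dataset` is a data frame of study-level effect observations on the
#' natural-log relative-risk scale, one row per extracted effect size.
#' Required columns are `study_id`, `log_rr` and `se_log_rr`; `n_repeats`
#' counts non-mutually-exclusive effect sizes drawn from the same sample
#' (1 = unique observation). Binary bias covariates live in columns prefixed
#' `cv_` and must be coded 0/1, with 0 the gold-standard (reference) level.
#'
#' @param x data frame with at least `study_id`, `log_rr`, `se_log_rr`.
#'   Optional: `n_repeats` (default 1), `measure_type` (`"RR"`, `"OR"` or
#'   `"HR"`; default `"RR"`), `subgroup_label`, and any number of `cv_*`
#'   columns.
#' @param risk_name,outcome_name labels for the risk factor and health
#'   outcome the table describes.
#' @return the validated data frame with class `ro_dataset` and attributes
#'   `risk_name` and `outcome_name`.
#' @examples
#' d <- ro_dataset(data.frame(
#'   study_id = c("a", "a", "b", "c"),
#'   log_rr = c(0.7, 0.6, 0.8, 0.5),
#'   se_log_rr = c(0.1, 0.2, 0.15, 0.3),
#'   cv_odds_ratio = c(0, 0, 1, 1)
#' ), risk_name = "exposure", outcome_name = "outcome")
#' n_studies(d)
#' @export
ro_dataset <- function(x, risk_name = "risk", outcome_name = "outcome") {
  if (!is.data.frame(x)) .stop_validation("`x` must be a data frame")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("study_id", "log_rr", "se_log_rr")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    .stop_validation(paste0("missing required column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  if (!"n_repeats" %in% names(x)) x$n_repeats <- 1L
  if (!"measure_type" %in% names(x)) x$measure_type <- "RR"
  x$study_id <- as.character(x$study_id)

  bad <- which(!is.finite(x$log_rr))
  if (length(bad)) .stop_validation(paste0("non-finite log_rr in row(s) ",
                                           paste(bad, collapse = ", ")))
  bad <- which(!is.finite(x$se_log_rr) | x$se_log_rr <= 0)
  if (length(bad)) .stop_validation(paste0(
    "se_log_rr must be finite and > 0; offending row(s): ",
    paste(bad, collapse = ", ")))
  bad <- which(is.na(x$n_repeats) | x$n_repeats < 1 | x$n_repeats != round(x$n_repeats))
  if (length(bad)) .stop_validation(paste0(
    "n_repeats must be a positive integer; offending row(s): ",
    paste(bad, collapse = ", ")))
  if (!all(x$measure_type %in% c("RR", "OR", "HR"))) {
    .stop_validation("measure_type must be one of RR, OR, HR")
  }
  for (cv in covariate_names(x)) {
    v <- x[[cv]]
    if (anyNA(v) || !all(v %in% c(0, 1))) {
      .stop_validation(paste0("covariate ", cv, " must be coded 0/1 with no NA"))
    }
    x[[cv]] <- as.numeric(v)
  }
  structure(x,
            risk_name = as.character(risk_name),
            outcome_name = as.character(outcome_name),
            class = c("ro_dataset", "data.frame"))
}

#' Bias-covariate column names of a dataset
#'
#' Covariate columns are identified by the `cv_` prefix.
#' @param x a `ro_dataset` or plain data frame.
#' @return character vector of covariate column names (possibly empty).
#' @export
covariate_names <- function(x) {
  grep("^cv_", names(x), value = TRUE)
}

#' Number of distinct studies in a dataset
#' @param x a `ro_dataset`.
#' @return integer count of distinct `study_id` values.
#' @export
n_studies <- function(x) length(unique(x$study_id))

#' Read an extraction table of study-level effect sizes
#'
#' Reads a delimiter-separated evidence table (comma for `.csv`, tab
#' otherwise) and returns a validated [ro_dataset()]. Two layouts are
#' understood:
#'
#' * a *canonical* table already on the log scale, with columns `study_id`,
#'   `log_rr`, `se_log_rr` (as written by [write_extraction_table()]);
#' * a *raw* extraction with a ratio estimate and its 95% confidence bounds,
#'   mapped through `schema`. The estimate is log-transformed and the
#'   standard error recovered as `(log(upper) - log(lower)) / (2 * 1.96)`,
#'   i.e. assuming a symmetric normal interval on the log scale.
#'
#' Bias-covariate columns are those prefixed `cv_` and must be 0/1.
#'
#' @param path file to read.
#' @param schema named list mapping the roles `study_id`, `estimate`,
#'   `lower`, `upper` and optionally `measure`, `n_repeats`,
#'   `subgroup_label` to column names in the file.
#' @param risk_name,outcome_name labels passed to [ro_dataset()].
#' @return a validated `ro_dataset`.
#' @seealso [write_extraction_table()], [adjust_se_for_repeats()]
#' @export
read_extraction_table <- function(path,
                                  schema = list(study_id = "study_id",
                                                estimate = "estimate",
                                                lower = "lower",
                                                upper = "upper",
                                                measure = "measure",
                                                n_repeats = "n_repeats"),
                                  risk_name = "risk",
                                  outcome_name = "outcome") {
  if (!file.exists(path)) .stop_validation(paste0("file not found: ", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) read.csv else read.delim
  raw <- tryCatch(reader(path, stringsAsFactors = FALSE, check.names = FALSE),
                  error = function(e) {
                    stop(errorCondition(
                      paste0("cannot parse ", path, ": ", conditionMessage(e)),
                      class = c("bop_parse_error", "error")))
                  })
  if (nrow(raw) == 0L) {
    stop(errorCondition(paste0("empty extraction table: ", path),
                        class = c("bop_parse_error", "error")))
  }

  if (all(c("study_id", "log_rr", "se_log_rr") %in% names(raw))) {
    return(ro_dataset(raw, risk_name = risk_name, outcome_name = outcome_name))
  }

  need <- c("study_id", "estimate", "lower", "upper")
  for (role in need) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      .stop_validation(paste0("required column for role '", role,
                              "' not found in ", path))
    }
  }
  est <- as.numeric(raw[[schema$estimate]])
  lo  <- as.numeric(raw[[schema$lower]])
  hi  <- as.numeric(raw[[schema$upper]])

  bad <- which(is.na(est) | is.na(lo) | is.na(hi))
  if (length(bad)) .stop_validation(paste0(
    "missing estimate or CI bound in row(s): ", paste(bad, collapse = ", ")))
  bad <- which(est <= 0 | lo <= 0)
  if (length(bad)) .stop_validation(paste0(
    "ratio estimates and CI bounds must be > 0; offending row(s): ",
    paste(bad, collapse = ", ")))
  bad <- which(hi <= lo)
  if (length(bad)) .stop_validation(paste0(
    "upper CI bound must exceed lower (zero-width or inverted interval) in row(s): ",
    paste(bad, collapse = ", ")))

  out <- data.frame(
    study_id = as.character(raw[[schema$study_id]]),
    log_rr = log(est),
    se_log_rr = (log(hi) - log(lo)) / (2 * .z95()),
    stringsAsFactors = FALSE
  )
  mcol <- schema$measure
  out$measure_type <- if (!is.null(mcol) && mcol %in% names(raw)) {
    toupper(as.character(raw[[mcol]]))
  } else "RR"
  rcol <- schema$n_repeats
  out$n_repeats <- if (!is.null(rcol) && rcol %in% names(raw)) {
    as.integer(raw[[rcol]])
  } else 1L
  scol <- schema$subgroup_label
  if (!is.null(scol) && scol %in% names(raw)) {
    out$subgroup_label <- as.character(raw[[scol]])
  }
  for (cv in covariate_names(raw)) out[[cv]] <- raw[[cv]]
  ro_dataset(out, risk_name = risk_name, outcome_name = outcome_name)
}

#' Write a dataset in the canonical extraction-table layout
#'
#' Columns are written in fixed order: `study_id`, `log_rr`, `se_log_rr`,
#' `n_repeats`, then covariates sorted by name. Reading the file back with
#' [read_extraction_table()] reproduces the dataset up to floating-point
#' formatting (15 significant digits).
#'
#' @param dataset a `ro_dataset`.
#' @param path output file; comma-separated for `.csv`, tab otherwise.
#' @return `path`, invisibly.
#' @export
write_extraction_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "ro_dataset"))
  cols <- c("study_id", "log_rr", "se_log_rr", "n_repeats",
            sort(covariate_names(dataset)))
  out <- as.data.frame(dataset)[, cols, drop = FALSE]
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inflate standard errors for repeated measurements of one sample
#'
#' When a study contributes several non-mutually-exclusive effect sizes
#' computed on the same sample (for example physical and sexual exposure
#' reported separately on one cohort), each observation's standard error is
#' inflated so the group as a whole does not outweigh a single independent
#' observation. With the default `"sqrt"` rule the SE is multiplied by
#' `sqrt(n_repeats)`, which makes the summed inverse-variance weight of the
#' `k` repeats equal the weight of one unadjusted observation. The `"linear"`
#' rule (SE x `n_repeats`) is stricter and down-weights the group below a
#' single observation.
#'
#' @param dataset a `ro_dataset` (or any data frame with `se_log_rr` and
#'   `n_repeats`).
#' @param method `"sqrt"` (default) or `"linear"`.
#' @return the dataset with adjusted `se_log_rr`; `n_repeats` is preserved
#'   for audit.
#' @export
adjust_se_for_repeats <- function(dataset, method = c("sqrt", "linear")) {
  method <- match.arg(method)
  stopifnot(all(dataset$n_repeats >= 1))
  fac <- switch(method,
                sqrt = sqrt(dataset$n_repeats),
                linear = dataset$n_repeats)
  dataset$se_log_rr <- dataset$se_log_rr * fac
  dataset
}

#' Determine which bias covariates are testable on a dataset
#'
#' A binary bias covariate can only be tested for significance when the data
#' carry information about both of its levels: there must be at least two
#' observations with value 0 and at least two with value 1. The flag is
#' recomputed for the dataset at hand and must never be cached across
#' datasets (subsetting can change it).
#'
#' @param dataset a `ro_dataset`.
#' @param covariates covariate names to assess; defaults to every `cv_`
#'   column. Unknown names are an error.
#' @return data frame with columns `covariate`, `n0`, `n1`, `testable`.
#' @export
derive_testable_covariates <- function(dataset, covariates = covariate_names(dataset)) {
  unknown <- setdiff(covariates, names(dataset))
  if (length(unknown)) {
    .stop_validation(paste0("unknown covariate(s): ", paste(unknown, collapse = ", ")))
  }
  n0 <- vapply(covariates, function(cv) sum(dataset[[cv]] == 0), integer(1))
  n1 <- vapply(covariates, function(cv) sum(dataset[[cv]] == 1), integer(1))
  data.frame(covariate = covariates, n0 = n0, n1 = n1,
             testable = n0 >= 2L & n1 >= 2L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.ro_dataset <- function(x, ...) {
  cat(sprintf("Risk-outcome dataset: %s -> %s\n",
              attr(x, "risk_name"), attr(x, "outcome_name")))
  cat(sprintf("  %d observations from %d studies; covariates: %s\n",
              nrow(x), n_studies(x),
              if (length(covariate_names(x))) {
                paste(covariate_names(x), collapse = ", ")
              } else "none"))
  NextMethod()
}

#' @export
`[.ro_dataset` <- function(x, i, j, drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "risk_name") <- attr(x, "risk_name")
    attr(out, "outcome_name") <- attr(x, "outcome_name")
    class(out) <- c("ro_dataset", "data.frame")
  }
  out
}
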