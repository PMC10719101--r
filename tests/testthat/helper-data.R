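# shared fixtures, built in code

make_dataset <- function(log_rr, se, study = seq_along(log_rr), ...) {
  ro_dataset(data.frame(study_id = as.character(study), log_rr = log_rr,
                        se_log_rr = se, ..., stringsAsFactors = FALSE))
}

# closed-form fixed-effect inverse-variance-weighted mean
ivw_mean <- function(y, se) sum(y / se^2) / sum(1 / se^2)

ivw_var <- function(se) 1 / sum(1 / se^2)

# independent trimming oracle: exhaustive leave-one-out marginal-likelihood
# search (refit on every subset of size n-1, return the index whose removal
# maximizes the likelihood)
loo_trim_oracle <- function(dataset) {
  n <- nrow(dataset)
  ll <- vapply(seq_len(n), function(i) {
    bop_model(dataset[-i, ], trim = 0)$logLik
  }, numeric(1))
  which.max(ll)
}

# write a raw extraction table (ratio + CI layout) to a temp csv
write_raw_extraction <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
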