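Package: bopmeta
Title: Burden-of-Proof Evidence Scoring for Dichotomous Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-regression based evidence scoring for dichotomous risk
    factors: pooled log relative risks with study-level random effects,
    likelihood-based trimming of outlying observations, Lasso-guided
    selection of binary bias covariates, between-study heterogeneity with
    Fisher-information uncertainty, burden-of-proof risk functions (BPRF),
    risk-outcome scores (ROS), star ratings, and Egger's regression
    diagnostics for publication bias. Includes a synthetic evidence-table
    generator with ground truth for recovery testing and a small pipeline
    for per-pair scoring, sensitivity analyses and report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
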