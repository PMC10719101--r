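---
title: "Burden-of-proof evidence scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burden-of-proof evidence scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(bopmeta)
```

## The problem

Classical random-effects meta-analysis reports a pooled relative risk (RR)
and a confidence interval that reflects only the sampling uncertainty of the
pooled mean. When the underlying studies disagree with each other — different
designs, exposure definitions, populations — that interval understates how
little we actually know: a handful of heterogeneous studies can produce a
tight-looking pooled CI around a large effect. Burden-of-proof evidence
scoring asks the opposite question: *what is the most conservative effect
still consistent with the evidence once between-study heterogeneity, and our
uncertainty about that heterogeneity, are priced in?*

`bopmeta` implements that workflow for dichotomous risk factors (exposed vs
unexposed), from an extraction table of study-level effect sizes to a
scored evidence row: pooled RR, uncertainty intervals with and without
heterogeneity, the burden-of-proof risk function (BPRF), the risk–outcome
score (ROS), a 0–5 star rating, and an Egger publication-bias flag.

## The model

Observations are log relative risks $y_{ij}$ (study $i$, observation $j$)
with reported sampling standard errors $\sigma_{ij}$ and binary bias
covariates $x_{ij}$:

$$
y_{ij} = \beta_0 + x_{ij}^\top \beta + u_i + \varepsilon_{ij}, \qquad
u_i \sim N(0, \gamma), \quad \varepsilon_{ij} \sim N(0, \sigma_{ij}^2).
$$

One random intercept is shared by all observations of a study; this is how
within-study correlation between repeated observations is accounted for.
Odds and hazard ratios are ingested as-is on the log scale; when their use
is a systematic source of bias, that is captured by a bias covariate (e.g.
`cv_odds_ratio`) rather than by a transformation, so the correction is
estimated from the data instead of assumed.

Estimation is by maximum *marginal* likelihood (not REML): the trimming
objective and the Fisher-information machinery below both operate on the
marginal likelihood, and mixing criteria would make the trimmed objective
incoherent. Numerically, $\beta$ is profiled out in closed form (GLS via
rank-one Woodbury identities, so a likelihood evaluation is $O(np^2)$) and
the one-dimensional profile in $\gamma$ is minimized by Brent's method on
$[0, \gamma_{\max}]$ with an explicit candidate at the boundary
$\gamma = 0$ and automatic interval expansion if the optimum presses
against $\gamma_{\max}$. A one-dimensional profile search is exactly
equivalent to joint optimization here and has no step-size or
initialization failure modes.

### Heterogeneity uncertainty

$\hat\gamma$ from a handful of studies is itself very noisy, and the method
deliberately propagates that: the standard deviation of $\hat\gamma$ comes
from the Fisher information

$$
I(\gamma) = \tfrac12 \sum_g \operatorname{tr}\!\left[
  \left(V_g^{-1} \tfrac{\partial V_g}{\partial \gamma}\right)^2\right]
  = \tfrac12 \sum_g \left(\mathbf{1}^\top V_g^{-1} \mathbf{1}\right)^2,
$$

where $V_g = D_g + \gamma \mathbf{1}\mathbf{1}^\top$ is study $g$'s marginal
covariance. For $m$ studies of equal information with per-study marginal
variance $v$ this reduces to $\mathrm{sd}(\hat\gamma) = v\sqrt{2/m}$ — the
fewer the studies, the wider everything downstream becomes. When
$\hat\gamma = 0$ the same (one-sided) information is used; no reflection is
applied.

All interval-type quantities then use the 95th quantile of the
heterogeneity estimate,

$$
\gamma^* = \max\!\left(0,\; \hat\gamma + 1.645\,\mathrm{sd}(\hat\gamma)\right),
$$

a normal approximation on the $\gamma$ estimator. The 95% UI *without*
heterogeneity is $\exp(\hat\mu \pm 1.96\sqrt{v_{\text{fixed}}})$ and the UI
*with* heterogeneity is
$\exp(\hat\mu \pm 1.96\sqrt{v_{\text{fixed}} + \gamma^*})$, where $\hat\mu$
and $v_{\text{fixed}}$ are the reference-level prediction and its variance
(below). The same $\gamma^*$ feeds the BPRF, so the printed interval and the
printed score are mutually consistent — a property checked row by row
against the published evidence table in the test suite.

### Trimming

With at least 10 observations, likelihood-based trimming removes the 10%
least self-coherent observations ($n - \lceil 0.9n \rceil$ of them; below
10 observations the fit is untrimmed). The algorithm is iterative hard
thresholding, the standard trimmed-MLE scheme: fit on the retained set,
score *every* observation by its marginal log-density
$N(x^\top\hat\beta,\ \sigma_{ij}^2 + \hat\gamma)$, retain the top
$\lceil 0.9n \rceil$, and repeat to a fixed point (cap 100 iterations). Ties
are broken by retaining the smaller standard error, then input order, which
makes the mask deterministic. On small instances the fixed point is checked
in the tests against an exhaustive leave-one-out likelihood search; the
scheme is a local optimizer in general, which is why the tests also assert
it dominates 200 random subsets of the same size.

### Bias-covariate selection

A covariate is *testable* only when both of its levels carry at least two
observations; testability is recomputed on every dataset (sensitivity
subsets can change it). Selection is a two-stage Lasso strategy at
threshold 0.05:

1. **Entry order.** An L1 path (100 logarithmic $\lambda$ values) is
   computed on the design standardized by the observation SEs — each row of
   $(1, x)$ and the response divided by $\sigma_{ij}$ — with the intercept
   column unpenalized. Candidates are ordered by where they first enter the
   path; never-entering candidates fall back to input order at the end.
2. **Confirmation.** Walking that order, each candidate is added to an
   *unregularized* weighted least-squares refit containing the candidates
   already retained, and kept iff its two-sided Wald z-test (known
   variances, the fixed-effect scale the Lasso itself used) is significant
   at $\alpha = 0.05$.

The procedure is deterministic given the dataset. By default selection runs
on the untrimmed data and only the final fit trims
(`select_on_trimmed = FALSE`): trimming reacts to the covariate set, so
selecting on a mask produced under a different covariate set would couple
the two decisions; the alternative is available as a config switch.
Type-I behaviour of the composite procedure is bounded, not exactly
calibrated (the pre-screening step makes it conservative in some designs
and slightly anti-conservative in others); the suite asserts a ≤10%
null-selection rate rather than 5% equality.

### Reference-level prediction

Selected covariates mark departures from the gold-standard design
(value 0). The reported pooled effect is the model prediction with all
selected covariates at 0 — observations from biased designs are adjusted
toward the gold standard rather than dropped. With no selected covariates
this is simply $(\hat\beta_0, \operatorname{Var}\hat\beta_0)$.

### BPRF, ROS and stars

For a harmful risk, the burden-of-proof risk function is the 5th quantile
of the pooled effect *including* heterogeneity, i.e. the conservative end
of the evidence:

$$
\mathrm{BPRF} = \exp\!\left(\hat\mu - 1.645\sqrt{v_{\text{fixed}} + \gamma^*}\right),
$$

(sign flipped for protective risks — the quantile closest to the null). The
risk–outcome score is $\mathrm{ROS} = \tfrac12 \log(\mathrm{BPRF})$, signed
so that positive means the conservative estimate still indicates an
association. Stars discretize the ROS: 1 star for ROS ≤ 0, 2 for
(0, 0.14], 3 for (0.14, 0.41], 4 for (0.41, 0.62], 5 above 0.62. The bin
edges are treated as belonging to the lower bin, and a ROS printed as 0.00
(or any non-positive value) is one star. A **zero-star** rating is special:
when the 95% UI *without* heterogeneity spans RR = 1 the relationship is
not significant at the 0.05 level, no BPRF or ROS is computed at all
(reports render "N/A"), and the pair is excluded from burden estimation. A
BPRF of 1.63 reads as "at least a 63% increase in risk"
(`excess_risk_percent()`).

### Publication bias

Egger's regression on the model residuals: weighted least squares of the
raw residual (observed minus covariate-adjusted prediction) on the standard
error, weights $1/\sigma^2$, intercept included, two-sided t-test with
$n-2$ degrees of freedom on the slope, flag at $p < 0.05$ (the conventional
threshold, consistent with every other threshold in the pipeline). By
default the test runs on the retained residuals of the trimmed fit — bias
detection after outlier handling — with the untrimmed variant behind a
config switch. When all SEs are identical the slope is undefined and the
result is "not flagged" with an explicit diagnostic. No trim-and-fill or
other correction is applied: the flag is reported, not acted on.

## The synthetic-data generator

`ro_truth()` / `simulate_ro_dataset()` generate evidence tables with
exactly the structure the estimator assumes, plus the ground truth for
recovery tests:

* study effects $u_i \sim N(0,\gamma)$; observation SEs uniform on a
  configurable range, default **0.05–0.5**, spanning the precision spread
  typical of forest plots in this literature and wide enough to produce
  funnel asymmetry when coupled to the mean;
* bias covariates Bernoulli with default prevalence **0.3**, independent
  across covariates — at realistic dataset sizes this keeps covariates
  testable (≥2 observations per level) with high probability;
* outliers as **mean shifts** on a fraction of observations (default 0) —
  the contamination trimming is designed to remove, as opposed to
  variance inflation, which the random-effect term already absorbs;
* optional SE–effect coupling (`egger_slope`) to emulate small-study
  publication bias;
* full determinism from an integer seed, with ensemble seeds derived
  arithmetically so replicates are independent but reproducible.

What it does **not** emulate: correlation between SEs and covariates,
non-normal sampling error, duplicated/overlapping cohorts, or any
individual-level structure (generation starts at the effect-size level,
which is what the pipeline consumes). Passing recovery tests on this
generator therefore demonstrates correctness of the estimator under its own
assumptions, not robustness to real extraction pathologies.

## Data handling choices

* CI → SE conversion assumes a symmetric normal interval on the log scale:
  $\sigma = (\log U - \log L) / (2 \times 1.96)$, using the full width for
  asymmetric reported intervals. Deterministic and standard meta-analytic
  practice.
* Repeated measurements: when a study reports $k$ non-mutually-exclusive
  effect sizes on the same sample, each SE is multiplied by $\sqrt{k}$
  (after CI → SE conversion), so the group's summed inverse-variance weight
  equals that of one independent observation — exactly the "prevent
  overweighting" goal. Multiplying by $k$ instead (available as
  `repeat_adjustment = "linear"`) would shrink the group's joint weight to
  $1/k$ of an observation, over-penalizing it.
* The minimum-evidence gate — at least three distinct studies — is enforced
  at fit time and in the pipeline with a structured refusal naming the rule.
* The theoretical minimum risk exposure level for a dichotomous harmful
  exposure is zero (no exposure); it is carried as configuration metadata,
  not computed.
* No multiplicity correction is applied across risk–outcome pairs; each
  pair is scored independently.

## Defaults that matter

| parameter | default | meaning |
|---|---|---|
| `trim_proportion` | 0.10 | fraction of observations removed by trimming |
| `trim_min_obs` | 10 | observations needed before trimming activates |
| `alpha_selection` | 0.05 | Wald threshold for covariate confirmation |
| `gamma_quantile` | 0.95 | quantile of $\hat\gamma$ in $\gamma^*$ |
| `star_thresholds` | 0, 0.14, 0.41, 0.62 | ROS bin edges |
| `repeat_adjustment` | `"sqrt"` | SE inflation rule for repeated measures |
| se_range (generator) | 0.05–0.5 | sampled observation SEs |
| cov_prevalence (generator) | 0.3 | Bernoulli prevalence of covariate = 1 |

## A worked run

```{r}
truth <- ro_truth(beta0 = log(2.1), gamma = 0.02, n_studies = 12,
                  obs_per_study = c(1, 2), seed = 5)
d <- simulate_ro_dataset(truth)
res <- run_pair(d, bop_config())
res
```

The scoring arithmetic can also be exercised directly on published summary
rows — back-solving the total standard deviation from a printed
heterogeneity-inclusive interval and recomputing BPRF/ROS/stars:

```{r}
head(rescore_published()[, c("outcome", "bprf", "bprf_calc", "ros",
                             "ros_calc", "stars", "stars_calc")])
```

## Verification scale and limitations

The test suite runs recovery at 20 replicates of 50 single-observation
studies, Egger calibration at 150–500 null replicates of 30 observations,
selection calibration at 200 replicates of 30 observations, and trimming
identification on 10-observation tables — sizes chosen to keep the full
suite under a minute while leaving Monte-Carlo margins comfortably wide
relative to the asserted bounds.

Known limitations:

* The trimming fixed point is a local optimum; pathological configurations
  could retain a subtle outlier (gross outliers are the design target).
* $\gamma^*$ rests on a normal approximation to the $\hat\gamma$ sampling
  distribution; with very few studies a profile-likelihood quantile would
  be more faithful but is not what the published arithmetic uses.
* The composite Lasso + Wald selection has bounded, not exact, type-I
  error.
* Dichotomous exposures only: no dose–response (spline) risk curves, and
  no attributable-burden computation downstream of the scores.
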