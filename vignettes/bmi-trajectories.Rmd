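---
title: "Modelling and projecting BMI distributions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and projecting BMI distributions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmitraj)
```

## The model

Adult BMI in a population cell is treated as lognormal: if `B` is BMI in
kg/m², then `log(B) ~ Normal(mu, sigma^2)`. The two parameters play
distinct roles — `mu` fixes the *position* of the distribution (the
median is `exp(mu)`), `sigma` its *shape* (spread and right skew). The
lognormal choice is itself screened in the package: `cullen_frey()`
computes the squared-skewness/kurtosis coordinates used to shortlist
candidate families, and `compare_distributions()` fits lognormal, gamma
and Weibull by maximum likelihood (via fitdistrplus) and ranks them by
the Kolmogorov–Smirnov statistic computed against the fitted
distribution. No small-sample (Lilliefors-style) correction is applied
to the KS statistic: it is used as a relative ranking across families
fitted to the same data, not as a calibrated test.

Survey microdata (`year`, `age`, `sex`, `bmi`) are first filtered to
adults (age ≥ 18) with BMI inside the inclusive bounds [10, 65] kg/m² —
measurement surveys contain occasional implausible values. Ten-year
birth cohorts are then formed: cohort label
`floor((year − age)/10) · 10`, i.e. decade of birth, so the same
individual-equivalent maps to the same cohort in every survey year.
Within each (cohort, year, sex) cell the lognormal parameters are the
closed-form MLE — mean and population-SD (divisor `n`) of log BMI — and
the cell's mean age becomes the age covariate. Cells below `min_cell_n`
records (default 50) are dropped: with fewer records the cell `sigma_hat`
is too noisy to regress on. Cells are sex-specific; sex then enters the
regressions as a covariate of the cell, which is the only reading
consistent with sex appearing as a regression term over cohort
observations.

### Two-step regression

Step one models the position: `mu_hat` regressed on sex, age and
calendar year. Step two models the shape: `sigma_hat` regressed on the
same covariates *plus the position as covariate* (`mu` and optionally
`mu^2` terms). At fitting time the `mu` covariate is the observed cell
`mu_hat` (the only position information available then); at projection
time it is the *predicted* `mu` from step one, which is what lets
predicted changes in spread track predicted changes in location.

### Trend families

Year is always centred at 2003 (`year_c = year − 2003`), keeping trend
coefficients on comparable scales; sex is coded 1 = male, 0 = female.

- **Linear (best case):** ordinary polynomial regression,
  `Y = x1 + x2 year + x3 year² + sex/age terms`. Extrapolated, the year
  quadratic can peak and turn downward.
- **Non-linear (worst case):** `Y = a − b exp(−c year) + sex/age terms`.
  For `c > 0` the year contribution approaches the asymptote `a`:
  growth that slows but never reverses. An estimated `c ≤ 0` (the
  exponential term then grows) is legal — the published shape model for
  England has `b < 0, c < 0` — and is flagged with a warning of class
  `bmitraj_nonflattening` rather than rejected.

### Candidate grammar

The original analysis never enumerates its candidate equation set, so
the grammar here is a reconstruction with two requirements: both
published optimal term sets must be reachable, and the linear list must
be strictly larger than the non-linear one (it carries the year
polynomial and its interactions). The optional pool is every term
appearing in the published optima plus the symmetric completion
`sex:year`, under hierarchy rules — a quadratic requires its linear
term, an interaction requires its components, `mu²` requires `mu`, and
position terms are only legal in shape models. This yields 50 linear /
5 non-linear candidates for `mu` and 150 / 15 for `sigma`
(`enumerate_candidates()`), deterministic and duplicate-free.

## Fitting

Linear candidates are fitted by OLS. The QR solution is polished with
two steps of iterative refinement on the column-equilibrated normal
equations: polynomial designs (an `age²` column of order 10⁴ next to a
unit intercept) are ill-conditioned enough that raw QR carries ~1e−7
coefficient error, and the refined solution is reproducible across
solvers to ~1e−12. Standard errors come from `sigma² (X'X)⁻¹`;
goodness-of-fit statistics follow the usual Gaussian-likelihood
conventions (AIC/BIC count the residual variance as a parameter, the
reported degrees of freedom are the parameter count and `n − k`).

Non-linear candidates are fitted by profiled least squares: for fixed
rate `c` the model is linear in everything else, so the profiled RSS is
a smooth one-dimensional function of `c`. It is minimised over the
bracketing intervals (−0.45, 0) ∪ (0, 0.3) ∪ (0.3, 1.5) — covering
negative rates and the plausible positive range — and the best profile
solution is then polished by damped Gauss–Newton iteration with
step-halving (relative RSS tolerance 1e−12, at most 100 iterations).
This replaces a plain multi-start Levenberg–Marquardt: it is the same
least-squares estimator, but immune to the flat likelihood of the
exponential term and fast enough to sit inside the cross-validation
loop. `|c| < 1e−3` is excluded from the profile search because at
`c = 0` the exponential column is collinear with the intercept; if the
polish drives `b` to 0 the rate becomes unidentified and the covariance
falls back to a pseudo-inverse. Standard errors come from the
Jacobian-based covariance at the optimum, with t-reference p-values on
residual df. Unit tests cross-check the fitter against
`minpack.lm::nlsLM` and against a coarse grid-search oracle.

Regressions are unweighted across cohort observations (matching the
original procedure); `fit_linear(weights = )` exposes count weighting
for sensitivity analysis.

## Model selection

`run_mccv()` repeats, `n_runs = 1000` times by default: draw a random
80/20 split of the cohort rows, fit every candidate on the training
side, score each by RMSE on the test side, record the winner. A failed
fit scores +Inf so the contest continues; a run in which every candidate
fails is void and leaves the denominator. The optimal model
(`select_optimal()`) is the most frequent winner; ties break by fewest
parameters, then lexicographic candidate id (ties are practically
unobserved, but the rule must be deterministic). Splits are simple
random — unstratified, since the regression treats cohort rows
exchangeably. `mu` and `sigma` selections run independently: the shape
candidates consume the *observed* cell `mu_hat`, so neither selection
depends on the other's winner.

## Projection, categories, uncertainty

`project_prevalence()` evaluates the selected model pair at every
(year, sex, single age) cell, converts `(mu, sigma)` to five-category
prevalence by lognormal CDF differences at the cut-points 18.5 / 25 /
30 / 35 kg/m² (categories are left-closed: BMI 25.0 is Overweight), and
aggregates by count-weighted means over a population table — by sex and
eight age groups (18–24 … 85+), by sex, and nationally. The untruncated
lognormal is used even though input data were filtered to [10, 65]: at
realistic parameter values the mass outside those bounds is below 1e−4.
Extrapolated polynomial shape models can go non-positive; predicted
`sigma ≤ 0` is floored at 0.01 with a loud warning. The declared
horizon is 2035; projecting beyond warns.

"At risk" is BMI ≥ 25, the sum of the top three categories.

`project_uncertainty()` propagates parameter uncertainty by resampling:
`n_draws = 1000` coefficient vectors per model from a multivariate
normal at the estimates and covariance, the full aggregated projection
recomputed per draw, the interval being the 2.5/97.5 percentile across
draws. The position and shape models are drawn independently — their
joint covariance does not exist across two separate fits — which makes
the intervals approximate; both the draw mean and the plug-in projection
are reported so the difference is visible. A covariance that is not
positive semi-definite is repaired by clipping negative eigenvalues,
with a warning.

## Validation

Held-out survey years are scored by comparing predicted against
observed category prevalence over (year, sex, age group, category)
cells, all cells weighted equally, pooled into a single MAE (reported on
the proportion and percentage scales) and RMSE. Predicted group
prevalence is aggregated over the held-out sample's own age composition
(`population_from_records()`), so prediction error is not confounded
with age-structure mismatch; empty observed cells are omitted, not
zero-filled.

## The synthetic-data generator

`generator_config()` defines the study conditions: by default 24 survey
years (1991–2014), 8,000 adults per year, ages 18–95, equal sex ratio,
and the published reference coefficient surfaces for England
(`reference_coefficients()`) as generating truth for `mu` and `sigma` —
the shape surface including its `mu`/`mu²` terms, evaluated at the
generating position. That scale yields ~415 cohort-year rows, matching
the residual degrees of freedom of the original cohort dataset (~399
rows). BMI is drawn per record as
`exp(Normal(mu(sex, age, year), sigma(sex, age, year)))`; the exact
surfaces are exposed through `truth_parameters()` for recovery tests.

Ages are sampled uniformly over the range — deliberately not the
English age pyramid, because uniform coverage maximises information per
covariate; a plug-in `age_sampler` hook accepts any other structure.
The generator emulates none of the survey's design features (clustering,
non-response weighting, five-year age banding in later years), so
passing recovery tests demonstrates correctness of the estimation
machinery, not robustness to complex survey designs.

Two inherent features of the cohort procedure are worth knowing when
reading recovery tests. First, a cohort cell spans up to ten single
ages, so the cell SD of log BMI absorbs the within-cell variation of
`mu` across ages, inflating `sigma_hat` age-dependently by ~1e−3 —
about 1.5 standard errors on the shape model's age terms at the default
scale. Second, cell estimates are heteroscedastic (their sampling
variance scales with 1/cell n) while the regressions are unweighted, so
reported standard errors are mildly optimistic. Both effects are
properties of the procedure being modelled, and both were necessarily
present in the original analysis; the package reproduces rather than
corrects them.

`generate_population_weights()` supplies a synthetic stand-in for an
official age/sex population projection: a smooth adult age profile with
a taper after 55, a small seeded per-(sex, age) perturbation, geometric
year-on-year growth. It is labelled synthetic everywhere; projections
aggregated over it are structurally, not numerically, comparable to
published national figures.

## Orchestration and reproducibility

`run_pipeline()` chains simulate → prepare → select → project →
validate, writing each artifact (survey, cohort, ranking and forecast
CSVs, fitted-model JSON, validation JSON) plus a manifest with config
hash and per-stage row counts. One global seed derives per-stage seeds
arithmetically (`derive_seed()`), so a stage rerun from saved artifacts
equals the full run, and identical config + seed gives byte-identical
outputs. Configuration can be supplied as YAML
(`pipeline_config_from_yaml()`); the exported functions are the
intended interface, with `scripts/acceptance.R` as a worked end-to-end
driver.

## Problem sizes used in the shipped checks

The test suite exercises the default study scale (24 × 8,000 records)
for parameter recovery and the candidate-wide OLS oracle; model
selection stability is checked at 1000 vs 2000 cross-validation runs on
a reduced candidate list (optional pool {age², year², sex:age}), and
the end-to-end validation study uses 27 years × 8,000 records with
200 cross-validation runs over the full grammar — enough for stable
selection while keeping a full suite run near one minute. The
acceptance script mirrors the end-to-end study and reports, alongside,
the reference-model projections to 2035.

## Known limitations

- Selection uncertainty is not propagated: intervals condition on the
  selected model pair.
- Independent position/shape coefficient draws understate (or overstate)
  interval width to an unknown degree.
- The one-standard-error selection rule is not implemented; the
  frequency-of-best rule is the only selector.
- Survey design weights are out of scope; all records count equally.
- `reference_model()` objects carry a diagonal covariance (only standard
  errors were published), so uncertainty projections from them ignore
  coefficient correlation — use fitted models for serious intervals.
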