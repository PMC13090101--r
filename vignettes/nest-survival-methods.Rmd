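---
title: "Modelling daily nest survival with interval-censored fates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily nest survival with interval-censored fates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestfate)
```

## The problem

Ground-nesting birds such as the Northern Lapwing (*Vanellus vanellus*) are
monitored in the field by periodic nest visits, sometimes supplemented by
cameras. Apparent nest success (fraction of found nests that hatch) is a
biased estimator of true success, because nests that fail early are less
likely to be found at all. The classical remedy, due to Mayfield and later
formalized as the known-fate daily survival model, is to model the *daily
survival rate* (DSR) — the probability that a nest active at the start of a
day is still active at the next midnight — over the days a nest was actually
under observation.

Each monitored nest is summarised by three dates on a day-of-season scale:
the day it was found with at least one egg ($i$), the last day it was known
to be active ($j$), and the day its fate was confirmed ($k$). Hatched nests
have $j = k$; for failed nests the failure happened on exactly one (unknown)
day in the window $(j, k]$, typically bracketed by a roughly weekly visit
schedule. A nest therefore contributes

$$\ell = \sum_{t=i}^{j-1} \log S_t \;+\;
  \mathbb{1}[\text{failed}]\,
  \log\!\Bigl(1 - \prod_{t=j}^{k-1} S_t\Bigr),
\qquad S_t = \operatorname{logit}^{-1}(x_t'\beta),$$

where $x_t$ holds that day's covariates (weather, possibly lagged one day)
and the nest's grouping factors (region, monitoring method, habitat, year,
clutch-size class). This is an interval-censored failure-time likelihood:
days of confirmed survival enter as Bernoulli successes, and the failure
window enters as the complement of surviving every day in it. `dsr_fit()`
maximizes this likelihood.

## Numerical choices in the fit

* **Raw covariates.** Covariates are not standardized, so coefficients are
  directly interpretable on natural units (logit per m/s of wind, per degree
  C, per mm of rain). The optimizer compensates: L-BFGS-B with an analytic
  gradient and a relative log-likelihood tolerance near 1e-8.
* **Start values.** The intercept starts at the logit of the Mayfield
  estimate $1 - F/E$ (failures over exposure days); all other coefficients
  start at 0. This is deterministic and robust across the model space.
* **Bounds and divergence.** Coefficients are box-bounded at $\pm 25$ on the
  logit scale. Data with no failures push the intercept to $+\infty$; the
  fit then reports `converged = FALSE` with diagnostic `"complete
  survival"`. Any estimate at a bound, optimizer failure, or singular
  observed information is likewise flagged, never silent.
* **Uncertainty.** The covariance is the inverse of the observed
  information, obtained by numerically differentiating the analytic
  gradient at the optimum. Wald intervals on the logit scale feed both
  reporting and the model-selection screen.
* **Failure-day granularity.** Failures are located to whole days only,
  even for camera-monitored nests; a nest "survives a day" if it is still
  active at midnight.
* **Effective sample size.** AICc uses $n = \sum_\text{nests} (k - i)$, the
  total exposure days. The day-level rows of the analysis table are exactly
  these days, so $n$ equals the number of likelihood contributions.

## Model selection

The global model contains five grouping factors, five daily weather
covariates (rain, irradiance, mean soil temperature, mean wind speed, and
the 1-day lags of the last two), day-of-season, and five candidate
interactions. Selection proceeds in the order the field workflow uses:

1. **Collinearity screen** (`screen_collinearity()`): pairwise Pearson $r$
   over all analysis rows; a pair with $|r| > 0.65$ (strictly) drops the
   member lower in a priority list ordered by expected ecological
   relevance.
2. **Enumeration** (`enumerate_models()`): every term subset of the global
   model respecting interaction hierarchy, always including the intercept
   and the null model.
3. **Balance filter** (`balance_filter()`): a candidate is dropped when the
   cross-tabulation of its categorical factors has any cell with $\le 5$
   nests, or a Pearson chi-square test (no continuity correction,
   $\alpha = 0.05$) rejects independence. With three or more factors the
   chi-square rule is applied to every factor pair, since a single test of
   mutual independence of a $k$-way table is not defined by `chisq.test`;
   models with at most one categorical factor face only the small-cell
   rule.
4. **Fitting** of the admissible candidates, sequentially and
   deterministically.
5. **Uninformative-parameter screen** (`informative_screen()`): a candidate
   (other than the null) is excluded when *every* non-intercept
   coefficient's 95% CI overlaps 0. This is the blanket reading of the
   uninformative-parameter rule; the alternative — checking only pairs of
   models that differ by one parameter — is narrower, and we adopt the
   blanket rule because it is the one that determines the final candidate
   set in the workflow this package reproduces. Exclusions are recorded,
   never deleted.
6. **Ranking**: AICc ascending; Akaike weights
   $w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$ renormalized over the
   retained candidates.

## Incubation-period survival

The probability that a hypothetical nest survives a full incubation —
27 days for lapwings — varies with the weather a nest happens to meet, so a
single $\bar S^{27}$ understates the structure. `season_mean_survival()`
computes $\prod_{t=s}^{s+26} S_t$ for every admissible start day $s$ of the
season and averages. `bootstrap_period_survival()` wraps this in a weather
bootstrap:

* **Resampling unit.** Whole observed days (covariate vectors) are resampled
  i.i.d. with replacement within the group, which preserves the joint
  within-day distribution of the covariates. Lag-1 columns are rebuilt from
  the resampled ordering (the first resampled day keeps its own value as its
  lag), so the lagged terms are exercised rather than frozen. Resampling
  nests, or parametric draws of $\beta$, are deliberate non-defaults: the
  estimand here is sensitivity to the weather mix, not sampling error of
  the coefficients.
* **Re-centering.** The bootstrap mean of season-mean window survival
  differs slightly from the value implied by the mean DSR; the difference
  between the expected mean $\bar S^{27}$ (mean predicted DSR over the
  group's observed days, to the 27th power) and the replicate mean is
  subtracted from every replicate. By construction the corrected replicate
  mean equals the expected mean to machine precision, the SE is the
  replicate SD, and the 95% CI is the 2.5–97.5 percentile range. Corrected
  replicates outside $[0, 1]$ are clamped and counted.

## Fate contingency analysis

`fate_table()` cross-tabulates fates (hatched, lost to agriculture,
abandoned, flooded, depredated, unknown failure) over regions or monitoring
methods. The overall test is Fisher's exact test on the full $r \times c$
table; fate-by-fate comparisons collapse each fate against the rest into a
$2 \times 2$, report the conditional maximum-likelihood odds ratio of the
noncentral hypergeometric model (the estimate of an exact 2x2 test; a zero
cell yields the likelihood limit 0 or $\infty$), and Holm-adjust the family
of p-values. These are standard procedures and are delegated to
`stats::fisher.test()` and `stats::p.adjust()`; the test suite cross-checks
both against direct hypergeometric enumeration.

## The synthetic-data generator

Field data cannot be redistributed, so every downstream stage is validated
against a generator that emulates the assumed structure:

* **Weather** (`simulate_weather()`): per region, Gaussian AR(1) series for
  soil temperature, wind and irradiance (wind and irradiance floored at 0),
  Bernoulli–exponential rain, optional linear seasonal trends centred
  mid-season. Defaults encode the observed regional contrasts (soil
  temperature 17.2 vs 15.5 C, wind 0.3 vs 0.6 m/s, 69% wet days with mean
  daily rainfall 2.6 vs 2.2 mm, irradiance 217 vs 223 W/m2). Daily SDs are
  not published at daily resolution; we fixed them once at field-realistic
  values (4 C, 0.10/0.15 m/s, 60 W/m2) — the wind SDs keep the truncation
  at 0 negligible ($\mu/\sigma \ge 3$). $\phi = 0.5$ gives the persistence
  that motivates lagged covariates. Trend defaults are 0: no seasonal
  slopes are published, and the AR(1) already carries the within-season
  structure.
* **Nests** (`simulate_nests()`): initiation uniform over the season (no
  initiation distribution is published; this is a stand-in, not an
  inference), a fixed 27-day incubation, true daily survival from the
  logit-linear model (defaults: the best-supported model's point
  estimates), failure day drawn day by day, discovery after a uniform 0–6
  day lag, visits at gaps of 6/7/8 days (probabilities 0.3/0.6/0.1, median
  7, IQR 6–7), and the censored $i/j/k$ triple read off the visit schedule.
  Hatched nests are confirmed on the hatch day ($j = k$); a later-visit
  confirmation would wrongly credit post-hatch days to the likelihood.
  Failure causes are labels drawn from the observed regional fate mixtures
  and do not feed back into the hazard — a single-hazard simplification.
  In the latent truth table, `failure_day` is the first day the nest is no
  longer active, which makes $i \le j < \text{failure day} \le k$ hold
  exactly for failed nests. Per-nest substreams derive from the master
  seed, so enlarging a scenario leaves earlier nests unchanged.

What the generator does *not* emulate: spatial structure in weather,
renesting after failure, observer effects on the hazard, heterogeneity
among nests beyond the modelled covariates, and cause-specific hazards.
Passing recovery tests therefore show the estimator is correct *under the
model*, not that the model is correct for any particular field system.

* Nests that fail before discovery are redrawn; the likelihood conditions
  on being active at $i$, so this truncation does not bias the fit — a
  property the coverage test verifies directly.

## Problem sizes used in validation

The test suite validates parameter recovery by simulating 100 replicates of
1,000 nests (study cell proportions) and checking that each generating
coefficient falls inside its 95% Wald CI in at least 90% of replicates.
Screening calibration uses 200 replicates of 150 nests; selection-recovery
runs use 600 nests over a 25-model space. These sizes were chosen to put
Monte-Carlo error well below the tolerances being checked while keeping the
suite routinely runnable.

## Known limitations and open accounting

* The published exposure-day totals do not state how the $j \to k$ window
  of failed nests is counted; we use $k - i$ per nest for summaries (all
  days under observation at risk) and the $j/k$ split only inside the
  likelihood. The deposited field data would settle the bookkeeping; the
  package reads them if supplied but does not redistribute them.
* Whether the original analysis fitted raw or standardized covariates is
  not stated; the published coefficient magnitudes are consistent with raw
  units, which is what this package uses.
* No random effects or shared frailty across nests: nests are conditionally
  independent given covariates.
* The odds ratios are point estimates; exact conditional CIs for them are
  out of scope.
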