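---
title: "Measuring household exposure to SSB price promotions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring household exposure to SSB price promotions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

promoscan studies how temporary retail price reductions on sugar-sweetened
beverages (SSBs) relate to how much households buy. The package takes two
kinds of input: a *retailer* side (weekly store-product unit prices) and a
*panel* side (household purchase lines with store, week, product and
volume), links them, derives two household-level annual exposure variables,
and fits adjusted log-linear purchase models. This vignette explains the
model, every tunable that matters, and the design decisions behind the
implementation.

## The exposure model

**Modal prices.** A promotion is a price temporarily *below* the product's
regular price. The regular price at a store is estimated as the modal
price: the most frequently observed weekly unit price of that store-product
over the year. Two decisions hide in this definition:

* The modal window is the full year, not a rolling window. Promotions in
  these data are intermittent, so the regular price dominates the year of
  weekly observations.
* Frequency ties are broken to the *highest* tied price. Promotions
  deflect prices downward, so when two prices are observed equally often
  the upper one is the regular price. A single observation is its own mode.

Prices are stored per fluid ounce (shelf price divided by package ounces),
which makes discounts comparable across package sizes.

**Weekly discounts.** For a store-product-week with observed unit price
$p$ and modal price $m$, the discount is $\max(0, (m - p)/m)$. Weeks priced
above modal are clamped to zero: a price rise is not a negative promotion.

**Store-week magnitude.** Discounts on individual products are combined
into one number per store-week as a weighted mean, with product weights
proportional to the total ounces of each product purchased by the analytic
sample (`weight_scheme = "sample_volume"`). This standardises promotion
magnitude across stores: a deep discount on a rarely bought product counts
less than a modest discount on a popular one. Weights are computed once,
globally, then renormalised within each store-week over the products
actually observed there. If every observed product carries zero sample
weight the products are weighted equally rather than leaving the store-week
undefined. A store-week with *no* price record contributes nothing: missing
is treated as "no information", never as "no discount".

**Household-week exposure.** Each household's weekly exposure aggregates
the store-week magnitudes over the set of covered stores at which the
household bought SSBs at any time during the year (the year-long store
set, not the stores visited that week). Two aggregation modes exist:

* `largest` (the default): the deepest discount on offer among the
  household's stores. This encodes the premise that seeing one large
  discount is a stronger purchase incentive than several small ones.
* `average`: the mean discount across the household's stores, used as a
  sensitivity definition. Because a maximum can never be below a mean over
  the same values, the largest-discount definition dominates the average
  definition week by week, so annual magnitude under `largest` is at least
  that under `average` for every household — the mechanical reason the
  average-mode association is expected to be attenuated.

Weeks in which no store in the set has an observed magnitude score zero, so
every household always has a full 52-week series.

**Annualisation.** With weekly magnitudes $x_1, \dots, x_{52}$ and
promotion threshold $t$ (default $t = 0.05$):

$$\text{frequency} = \frac{\#\{i : x_i \ge t\}}{52}, \qquad
  \text{magnitude} = \frac{1}{52}\sum_{i=1}^{52} x_i.$$

The threshold comparison is inclusive, and the magnitude mean deliberately
includes sub-threshold weeks — the annual magnitude is the average discount
environment, not the average conditional on promotion. The calendar is 52
seven-day bins starting January 1, with the final odd days folded into week
52, so both denominators are always 52.

## Cohort construction

**Coverage filter.** Exposure can only be computed from stores whose prices
are observed. Households qualify when at least 80% of their SSB purchase
volume (by ounces) was bought at covered stores; the comparison is
inclusive at the boundary. The filter is monotone by construction: raising
the threshold can only shrink the retained set. The sensitivity grid probes
60%, 70%, 80% and 90%.

**Outcome.** Annual per-capita purchase: the household's total SSB ounces
over the year — covered *and* uncovered purchases, since the filter
conditions on where volume was bought but does not discard the remainder —
divided by household size. The outcome is right-skewed and is
log-transformed in all models; descriptive tables report medians and
25th–75th percentiles. A 12-oz serving basis (`annual_oz / (12 * 52)`)
converts annual ounces to weekly servings for interpretation.

**Income per capita.** Household income arrives in six brackets; each is
assigned a dollar midpoint (the open top bracket is top-coded at its floor,
$100,000), divided by household size, and cut into four ordered bins at
$15,000, $30,000 and $50,000. Boundary values go to the higher bin; with
the configured midpoints only the $50,000 boundary is actually attainable.

**Quartiles.** Descriptive quartiles are rank-based with groups as equal as
possible; when $n \bmod 4 \ne 0$ the extra members go to the later
quartiles, and ties resolve by stable input order. Splitting 11,299
households therefore yields groups of 2824, 2825, 2825, 2825.

## Regression models

The main model is ordinary least squares:

$$\ln(\text{annual\_oz}_i) = \beta_0 + \beta_1 \cdot s\,E_i +
  \boldsymbol{\gamma}^\top \mathbf{z}_i + \varepsilon_i$$

where $E_i$ is promotion frequency (scale $s = 10$) or magnitude
($s = 100$) and $\mathbf{z}_i$ are dummy-coded covariates: household size
category, income-per-capita bin, male and female head age, education and
occupation, presence of children, race, census division and metropolitan
status. With these scalings $e^{\beta_1}$ reads directly as the
multiplicative change in annual per-capita purchase per 10-percentage-point
increase in frequency, or per 1-point increase in magnitude;
`percent_change()` converts it to $100(e^{\beta_1} - 1)$ percent.

Reference levels are the first listed category of each covariate (e.g.
race "white"); exposure-slope inference is invariant to this choice.
Confidence intervals use classical OLS standard errors — no robust or
clustered variants.

**Structural aliasing.** The age, education and occupation of each head
share an identical "no head" class, so any full dummy coding of the three
is rank-deficient by exactly two columns per sex. The model orders head age
before education and occupation, so the redundancy lands on the
education/occupation "no head" dummies; `fit_main()` recognises aliasing
confined to those columns as structural (their effect is absorbed by the
age variable, as in a generalised-inverse fit) and raises a singular-design
error for any *other* collinearity, naming the offending columns.

**Effect modification.** `fit_interaction()` adds exposure-by-modifier
interaction terms to the same model. Stratum-specific slopes are
reconstructed as $\exp(\beta_1 + \beta_{1\ell})$ with delta-method
confidence intervals from the full covariance matrix, and the interaction
is tested with the extra-sum-of-squares partial F-test of the full
interaction block against the main-effects model (the usual meaning of a
"Type-3" interaction test in this reporting style). Under normal errors
this test is exact, which is what the calibration tests check.

## The synthetic generator

Real household-panel and retail-scanner databases of this kind are
proprietary, so the package ships a seeded generator that emulates the
structure the analysis assumes, making every stage testable end to end.

* **Prices.** Each store-product gets a planted regular unit price (product
  base price in $0.03–0.10 per oz times a store factor in 0.9–1.1). Each
  week, independently with probability `promo_prob`, the price drops by a
  truncated-normal depth. A small fraction of price records
  (`price_missing_prob = 0.02`) is withheld to exercise the
  missing-as-no-information paths.
* **Households.** Demographic categories are sampled from margins that echo
  a large US consumer panel (26.6% single-member households, 83.8% white,
  90.2% metropolitan, and so on), with the structural constraints enforced
  (a head absent in one field is absent in all; every household has at
  least one head; no single-member household has children).
* **Store sets and purchases.** Each household shops at 1–5 covered
  stores; a `coverage_mix` fraction additionally buys a Beta-distributed
  share of volume at an uncovered outlet, so every coverage threshold from
  60% to 90% excludes someone. Annual volume is spread uniformly over
  Poisson-many trip weeks; only annual sums and store identities matter
  downstream, so within-year timing is a free choice.
* **Planted outcome.** $E[\ln(\text{annual\_oz})]$ is the baseline
  intercept plus $\ln(\texttt{beta\_freq\_per10}) \cdot 10 \cdot
  \text{frequency}$, the magnitude analogue, and the configured covariate
  shifts, with normal noise on the log scale — log-normality being the
  natural generating family for a right-skewed outcome handled by log
  transform.

**Truth versus recomputation.** The generator defines the true exposure by
running the exposure machinery against the *planted* regular prices, using
its product-popularity weights. `verify_truth()` then recomputes exposure
from the emitted tables alone — empirical modal prices — and checks
agreement to $10^{-9}$. The two agree whenever the planted regular price is
still the empirical mode, which holds in all realistic regimes: with
variable depths the discounted prices are almost surely distinct, so the
regular price wins any frequency tie (ties break upward), and
constant-depth promotions would need to occupy a majority of weeks to
displace it. The one corner where they diverge — every week promoted at a
constant depth — is exactly the saturated case in which "the regular
price" is no longer identifiable from the data, and the planted definition
is the meaningful one.

**Default calibration.** Defaults were chosen once so the derived
exposures land near the ranges reported for US household panels — mean
annual promotion frequency around 0.44 (SD ≈ 0.24) and magnitude around
0.046 (SD ≈ 0.02), with a per-capita outcome median in the several-hundred
ounce range: `promo_prob = 0.135`, `promo_depth_mean = 0.21`,
`promo_depth_sd = 0.07`, `baseline_log_oz_mean = 5.5`,
`baseline_log_oz_sd = 1.6`, planted `beta_freq_per10 = 1.15`. These are
plausibility anchors, not calibrated claims; individual seeds vary around
them because a dataset has only a few dozen stores.

`simulate_cohort()` is the fast route for Monte-Carlo work on the
inference module: it draws exposures directly from the matched marginal
distributions (frequency $\sim$ Beta(1.49, 1.87), magnitude a Beta-scaled
fraction of frequency) and outcomes from the planted model, skipping the
scanner tables. Parameter-recovery and test-calibration studies use it so
that hundreds of replicate cohorts fit in seconds.

## The study runner and sensitivity grid

`run_study()` evaluates the full grid: promotion thresholds
{2%, 5%, 10%, 15%} × aggregation {largest, average} × coverage
{60%, 70%, 80%, 90%}, always including the main cell (5%, largest, 80%).
Two factorisations keep the grid cheap and internally consistent:

* Store-week and household-week magnitudes do not depend on the threshold,
  so weekly exposure is derived once per aggregation mode and only
  re-annualised per threshold.
* Product volume weights formally depend on the analytic sample, which the
  coverage grid changes; they are computed once from the main-analysis
  sample (coverage 80%) and held fixed across all cells, so each
  sensitivity cell differs from the main analysis only in the parameter
  being probed.

Cell failures (for example, a dataset with no exposure variance) are
recorded per cell and do not abort the grid. No multiplicity adjustment is
applied across cells. `sensitivity_report()` pairs the two aggregation
modes and flags whether the average-mode estimate is attenuated relative
to the largest-mode estimate; the flag is reported, not asserted, because
the per-household dominance of exposures does not force the same ordering
on noisy regression estimates in every sample.

## Numerical choices and degenerate inputs

* Modal-price ties break to the highest tied price; discounts clamp at 0.
* Missing store-weeks carry no information; household-weeks with no
  information score 0, keeping denominators at 52.
* Quartile ties resolve by stable input order; group sizes are later-heavy.
* Income-per-capita boundary values go to the higher bin.
* Exact floating-point comparisons in tests allow $10^{-12}$ slack where
  associativity of summation differs between the pipeline and a
  brute-force oracle.
* Households with zero covered purchases cannot be scored for exposure and
  fail the inclusion filter upstream; an empty store set passed directly
  to the exposure functions is a contract violation.
* A constant exposure column makes the design singular; the fit reports it
  as such rather than returning a degenerate estimate.

## What the tests do and do not show

The test suite checks, among other things: exact agreement of the exposure
pipeline with an independent brute-force enumeration on hundreds of small
random instances; unbiased recovery of a planted frequency effect
(200 replicate cohorts of n = 10,000) with confidence-interval coverage
near the nominal 95%; correct size of the interaction F-test under equal
stratum slopes (200 replicates); per-household dominance of the
largest-discount definition; and monotonicity of the coverage filter.
Simulation sizes were chosen so the full suite runs in a couple of minutes
on one CPU.

Passing these tests shows that the pipeline computes its definitions
correctly and that the estimator behaves as OLS theory predicts when the
generating model is true. It does not validate the substantive
assumptions on real scanner data: the generator has no within-year
seasonality, no stockpiling dynamics, no store-choice behaviour, no
correlation between promotion depth and demand shocks, no survey
projection weights, and independent promotion draws across stores and
weeks. Conclusions about real households require the real linked panel.

## Known limitations

* The week calendar is a fixed 52-bin convention; no attempt is made to
  reproduce any proprietary retail week definition.
* Promotion detection is purely price-based; feature/display promotions
  and manufacturer coupons are out of scope.
* The outcome is purchase volume, not consumption; purchases from
  restaurants, vending machines and other away-from-home outlets are
  invisible to panels of this kind.
* The cross-sectional design supports association, not causal claims
  about restricting promotions.
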