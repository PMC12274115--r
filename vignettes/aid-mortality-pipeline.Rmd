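---
title: "Estimating and forecasting the mortality impact of development-aid funding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and forecasting the mortality impact of development-aid funding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `aidmort`, the
design decisions embedded in its defaults, what the synthetic-data
generator does and does not emulate, and the package's known
limitations.

## The scientific problem

Development-aid disbursements are concentrated in low- and
middle-income countries whose mortality has been falling for two
decades. The question the pipeline addresses is dose-response: do
country-years with higher per-capita funding show lower all-cause,
age-specific and cause-specific mortality than comparable country-years
with little or none, after absorbing stable country traits and common
time shocks? And, taking the fitted dose-response at face value, how
many deaths would an abrupt defunding add by 2030?

The design is longitudinal and ecological: the unit is the
country-year, outcomes are age-standardised rates taken as inputs (the
package does not perform age standardisation), and inference is at the
country level.

## Retrospective model

For country $i$, year $t$, outcome deaths $Y_{it}$ with denominator
$N_{it}$ (population; live births for under-five outcomes):

$$E[Y_{it}]=\exp\!\big(\alpha_i+\gamma_t+\beta_{c(i,t)}+\delta'Z_{it}\big)\,N_{it}/1000 .$$

* **Exposure bands** $c(i,t)$: per-capita funding categorised at cut
  points $1.97/3.97/7.10$ USD — the quartiles of the distribution in
  low-income countries. Intervals are half-open with the cut at the
  lower edge of the upper band: a 2-dp value of 1.96 is baseline, 1.97
  is low. `quartile_thresholds()` re-estimates cuts from data using
  linear interpolation between order statistics (type-7 percentile; the
  definition is recorded in the scheme's metadata so alternatives can
  be compared). Categorisation is monotone and total on non-negative
  inputs.
* **Covariates** $Z_{it}$: each continuous covariate (Gini index,
  sanitation and water access, education and health and military
  expenditure, nurses and hospital beds per 1000, ...) is replaced by
  the indicator `value > pooled median`, the median taken once over
  every country-year of the study window. The tie rule is strict
  (a value equal to the median maps to 0), which is deterministic and
  balanced for symmetric data. Dichotomization is idempotent, and
  frozen medians can be re-applied to future records.
* **Time controls** $\gamma_t$: the default is four shock-period
  dummies (2008–09, 2013–14, 2015–16, 2020–21); an alternative
  single-year set (2007–08, 2015, 2020, 2021) and a full year-dummy
  specification are selectable in `model_spec()`. The validation
  studies below use the year-dummy form — see *Time controls and
  specification*.
* **Family**: quasi-Poisson. Outcomes supplied as age-standardised
  rates become pseudo-counts (rate × denominator / 1000), which are
  generally non-integer; the Poisson score equations remain
  well-defined and all inference is based on the robust variance, so
  the likelihood is used as a quasi-likelihood. A negative-binomial
  variant estimates a dispersion parameter by maximum likelihood for
  sensitivity comparison. Population weighting (analytic weights on
  the score contributions, normalised to mean 1) is available.

Two estimation engines are provided and must agree: country-intercept
dummy columns solved by IRLS, and a profile ("within") Newton solver
that concentrates the country intercepts out analytically
($e^{\alpha_i}=\sum_t w y/\sum_t w\,\text{offset}\,e^{x'\beta}$). The
equivalence is asserted to $10^{-6}$ in the test suite. IRLS uses a
relative tolerance of $10^{-8}$ with at most 100 iterations; countries
whose outcome is zero in every year contribute nothing to the
fixed-effects likelihood and are dropped with a logged count; design
columns with no within-country variation are absorbed by the country
intercepts and are likewise dropped and logged, while genuine
cross-column collinearity raises an error naming the aliased columns.

**Variance.** `cluster_vcov()` is the sandwich $A^{-1}BA^{-1}$ with
$A$ the observed information and $B$ the outer product of
within-country summed scores, times $G/(G-1)$. Clustering defaults to
country because exposure and residuals are serially dependent within
countries; observation-level (HC) clustering is available for
comparison and is anti-conservative on panels. Wald rate-ratio tables
use normal quantiles.

## Attribution

"Setting funding to zero" is interpreted as assigning every
country-year to the unexposed baseline band while keeping all other
variables fixed — the exposure indicators are zeroed in the design, and
nothing else changes. The averted total is
$\sum(\hat\mu^{cf}-\hat\mu)$; because the fixed-effects Poisson score
equations force $\sum_t\hat\mu_{it}=\sum_t Y_{it}$ per country, the
predicted observed total equals the actual observed total, and the
prevented fraction $(\text{cf}-\text{obs})/\text{cf}$ equals
$1-\sum\hat\mu/\sum\hat\mu^{cf}$ exactly. The reported "percentage of
deaths averted relative to total deaths" uses
averted/(observed + averted), which coincides with the prevented
fraction; a version with observed deaths in the denominator is
selectable.

Uncertainty propagates by drawing coefficient vectors from
$\mathrm{MVN}(\hat\beta,\hat V_{cluster})$ — the standard asymptotic
choice; the draw law is recorded in the result. The default draws the
full modelled block (exposure, covariate and time coefficients);
country intercepts are treated as fixed nuisance parameters, and an
exposure-only mode is provided. Intervals are 2.5/97.5 percentiles of
the draw distribution, deterministic given the seed.

## Forecasting

Stage one builds a synthetic cohort for 2024–2030: every covariate,
denominator and the population of each country is extrapolated by a
linear trend fitted on a transformed scale (logit for proportions, log
for strictly positive series, identity otherwise) over the most recent
10 observed years, back-transformed and clipped to the admissible
range. Covariates are then dichotomized with the *retrospective*
medians, and exposure uses the *retrospective* cut points — both
frozen. The reference funding level is the last observed year.

Stage two applies scenarios as per-year multipliers on the reference
funding: business-as-usual ($m_t=1$) versus defunding ($m_{2025}=0.17$
for the 83% cut, $m_t=0$ from 2026). For each of the (default 1000)
Monte-Carlo draws a single coefficient vector is shared across both
scenarios (common random numbers), so excess-death intervals reflect
the scenario contrast rather than independent sampling noise. Country
intercepts and fitted time-control levels are carried forward
unchanged — with year dummies, the last observed year's coefficient is
held; no recalibration to post-window mortality is attempted. Reported
rows cover 2025–2030 with a cumulative row that is, per draw, exactly
the sum of the annual rows. The whole-calendar-year multiplier is a
simplification: no mid-year cut timing is modelled.

A note on the defunding path: an 83% cut applied to the high-band mean
reference of \$20.45 gives \$3.48, which falls in the *low* band under
the default cuts (the low/intermediate boundary is \$3.97).

## Triangulation

The matched difference-in-differences compares countries with low
coverage against medium/high coverage (country mean per-capita funding
at or above the low/intermediate cut — the operational definition,
since "coverage" is not otherwise defined) between a pre year (2001)
and a post year (2021). Propensity scores come from a logistic model
on baseline covariates; matching is greedy 1:1 nearest-neighbour on the
logit score without replacement, caliper 0.2 SD of the logit scores,
treated units processed in descending score order and ties broken by
id — all standard defaults, all recorded in the result. The double
difference is taken on log rates so the exponentiated effect aligns
with the Poisson log link; its SE comes from the pair-level
distribution. The negative-control harness refits the primary model on
injury mortality and reports PASS only when every exposure-band CI
covers 1.

## The synthetic-data generator

`generate_panel()` draws panels from exactly the model class the
estimator assumes, so recovery failures indict the estimator, not the
fixture. Defaults define the study conditions: 133 countries
(20/40/40% low / lower-middle / upper-middle income), years 2001–2023,
true high-band rate ratios 0.85 (all-age), 0.68 (under-five), 0.35
(HIV) and 1.0 (injuries, the built-in negative control), country
log-rate heterogeneity SD 0.35, secular declines matching observed
2001–2021 changes (e.g. −13% all-age, −49% under-five), +3% mortality
in shock periods, and covariate paths drifting between the observed
2001 and 2021 cross-country means with AR(1) noise on a transformed
scale.

Funding is a zero-inflated lognormal: a never-funded point mass plus a
persistent country level and AR(1) year noise (85% of the log variance
at the country level). Its three parameters are solved exactly so the
low-income quartiles equal the canonical cuts (1.97, 3.97, 7.10); the
solved zero mass is ≈13%. Middle-income groups get scaled-down funding
and larger zero mass. Two deliberate design choices matter for
interpretation:

* the funding process is *time-stationary* by default (no drift), so
  the exposure is orthogonal to the secular mortality trend and
  parameter-recovery results measure estimator behaviour rather than a
  trend confound; observed real-world funding drifted upward, and a
  drift is available via `funding_drift`;
* covariate effects act on `indicator(value > realized pooled
  median)` — the same rule the analysis applies — so the estimating
  model is correctly specified. An earlier variant using a theoretical
  threshold left systematic residuals that scale with country size and
  visibly degraded sandwich coverage; the present rule is the faithful
  rendering of "the generator encodes the model class".

The generator does **not** emulate: real country identities or actual
disbursement series, migration or age-structure dynamics (rates are
simulated directly), reporting error in mortality estimates,
cross-country spillovers, or funding responding to mortality (no
reverse causation unless `confounding_strength` is set, which ties
country intercepts to funding levels for the triangulation fixtures).
Passing tests therefore demonstrate statistical correctness of the
machinery under the assumed model, not the substantive validity of any
real-world estimate. Both Poisson and negative-binomial count
generation are provided, since the dispersion of real burden-derived
counts is not established.

## Time controls and specification

The default time control is the shock-dummy set, mirroring the
published retrospective specification. The generator's world, however,
contains a smooth secular decline that shock dummies do not span; a
quasi-Poisson fit then carries systematic residuals proportional to
country size, which point estimates tolerate (exposure is stationary,
and recovery stays unbiased) but interval coverage does not. The
validation studies — parameter recovery, null coverage,
negative-control power, and `scripts/acceptance.R` — therefore fit with
`time_controls = "year"` (two-way fixed effects), which nests the
generating process. Users analysing data with a secular outcome trend
should do the same or add trend terms.

## Numerical choices

* Percentiles: linear interpolation between order statistics (type 7)
  everywhere — quartile cuts and all Monte-Carlo interval endpoints.
* Band boundaries: half-open, value < cut → lower band, reproducing
  the printed 2-dp band memberships ($0–1.96 baseline, 1.97–3.96 low,
  ...).
* Median ties: strict `>`.
* IRLS: relative tolerance $10^{-8}$, max 100 iterations; the within
  Newton solver uses step halving with the same budget.
* Negative binomial: alternation of IRLS with `theta.ml`, capped at
  $\theta=10^6$ (the Poisson boundary).
* All generator and Monte-Carlo randomness flows through a single seed
  per call; results are byte-identical across runs with equal seeds.
* Missing modelled covariate cells are dropped (no imputation) with a
  logged count.

## Validation problem sizes

The shipped suite validates at these scales, chosen to exercise the
study geometry while keeping the suite quick: parameter recovery and
interval coverage on 100 replicate 133 × 21 panels (mean recovered
high-band RRs within ±0.08 of 0.85 / 0.68; measured coverage 92–94%);
null-effect coverage on 50 replicate 200-country panels;
law-of-large-numbers checks on a 2000-country panel; Monte-Carlo
attribution coverage on 40 replicate 40-country panels; and exact
closed-form oracles (2 × 2 ratio-of-ratios, matched DiD equivalence,
3-country forecast arithmetic) at trivial sizes.

## Known limitations

* **Few effective clusters.** Country populations are heavy-tailed, so
  a handful of large countries dominates the sandwich meat; measured
  CI coverage at the study geometry sits at the low end of nominal
  (92–94%). This is a documented property of cluster-robust inference
  with unbalanced cluster information, and it is why the spread of the
  null-coverage acceptance band reaches down to 90%.
* **Ecological design.** Estimates are country-level associations;
  individual-level conclusions do not follow.
* **Scenario realism.** The defunding path is a stylised multiplier on
  the last observed funding level; programme composition, mid-year
  timing and exogenous shocks (conflict, pandemics) are out of scope,
  so scenario *contrasts* are more trustworthy than absolute levels.
* **No uncertainty from band estimation.** Exposure-cut estimation and
  median dichotomization are treated as fixed when propagating
  uncertainty.
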