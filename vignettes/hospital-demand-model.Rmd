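---
title: "Methods: panel mixed models and scenario projection for county hospital demand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel mixed models and scenario projection for county hospital demand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`hospanel` analyses a balanced county-week panel: every county is
observed at the same consecutive weeks. Four dependent variables are
modelled separately — COVID and non-COVID hospital beds in use, and
COVID and non-COVID ICU beds in use — each transformed to
`y = ln(1 + 100000 * count / population)`. The `1 +` offset keeps zero
counts at exactly 0 on the log scale and makes the transform invertible
(`exp(y) - 1`); it matters for small counties where weekly counts touch
zero.

For county $z$ and week $t$,

$$y_{zt} = \beta' x_{zt} + \varepsilon_{zt},$$

with jointly normal within-county errors whose covariance has the
repeated-measures ARMA structure

$$\Omega_{st} = \sigma^2 \,\phi\, \rho^{|s-t|} \ (s \neq t), \qquad
  \Omega_{tt} = \sigma^2.$$

`phi` (common correlation factor) sets the level of correlation shared
by all pairs of weeks; `rho` (dampening parameter) shrinks it with the
gap between weeks; `sigma2` is the error variance in squared log-rate
units. Note the lag-$k$ correlation is $\phi\rho^{k}$ — the *first*
off-diagonal is $\phi\rho$ — which differs from the common ARMA(1,1)
convention $\phi\rho^{k-1}$. The two families coincide under
$\phi' = \phi\rho$, so this is a pure parameterization choice; we
implement the form above throughout and report parameters in it.

A consequence worth knowing: at independence the two correlation
parameters are not separately identified ($\phi\rho^k \equiv 0$ for any
$\phi$ when $\rho = 0$, and for any $\rho$ when $\phi = 0$). Away from
zero both are well identified. Tests of independence-recovery therefore
check the estimable lag-$k$ correlations, not the raw parameters.

## Covariates

`add_panel_features()` derives every model covariate from the raw
panel:

* case rate per 100 residents, with lags of 1–3 weeks (hospitalization
  responds to transmission with a one-to-two-week delay);
* the mean of the three *preceding* weeks of the case rate (3-week
  moving average), the percentage difference of the current week from
  it, and an indicator for the current week exceeding it. The
  percentage difference is bounded below by −1; when the moving average
  is zero but the current value positive, the feature falls back to the
  raw value over a floor of one unit (configurable) and warns — the
  quantity is otherwise undefined;
* log daily-average mobility exposure with 2- and 3-week lags;
* temporal indicators switching on 2020-10-30 (second-wave onset) and
  2020-12-25 (holiday acceleration), both configurable dates;
* four-level region dummies (West, MidWest, NorthEast, South) and
  interactions written `"a:b"` (elementwise products).

Rows lost to lags are dropped rather than imputed: fitting uses weeks
`max_lag + 1 .. T`, which keeps the panel balanced — the property that
lets all counties share a single `T_eff x T_eff` covariance. The preset
COVID layouts need 3 weeks of history (`T_eff = T - 3`); the non-COVID
layouts need 2.

## REML estimation

`fit_reml()` maximizes the restricted likelihood

$$\ell = -\tfrac12\Big[(N-p)\ln 2\pi + Z\ln|\Omega|
  + \ln\Big|\sum_z X_z'\Omega^{-1}X_z\Big|
  + \sum_z r_z'\Omega^{-1}r_z\Big],$$

with $r_z$ the GLS residuals. Numerical design:

* **Profiling.** At fixed $(\phi, \rho)$ the optimal error variance is
  available in closed form, $\hat\sigma^2 = \mathrm{RSS}_C/(N-p)$ with
  $\mathrm{RSS}_C$ the whitened residual sum of squares at unit
  variance. The search therefore runs over $(\phi, \rho)$ only, on the
  unconstrained `atanh` scale. This is the standard device in mixed-model
  software and removes one badly-scaled direction from the search.
* **Multistarts.** Three deterministic starts —
  $(\phi,\rho) \in \{(0.3,0.5), (0.7,0.9), (0.9,0.97)\}$ — each run
  through Nelder–Mead (relative tolerance `1e-10`, up to 500
  iterations) and polished by BFGS. The best value wins; the
  convergence flag reflects the winning start's optimizer status.
* **Positive definiteness.** The correlation matrix is PD for
  $\phi \in [0, 1)$, $|\rho| < 1$, but not everywhere in the square; a
  failed Cholesky factorization returns a large penalty, so the search
  simply cannot enter the invalid region.
* **Cost.** One likelihood evaluation factorizes the shared
  `T_eff x T_eff` matrix once and whitens the stacked design by
  reshaping each column to a `T_eff x Z` matrix — O(T³ + Z·T²·p), never
  O((ZT)³). A full 1,765-county fit takes seconds per evaluation
  and under half a minute end to end on one CPU.
* **Inference.** `t = beta / SE` with large-sample normal reference:
  at N ≈ 32,000 rows, small-sample degrees-of-freedom corrections are
  immaterial.

The likelihood implementation is verified against an independent dense
oracle (explicit block-diagonal covariance, direct determinants) on
randomized small instances to `1e-8`, and the `phi = 0` special case
against an ordinary linear model fit to `1e-6`.

## The synthetic-data generator

`generate_panel()` produces panels with exactly the statistical
structure the estimator assumes, so that parameter recovery has known
ground truth. The defaults emulate the study conditions the package
ships as reference estimates: 1,765 counties × 21 weeks beginning
2020-08-28; static covariates drawn from scaled-beta distributions
matched to the default min/mean/max ranges (on the log scale where the
model uses logs); region proportions 12.0/10.8/30.8/46.4%; a two-wave
weekly case process (Gaussian-shaped surges peaking around weeks 12 and
20, multiplicative county severity, AR(1) noise, hard cap at 4.56 cases
per 100); log mobility inside the [2.319, 6.841] envelope with a
late-December spike; log-normal county populations (median 110k,
clamped to [20k, 5M]). Outcomes are drawn per county as
`y = X beta + eps` with `eps` from the triangular factor of the target
covariance, then back-transformed to integer bed counts.

Two generator-design decisions deserve emphasis:

* **Censoring is kept rare by construction.** The estimation model has
  no censoring component, but counts are physically bounded: they
  cannot be negative and cannot exceed capacity. With error variances
  near 1.4–1.9 the log-scale tails span two orders of magnitude, so a
  generator calibrated to sit near the zero floor, or given capacities
  at typical per-resident levels, would floor- or capacity-censor
  several percent of county-weeks — visibly attenuating the case-rate
  coefficient and biasing the variance parameters. The defaults
  therefore place the hospitalization linear predictors well above
  zero (case-rate mean near 2 per 100), and capacities are finalized as
  the maximum of a heavy-tailed per-100k draw and a generous headroom
  over the county's expected peak demand (its upper demand quantile at
  2.9 error SDs, times a log-normal jitter). Residual clip events are
  counted in the panel's `clip_log` attribute and sit around 0.1% at
  the defaults. The cost of this choice is descriptive: synthetic
  occupancies are low (a few percent) and the simulated outcome means
  sit higher than the real data the structure emulates, where the
  observed minimum of 0 shows genuine floor-sitting. Passing recovery
  tests on these panels demonstrates the estimator is correct under its
  own assumptions — not that real, floor-censored data are free of
  attenuation.
* **ICU truths.** No reference ICU coefficients ship with the package,
  so the ICU outcomes default to the hospitalization coefficient
  vectors with intercepts shifted down by the observed gaps between
  ICU and hospitalization outcome means (−1.183 and −2.533), landing
  simulated ICU levels on the right scale. Both are plain config
  entries and can be overridden. ICU linear predictors sit closer to
  the floor (as in reality), so ICU parameter recovery is looser than
  for the bed outcomes.

The generator does not emulate reporting artifacts of real
administrative data — late corrections, suppression of small counts,
facility-to-county allocation error — nor spatial spillovers between
counties. Green tests here say nothing about those features.

## Scenarios and forecasting

Scenario trajectories are deterministic positive multipliers `m(t)`
applied to each county's reference case level (the mean of its last
three observed weeks — a smoother anchor than the single final week):

| kind | shape | defaults |
|------|-------|----------|
| PV | `1 + a sin(2 pi t / p)` | amplitude 0.35, period 8 |
| UP | ramp to gain `g` at week `s`, then `1 + (g-1) d^(t-s)` | s = 6, g = 2.5, d = 0.85 |
| SB | `max(f, d^t)` | d = 0.93, floor 0.1 |
| RV | `d^t` | d = 2^(-1/3) (3-week half-life) |

The shapes are the simplest curves matching the qualitative scenario
descriptions (repetitive waves; an early-spring spike then vaccination-
driven decay; slow decline; fast decline); every parameter is exposed.

`forecast_demand()` extends the case series, holds mobility at each
county's trailing 3-week profile (one fixed profile across scenarios,
so differences isolate transmission), keeps static covariates fixed,
recomputes all lagged and moving-average features on the extended
series, and predicts the marginal mean `X beta` back-transformed as
`exp(y) - 1`. Conventions, each deliberate:

* predictions are *marginal* — observed residuals are not propagated
  through the error correlation; an optional log-normal mean correction
  `exp(sigma2/2)` exists but is off by default, since point projections
  are the intended output;
* the first two horizon weeks inherit the raw observed lag values, so
  they can be volatile where the final observed weeks were (that is the
  information actually available at the forecast origin); from week 3
  the scenario series feeds the lags;
* forecast weeks are labelled from 2021-03-05 by default (configurable
  start); both temporal indicators are on throughout a 2021 horizon;
* predicted counts are *not* capacity-capped — demand overruns are the
  object of interest;
* a horizon of 0 returns in-sample fitted values for the final observed
  week, which pins the forecasting path to the fitting path in tests.

## Capacity stress

`occupancy_metrics()` computes, per county-week, bed and ICU occupancy
(occupied / capacity) and the COVID share *of occupied beds* — the
share-of-patients reading; a share-of-capacity alternative can be had
by passing capacities as the denominator columns. Stress flags use
inclusive thresholds (at least 90% occupancy, at least 25% COVID
share), both configurable. `aggregate_capacity()` pools counts and
capacities within state/region/nation before re-forming ratios — a
capacity-weighted rollup, not an average of county fractions — so the
national number equals the capacity-weighted mean of county
occupancies exactly (tested as an identity), and flag columns become
fractions of member counties flagged. All 1,765 synthetic counties
enter every denominator (no restriction to counties with ICUs).

## Problem sizes in the test suite

Unit tests run on hand-built 3–4 county panels and generated panels of
40–150 counties over 14 weeks (short windows start 2020-10-02 so both
temporal cuts fall inside). Recovery tests run at the full study
dimensions, 1,765 × 21, where the covariance parameters are estimated
to two to three decimals; oracle-equivalence tests use 50 randomized
instances with at most 6 counties and 5 weeks; generator-fidelity tests
compare the empirical error covariance of 10,000 simulated counties at
T = 3 to its target within three Monte-Carlo standard errors.

## Known limitations

* Ingestion of the real hospitalization/case/mobility feeds is out of
  scope; the panel CSV schema is the interface.
* No unbalanced-panel likelihood: incomplete counties are dropped (a
  documented completion policy), not modelled.
* No random intercepts/slopes beyond the residual ARMA structure, no
  spatial spillover terms, no vaccination covariate.
* Scenario multipliers are exogenous: there is no epidemic dynamics
  model linking cases, mobility and immunity.
* The floor at `y = 0` is real in the data this structure emulates but
  absent from the estimation model; see the generator notes above for
  what that implies about recovery versus real-data bias.
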