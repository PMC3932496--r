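---
title: "Individual relative survival: model, transformation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual relative survival: model, transformation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexisurv)
```

## The problem

Cohorts recruited over several years, spanning entry ages from under
20 to over 70, and followed for decades cannot be analysed sensibly on
the raw follow-up time axis: a year of follow-up means something very
different to a 25-year-old in 1966 and a 70-year-old in 1970, and
background mortality itself fell substantially over the follow-up
period. Individual relative survival removes both effects *per
subject* before any regression is fitted.

## The transformation

Each subject is a point moving along a 45° diagonal of the Lexis
diagram: entering at exact age $a_0$ on calendar date $y_0$ (decimal
years), after $u$ years of follow-up they are aged $a_0+u$ in year
$y_0+u$. Given a reference life table of sex-specific central
mortality rates $\mu(s, a, y)$ on a single-year-of-age ×
single-calendar-year grid, the expected cumulative hazard is

$$\Lambda^*(t) = \int_0^t \mu(s,\; a_0+u,\; y_0+u)\, du,$$

and the two individual relative-survival measures are $Z =
\Lambda^*(t_{obs})$ and $Y = 1-\exp(-Z)$, with the death/censoring
indicator carried through unchanged. If the subject dies exactly at
reference-population rates, $Z\sim\mathrm{Exp}(1)$ and
$Y\sim\mathrm{U}(0,1)$ — the probability integral transform. This is
the package's central identity and the basis of its null-calibration
test.

**Numerical convention.** The hazard is taken piecewise constant on
each 1-year-age × 1-calendar-year Lexis cell, so a subject's hazard
changes on their (fractional) birthday and at new year and
$\Lambda^*$ is continuous, non-decreasing and *piecewise linear* —
exactly integrable and exactly invertible, which the compiled
integrator exploits (segment walking, no quadrature error). The
inverse map $\Lambda^{*-1}$ is what turns model-scale quantiles back
into ages at death. Dates are decimal years on a 365.25-day year;
cohort files giving integer entry ages are interpreted as mid-year
($a_0 + 0.5$), unbiased under uniform birthdays.

**Extrapolation.** Predictions can require rates outside the grid
(e.g. an anchor date one year before the first rate year, or 95th
percentiles past age 100). Calendar years off the grid reuse the
nearest edge column; ages above the top are extended log-linearly in
age (a Gompertz tail fitted to the top 10 ages of each column),
capped at 1 death per person-year, up to age 130. The ceiling is a
hard boundary: an inversion that would pass it *saturates* and is
flagged, never silently capped. All of this is configurable and can
be disabled, in which case off-grid queries are errors naming the
missing cell.

**Follow-up frame.** Analysis is of mortality before age 90: exits
beyond attained age 90 (deaths after 90, late embarkations) are
censored at exactly 90 with the event indicator forced to zero. In
cause-specific runs, deaths from other causes are treated as censored
at the death time and the transformation uses the cause-specific rate
table; this cause-specific-hazard convention is the one that keeps the
Cox partial likelihood well defined, and is a declared choice — the
competing-risk convention is genuinely open in this design.

## Regression models

The transformed times are modelled by proportional hazards. Cox
regression depends on the time axis only through ranks, and $Z = -
\log(1-Y)$ is strictly increasing, so Y-scale and Z-scale fits give
identical coefficients (asserted to $10^{-8}$ in the tests). The
Z scale additionally supports the parametric Weibull PH model
$h(z\mid x) = k\lambda z^{k-1} e^{x'\beta}$, fitted by maximum
likelihood through the accelerated-failure-time parameterisation and
re-expressed in PH form ($k=1/\sigma$, $\beta=-\gamma/\sigma$,
$\log\lambda=-\mu/\sigma$) with a delta-method covariance, so its
$\exp(\beta)$ are directly comparable with the Cox hazard ratios. With
$k$ fixed at 1 it reduces to the exponential model; under the
generative model below, truth is $k=1$, and the fitted shape hovering
near 1 is itself a specification check. Ties are handled by the Efron
approximation by default (transformed times are continuous, so ties
arise only from file rounding); Breslow is selectable. Confidence
intervals are Wald on the log scale throughout.

### The interaction parameterisation

The design matrix carries smoking-grade indicators (reference: never
smoked), a female indicator, and the gender × grade products. The
exponentiated interaction coefficient for a grade *is* the female
to-male, smoker-to-never relative risk ratio for that grade: with
4 RRRs (light, medium, heavy, former) for event-rich analyses, or
3 RRRs with medium and heavy pooled *before* forming interactions for
sparse cause-specific analyses. Confounder sets: full (byssinosis,
cough & phlegm, decades in industry, and the two lung-function
covariates), no-lung (lung function is itself smoking-affected, so
dropping it is the natural sensitivity analysis), or none. Log-height
can be added as an allometric size covariate.

The FEV1 % predicted covariate is scored as $(100 - \text{FEV1\%})/10$
so its hazard ratio reads per 10% reduction. The FEV1/FVC covariate is
scored the same way, $(100 - 100\,\text{FEV1}/\text{FVC})/10$: +1 at a
ratio of 0.9. The opposite sign convention (the ratio minus 100,
giving −1 at 0.9) is selectable by `ratio_sign = "printed"`; the
default is the one under which "hazard ratio above 1" means "reduced
lung function is harmful", which is the interpretable direction.

### Proportional-hazards diagnostic

At each event time the raw Schoenfeld residual is the case's covariate
minus the risk-set weighted mean; scaled residuals premultiply by
$d\cdot\widehat{\mathrm{Var}}(\hat\beta)$ ($d$ events). The diagnostic
is the Pearson correlation $\rho$ of each covariate's scaled residuals
with the transformed survival times at the events, with a t-based
p-value on $d-2$ degrees of freedom. The time axis is the identity on
Z — the transformed scale is already the analysis scale — with a rank
transform available. The tests verify calibration (type-I error at
the nominal 5% within Monte-Carlo bands; p-values uniform under PH)
and power against a hazard ratio that decays over the Z range.

## Predictions

For a covariate scenario $x$ the Weibull quantile is closed-form,
$z_p = \left(-\log(1-p)/(\lambda e^{x'\beta})\right)^{1/k}$, and the
predicted age at death is $a_0 + \Lambda^{*-1}(z_p)$ from the
scenario's anchor position. Percentile tables are anchored at
1 January 1965 by default (entry ages 25/45/65; percentiles
5/50/95%) — one year before the rate grid starts, which the edge-column
extrapolation covers by design. Mortality curves are
$1-\exp(-\lambda \Lambda^*(a-a_0)^k e^{x'\beta})$ on the attained-age
scale. Scenario covariates hold all confounders at their reference
values.

Years-of-life-lost contrasts are differences of median predicted ages
at death (never-smoked minus grade, within sex and entry age),
reported to 1 decimal; the gender gap differences the two per-sex
values *after* rounding each to 1 decimal, matching how such contrasts
are quoted from published per-sex figures. The package ships a
published residual-lifetime percentile table for the cotton workers'
cohort as a plain-CSV fixture; it encodes the printed values verbatim,
including one (entry 45, heavy-smoking women) cell pair whose 5th and
95th percentiles are evidently transposed in print —
`validatePercentileTable()` flags that cell rather than correcting it,
and the year-of-life-lost arithmetic uses medians only, so it is
unaffected.

## The synthetic-data generator

No cohort microdata or national rate file is distributable, so the
generator stands in for both, with defaults chosen once to match the
published study conditions:

* rate surface $\mu = \exp(a + b\,\mathrm{age} - c(\mathrm{year}-1966)
  + d\,\mathrm{male})$ with $a=-9.6$, $b=0.085$ (a Gompertz slope
  typical of adult all-cause mortality), $c=0.015$ (≈1.5%/yr secular
  improvement, the order observed in England & Wales over 1966–2007)
  and $d=0.35$ (≈1.4× male excess), on ages 0–100 × years 1966–2007;
* $n=3459$ subjects, 45% men; entry ages truncated-normal on 15–75
  with mean (SD) 41.5 (15.6) for men and 45.6 (12.2) for women; entry
  uniform over 1966–1970;
* per-sex smoking-grade frequencies 22/38/29/6/6% (men) and
  45/32/18/3/3% (women) for never/light/medium/heavy/former, and
  banded years-in-industry frequencies, all from the published
  demographic table;
* true Z-scale log-hazard effects following the published dose-response
  pattern (grade HRs 1.21/1.68/1.99/0.89, female 1.07, RRRs
  1.35/1.15/1.00/1.10, small confounder effects) — used as *truth for
  recovery*, never as targets;
* administrative censoring at end-2007, an exponential embarkation
  clock at $6\times10^{-4}$/yr (matching the published ~90
  embarkations), and the age-90 frame applied downstream by the
  transformation.

Each subject draws $Z^*\sim\mathrm{Weibull}(k,\ \lambda e^{x'\beta})$
and dies at $t=\Lambda^{*-1}(Z^*)$: proportional hazards hold *on the
transformed scale*, exactly the assumption the analysis makes, so
parameter recovery tests the pipeline, not model misspecification (a
`natural_scale` toggle moves the effects to the age scale for
robustness studies). With all effects zero and $k=1$ the pipeline
returns $Z\sim\mathrm{Exp}(1)$ among uncensored subjects — verified by
Kolmogorov–Smirnov in the tests. What the generator deliberately does
not emulate: the real rate surface's infant/accident structure,
covariate correlations within the cohort (smoking vs lung function),
and reporting errors; passing recovery here shows the machinery is
correct, not that any real cohort satisfies proportional hazards.

Randomness is driven by one `set.seed(config$seed)` per cohort draw —
byte-identical reproducibility for a given configuration; replicate
$r$ of an experiment uses `seed + r`.

## Problem sizes used in the tests

The shipped test-suite and acceptance script use: $n=5000$ uncensored
subjects for the Exp(1) null (KS, p > 0.01); 200 replicates at
$n=3459$ for coverage (all six headline parameters within a
91–99% band) and Cox-Weibull agreement (mean max $|\Delta\beta| <
0.02$); 1000 replicates at $n=1000$ for the ρ test's type-I error
(0.03–0.07); 100 random queries against a boundary-aligned Riemann
oracle at relative tolerance $10^{-6}$; and 20 000 draws per cell for
the prediction round trip (medians within 0.5 years). These sizes give
Monte-Carlo error comfortably inside each band while keeping a full
run to a few minutes.

## Known limitations

* Central rates are used directly as hazards (no $q\leftrightarrow m$
  conversion); appropriate for mid-year population-based rates, and an
  approximation if a life table supplies probabilities instead.
* No delayed-entry machinery beyond the entry-age anchoring of the
  transformation itself, no frailty, no time-varying covariates, and
  no multiple imputation for missing covariates.
* Cause groupings are labels: mapping ICD codes across revisions to
  the six cause groups is out of scope.
* The ρ diagnostic correlates with the identity time axis on Z; a
  differently transformed axis would give slightly different ρ values
  (the published values are too small to disambiguate the convention).
* Percentile predictions are point predictions; no uncertainty bands.
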