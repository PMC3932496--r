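# lexisurv

Individual relative-survival analysis for cohorts with very long
follow-up, built for occupational and population cohort studies in
which subjects enter at widely different ages and calendar eras — the
motivating application is a 1960s cotton-industry cohort of men and
women followed for mortality over four decades, used to ask whether
smoking recorded at baseline was more hazardous to women than to men.

## The method

Comparing subjects who entered a cohort at age 18 in 1966 with subjects
who entered at 70 in 1970 on the raw time axis confounds every effect
of interest with age and with the rapid secular improvement in
mortality. `lexisurv` instead transforms each subject's observed
follow-up time *t* into the **expected cumulative hazard** accumulated
along their own diagonal of the Lexis diagram (age and calendar year
advancing together):

    Z = Λ*(t) = ∫₀ᵗ μ(sex, a₀ + u, y₀ + u) du ,     Y = 1 − exp(−Z)

where `μ` is a reference life table of sex-specific central mortality
rates by single year of age × calendar year. If a subject dies exactly
like the reference population, Z is unit-exponential and Y is the
individual relative-survival measure on [0, 1). Both measures carry
the same ranks, so Cox regression gives identical coefficients on
either scale; Z in addition supports a fully parametric Weibull
proportional-hazards model

    h(z | x) = k λ z^(k−1) exp(x'β)

whose closed-form quantiles can be pushed back through the inverse of
Λ* to give **conditional residual-lifetime percentiles** — the
predicted age at death by percentile, smoking grade and sex — and
mortality curves on the attained-age scale.

The scientific contrast of interest is the **relative risk ratio
(RRR)**: the female smoker-vs-never hazard ratio divided by the male
smoker-vs-never hazard ratio, estimated as the exponentiated
gender × smoking-grade interaction (grades: never, light 1–14,
medium 15–24, heavy ≥ 25 cigarettes/day, former). The
proportional-hazards assumption is checked per covariate by the
Pearson correlation ρ between scaled Schoenfeld residuals and the
transformed survival times.

Because the original cohort data are not publicly deposited, the
package ships a first-class synthetic generator: a Gompertz reference
rate surface (log-linear in age, improving over calendar time, male
excess) and cohorts with the published demographic structure and a
known multiplicative truth on the Z scale, so the whole pipeline is
testable by parameter recovery.

## Worked example

```r
library(lexisurv)

cfg    <- simulationConfig(n = 3459, seed = 1)   # published cohort structure
rates  <- makeRateTable(cfg)                     # synthetic national life table
cohort <- simulateCohort(cfg, rates)             # known truth attached

tc  <- transformCohort(cohort, rates)            # Y, Z, event per subject
X   <- buildDesign(cohort, scheme = "rrr4", confounders = "full")
fit <- fitCox(tc, X)
extractRRR(fit)
```

    #           term       rrr        lo       hi           p  grade
    # 1  female_light 1.4700068 1.1507485 1.877839 0.002042593  light
    # 2 female_medium 1.1301526 0.8776906 1.455234 0.342840094 medium
    # 3  female_heavy 0.6645103 0.4080606 1.082128 0.100434775  heavy
    # 4 female_former 1.5161273 0.9254163 2.483900 0.098481754 former

The generator's truth for this cohort put the light-smoking RRR at
1.35 (medium 1.15, heavy 1.00): a single replicate recovers the
dose-response pattern — the female excess is concentrated in light
smoking — within sampling error (the light RRR above is 1.47 with 95%
CI 1.15–1.88). `phTest(fit)` appends the ρ/P proportional-hazards
diagnostics; all |ρ| are small when the model is well specified.

Predictions come from the parametric fit:

```r
fw  <- fitWeibull(tc, X)                         # shape ≈ 1 here
tab <- residualLifetimeTable(fw, rates, entry_ages = 45)
yearsOfLifeLost(tab, "light", "male")            # 1.8 years
yearsOfLifeLost(tab, "light", "female")          # 6.9 years
genderYllGap(tab, "light")                       # 5.1 years
mortalityCurve(fw, rates, entry_age = 45, sex = "female", grade = "light")
```

`runAnalysis()` orchestrates the whole pipeline (including per-cause
RRR tables and publication-shaped delimited outputs) from a single
config, and `inst/cli/lexisurv.R` exposes the same steps as shell
subcommands.

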