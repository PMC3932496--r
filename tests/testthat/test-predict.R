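# minimal hand-built parametric fit for closed-form checks
toy_weibull_fit <- function(shape = 1, rate = 1,
                            beta = c(light = 0, medium = 0, heavy = 0,
                                     former = 0, female = 0,
                                     female_light = 0, female_medium = 0,
                                     female_heavy = 0, female_former = 0)) {
  structure(list(family = "weibull", coefficients = beta,
                 vcov = diag(length(beta)), shape = shape, rate = rate,
                 rrr_terms = grep("^female_", names(beta), value = TRUE)),
            class = "lexisurv_fit")
}

test_that("zQuantile matches closed forms and PH scaling", {
  f <- toy_weibull_fit()
  expect_equal(zQuantile(f, p = 0.5), log(2))
  # a log-2 linear predictor halves the exponential median
  f2 <- toy_weibull_fit(beta = c(light = log(2)))
  expect_equal(zQuantile(f2, c(light = 1), 0.5), log(2) / 2)
  # k = 2: agree with numerical inversion of S(z) = exp(-rate z^2 e^lp)
  f3 <- toy_weibull_fit(shape = 2, rate = 0.7,
                        beta = c(light = 0.3))
  zq <- zQuantile(f3, c(light = 1), 0.8)
  surv <- function(z) exp(-0.7 * z^2 * exp(0.3))
  root <- uniroot(function(z) surv(z) - 0.2, c(1e-9, 50),
                  tol = 1e-12)$root
  expect_equal(zq, root, tolerance = 1e-8)
  expect_error(zQuantile(f, p = 1.2), "in \\(0, 1\\)")
  cfit <- structure(list(family = "cox", shape = NULL),
                    class = "lexisurv_fit")
  expect_error(zQuantile(cfit, p = 0.5), "parametric")
})

test_that("percentile table reduces to the closed form for constant rates", {
  tb <- const_table(0.02)
  f <- toy_weibull_fit()
  tab <- residualLifetimeTable(f, tb, anchor = 1965.0, entry_ages = 45,
                               grades = "never", sexes = "male",
                               percentiles = 0.5)
  expect_equal(tab$age_death, 45 + log(2) / 0.02, tolerance = 1e-9)
})

test_that("percentile tables are monotone in percentile and above entry age", {
  cfg <- simulationConfig(n = 2500, seed = 88)
  tb <- makeRateTable(cfg)
  co <- simulateCohort(cfg, tb)
  tc <- transformCohort(co, tb)
  X <- buildDesign(co, confounders = "none")
  fw <- fitWeibull(tc, X)
  tab <- residualLifetimeTable(fw, tb)
  expect_false(any(tab$saturated))
  expect_true(all(tab$age_death >= tab$entry_age))
  expect_equal(nrow(validatePercentileTable(tab)), 0)
  # per-cell monotonicity explicitly: 5% <= 50% <= 95%
  w <- split(tab, interaction(tab$entry_age, tab$grade, tab$sex))
  for (d in w) {
    d <- d[order(d$percentile), ]
    expect_true(all(diff(d$age_death) >= 0))
  }
})

test_that("the published fixture carries its transposed cells as flagged anomalies", {
  tab <- fixture_percentiles()
  bad <- validatePercentileTable(tab)
  expect_equal(nrow(bad), 1)
  expect_equal(bad$entry_age, 45)
  expect_equal(bad$grade, "heavy")
  expect_equal(bad$sex, "female")
})

test_that("years-of-life-lost contrasts reproduce the published arithmetic", {
  tab <- fixture_percentiles()
  expect_equal(yearsOfLifeLost(tab, "light", "male"), 2.6)
  expect_equal(yearsOfLifeLost(tab, "light", "female"), 5.9)
  expect_equal(genderYllGap(tab, "light"), 3.3)
  expect_equal(genderYllGap(tab, "medium"), 1.2)
  expect_equal(genderYllGap(tab, "heavy"), -0.4)
})

test_that("saturated cells refuse the contrast", {
  tab <- fixture_percentiles()
  tab$saturated[tab$grade == "light" & tab$sex == "male" &
                  tab$entry_age == 45 & tab$percentile == 0.5] <- TRUE
  expect_error(yearsOfLifeLost(tab, "light", "male"), "saturated")
})

test_that("mortality curves start at zero, increase, and cross 50% at the median", {
  tb <- const_table(0.02)
  f <- toy_weibull_fit(beta = c(light = 0.4, female = -0.3,
                                female_light = 0))
  cv <- mortalityCurve(f, tb, entry_age = 45, sex = "male",
                       grade = "never", ages = seq(45, 100, 0.25))
  expect_equal(cv$mortality_pct[1], 0)
  expect_true(all(diff(cv$mortality_pct) >= 0))
  # female curve below male when the female coefficient is negative
  cvf <- mortalityCurve(f, tb, entry_age = 45, sex = "female",
                        grade = "never", ages = seq(45, 100, 0.25))
  expect_true(all(cvf$mortality_pct[-1] < cv$mortality_pct[-1]))
  # the curve crosses 50% at its own median age
  med <- residualLifetimeTable(f, tb, entry_ages = 45, grades = "never",
                               sexes = "male",
                               percentiles = 0.5)$age_death
  below <- max(cv$age[cv$mortality_pct < 50])
  above <- min(cv$age[cv$mortality_pct >= 50])
  expect_true(below <= med && med <= above + 0.25)
})

test_that("the tabulated median matches the generative median (round trip)", {
  # simulate from the fitted model's own parameters and compare the
  # empirical median age at death per cell with the table cell
  cfg <- simulationConfig(n = 4000, seed = 99)
  tb <- makeRateTable(cfg)
  co <- simulateCohort(cfg, tb)
  tc <- transformCohort(co, tb)
  X <- buildDesign(co, confounders = "none")
  fw <- fitWeibull(tc, X)
  cell <- expand.grid(grade = c("never", "light"),
                      sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  tab <- residualLifetimeTable(fw, tb, entry_ages = 45,
                               grades = unique(cell$grade),
                               percentiles = 0.5)
  n <- 20000
  set.seed(100)
  for (i in seq_len(nrow(cell))) {
    x <- lexisurv:::scenarioCovariates(fw, cell$grade[i], cell$sex[i])
    lp <- sum(fw$coefficients * x)
    zstar <- (rexp(n) / (fw$rate * exp(lp)))^(1 / fw$shape)
    td <- invertCumulativeHazard(
      tb, lexisPosition(cell$sex[i], 45, 1965.0), zstar)
    emp <- median(45 + td)
    pred <- tab$age_death[tab$grade == cell$grade[i] &
                            tab$sex == cell$sex[i]]
    expect_lt(abs(emp - pred), 0.5)
  }
})
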