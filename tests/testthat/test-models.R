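make_small_records <- function(time, event) {
  data.frame(id = seq_along(time), y = 1 - exp(-time), z = time,
             event = event)
}

test_that("symmetric groups give a zero coefficient", {
  time <- c(1, 2, 3, 1, 2, 3)
  rec <- make_small_records(time, c(1, 1, 1, 1, 1, 1))
  X <- cbind(grp = c(0, 0, 0, 1, 1, 1))
  f <- fitCox(rec, X, ties = "breslow")
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
})

test_that("fitCox matches the brute-force partial-likelihood maximiser", {
  time <- c(0.3, 0.9, 1.4, 2.2, 3.1, 4.0)
  event <- c(1, 0, 1, 1, 0, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  rec <- make_small_records(time, event)
  X <- cbind(xc = x)
  f <- fitCox(rec, X)
  bhat <- golden_max(function(b) partial_loglik_1cov(b, time, event, x),
                     -5, 5)
  expect_equal(unname(f$coefficients), bhat, tolerance = 1e-6)
  expect_equal(f$loglik, partial_loglik_1cov(bhat, time, event, x),
               tolerance = 1e-8)
})

test_that("Cox coefficients are identical on the Y and Z scales (rank invariance)", {
  cfg <- simulationConfig(n = 1200, seed = 77)
  tb <- makeRateTable(cfg)
  co <- simulateCohort(cfg, tb)
  tc <- transformCohort(co, tb)
  X <- buildDesign(co, confounders = "none")
  fz <- fitCox(tc, X, scale = "z")
  fy <- fitCox(tc, X, scale = "y")
  expect_equal(fz$coefficients, fy$coefficients, tolerance = 1e-8)
  # any strictly increasing transform leaves the fit unchanged: Y^2
  tc2 <- tc; tc2$y <- tc$y^2
  fy2 <- fitCox(tc2, X, scale = "y")
  expect_equal(fz$coefficients, fy2$coefficients, tolerance = 1e-8)
})

test_that("exponential fit recovers the closed-form rate-ratio MLE", {
  set.seed(11)
  n <- 400
  x <- rep(c(0, 1), each = n / 2)
  time <- rexp(n, exp(0.7 * x))
  cens <- runif(n, 0, 4)
  event <- as.integer(time <= cens)
  obs <- pmin(time, cens)
  rec <- make_small_records(obs, event)
  f <- fitWeibull(rec, cbind(x = x), shape_fixed = 1)
  # exponential MLE: log rate = log(events / exposure) per group
  closed <- log(sum(event[x == 1]) / sum(obs[x == 1])) -
    log(sum(event[x == 0]) / sum(obs[x == 0]))
  expect_equal(unname(f$coefficients), closed, tolerance = 1e-6)
  expect_equal(f$shape, 1)
  expect_identical(f$family, "exponential")
})

test_that("Weibull shape is recovered from unit-exponential data", {
  set.seed(21)
  rec <- make_small_records(rexp(2000), rep(1L, 2000))
  f <- fitWeibull(rec, matrix(numeric(0), 2000, 0))
  expect_true(f$shape > 0.93 && f$shape < 1.07)
  expect_true(abs(f$rate - 1) < 0.1)
})

test_that("Cox and Weibull agree under exponential truth", {
  cfg <- simulationConfig(n = 3000, seed = 303)
  tb <- makeRateTable(cfg)
  co <- simulateCohort(cfg, tb)
  tc <- transformCohort(co, tb)
  X <- buildDesign(co, confounders = "none")
  fc <- fitCox(tc, X)
  fw <- fitWeibull(tc, X)
  se <- sqrt(diag(fc$vcov) + diag(fw$vcov))
  expect_true(all(abs(fc$coefficients - fw$coefficients) < 2 * se))
})

test_that("RRR extraction is exp(beta) with Wald CIs, algebraically consistent", {
  # hand-set coefficient/covariance fixture
  beta <- c(light = 0.2, female = 0.1, female_light = log(1.5))
  V <- diag(c(0.01, 0.02, 0.04))
  dimnames(V) <- list(names(beta), names(beta))
  tab <- data.frame(term = names(beta), estimate = beta,
                    se = sqrt(diag(V)), hr = exp(beta),
                    lo = exp(beta - 1.96 * sqrt(diag(V))),
                    hi = exp(beta + 1.96 * sqrt(diag(V))),
                    p = 2 * pnorm(-abs(beta / sqrt(diag(V)))),
                    rrr = names(beta) == "female_light")
  fit <- structure(list(family = "cox", coefficients = beta, vcov = V,
                        table = tab, rrr_terms = "female_light"),
                   class = "lexisurv_fit")
  r <- extractRRR(fit)
  expect_equal(r$rrr, 1.5)
  expect_equal(r$lo, exp(log(1.5) - 1.96 * 0.2))
  expect_equal(r$hi, exp(log(1.5) + 1.96 * 0.2))
  # RRR = ratio of female and male smoker-vs-never hazard ratios
  hr_female_smoker <- exp(beta["light"] + beta["female_light"])
  hr_male_smoker <- exp(beta["light"])
  expect_equal(r$rrr, unname(hr_female_smoker / hr_male_smoker))
  # a zero interaction gives RRR 1 with CI containing 1
  fit$coefficients["female_light"] <- 0
  fit$table$hr[3] <- 1
  fit$table$lo[3] <- exp(-1.96 * 0.2); fit$table$hi[3] <- exp(1.96 * 0.2)
  r0 <- extractRRR(fit)
  expect_equal(r0$rrr, 1)
  expect_true(r0$lo < 1 && r0$hi > 1)
})

test_that("RRR estimates recover a known female-light interaction", {
  cfg <- simulationConfig(
    n = 2500,
    beta_true = c(light = log(1.3), female = log(1.1),
                  female_light = log(1.5)),
    seed = 515)
  tb <- makeRateTable(cfg)
  ests <- vapply(1:100, function(r) {
    cfg$seed <- cfg$seed + r
    co <- simulateCohort(cfg, tb)
    tc <- transformCohort(co, tb)
    X <- suppressWarnings(buildDesign(co, confounders = "none"))
    extractRRR(fitCox(tc, X))$rrr[1]
  }, numeric(1))
  expect_gt(mean(ests), 1.4)
  expect_lt(mean(ests), 1.6)
})

test_that("model comparison ranks by likelihood with ties to fewer parameters", {
  set.seed(33)
  z <- rweibull(1500, shape = 2, scale = 1)
  rec <- make_small_records(z, rep(1L, 1500))
  X <- cbind(x = rbinom(1500, 1, 0.5))
  fw <- fitWeibull(rec, X)
  fe <- fitWeibull(rec, X, shape_fixed = 1)
  cmp <- compareModels(list(fe, fw))
  expect_identical(cmp$family[1], "weibull")
  # nested pair: LR statistic is non-negative
  expect_gte(2 * (fw$loglik - fe$loglik), 0)
  # a model against itself: stable tie kept in input order
  cmp2 <- compareModels(list(fw, fw))
  expect_identical(cmp2$index, c(1L, 2L))
  # different data are refused
  rec2 <- rec; rec2$z <- rec2$z * 2
  f2 <- fitWeibull(rec2, X)
  expect_error(compareModels(list(fw, f2)), "fingerprint")
})

test_that("degenerate fits fail loudly", {
  rec <- make_small_records(c(1, 2, 3, 4), c(1, 1, 1, 1))
  X <- cbind(a = c(1, 0, 1, 0), b = c(2, 0, 2, 0))  # collinear
  expect_error(fitCox(rec, X), "rank deficient|collinear")
  # perfect separation: covariate orders the deaths exactly
  rec2 <- make_small_records(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 1, 1, 1))
  X2 <- cbind(sep = c(1, 1, 1, 0, 0, 0))
  expect_error(fitCox(rec2, X2), "diverged|infinite")
  expect_error(fitCox(make_small_records(1:3, c(0, 0, 0)),
                      cbind(x = 1:3)), "no events")
})
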