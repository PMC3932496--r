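test_that("constant and piecewise hazards integrate in closed form", {
  tb <- const_table(0.01)
  pos <- lexisPosition("male", 37.4, 1970.2)
  expect_equal(cumulativeHazard(tb, pos, 10), 0.1)
  expect_equal(cumulativeHazard(tb, pos, 0), 0)
  expect_equal(expectedSurvival(tb, pos, 10), exp(-0.1))
  expect_equal(expectedSurvival(tb, pos, 0), 1)

  st <- step_table(0.01, 0.02)
  p48 <- lexisPosition("female", 48.0, 1970.0)
  expect_equal(cumulativeHazard(st, p48, 5), 0.01 * 2 + 0.02 * 3)  # = 0.08
  expect_equal(expectedSurvival(st, p48, 5), exp(-(0.01 * 2 + 0.02 * 3)))
})

test_that("Lexis integration matches the fine-grid Riemann oracle", {
  tb <- varied_table()
  set.seed(41)
  for (i in 1:25) {
    sex <- sample(c("male", "female"), 1)
    a0 <- runif(1, 16, 70); y0 <- runif(1, 1966, 1971)
    t <- runif(1, 0.5, 20)
    exact <- cumulativeHazard(tb, lexisPosition(sex, a0, y0), t)
    oracle <- riemann_cumhaz(tb, sex, a0, y0, t)
    expect_equal(exact, oracle, tolerance = 1e-6)
  }
})

test_that("cumulative hazard is additive along the diagonal", {
  tb <- varied_table()
  set.seed(42)
  for (i in 1:20) {
    sex <- sample(c("male", "female"), 1)
    a0 <- runif(1, 16, 70); y0 <- runif(1, 1966, 1971)
    t1 <- runif(1, 0.1, 15); t2 <- runif(1, 0.1, 15)
    pos <- lexisPosition(sex, a0, y0)
    whole <- cumulativeHazard(tb, pos, t1 + t2)
    split <- cumulativeHazard(tb, pos, t1) +
      cumulativeHazard(tb, lexisPosition(sex, a0 + t1, y0 + t1), t2)
    expect_equal(whole, split, tolerance = 1e-10)
  }
})

test_that("inversion is the exact round-trip inverse", {
  expect_equal(invertCumulativeHazard(const_table(0.02),
                                      lexisPosition("male", 30, 1970),
                                      log(2)),
               log(2) / 0.02, tolerance = 1e-9)
  tb <- step_table()
  pos <- lexisPosition("female", 44.5, 1967.3)
  expect_equal(invertCumulativeHazard(tb, pos, 0), 0)
  zmax <- cumulativeHazard(tb, pos, 40)
  set.seed(43)
  z <- runif(30, 0, zmax)
  t <- invertCumulativeHazard(tb, pos, z)
  expect_equal(cumulativeHazard(tb, pos, t), z, tolerance = 1e-9)
  expect_true(all(diff(t[order(z)]) >= 0))
  # forward-then-invert identity
  tt <- runif(10, 0, 40)
  expect_equal(invertCumulativeHazard(tb, pos,
                                      cumulativeHazard(tb, pos, tt)),
               tt, tolerance = 1e-9)
})

test_that("extrapolation reuses edge years and grows a Gompertz tail", {
  tb <- varied_table(ages = 0:90, years = 1990:2000)
  pos_pre <- lexisPosition("male", 40, 1980.0)   # before first year
  h_pre <- cumulativeHazard(tb, pos_pre, 1)
  h_first <- cumulativeHazard(tb, lexisPosition("male", 40, 1990.0), 1)
  expect_equal(h_pre, h_first, tolerance = 1e-12)
  # beyond the top age the tail keeps rising (Gompertz, capped)
  r95 <- cumulativeHazard(tb, lexisPosition("male", 95, 1995.0), 1)
  r89 <- cumulativeHazard(tb, lexisPosition("male", 89, 1995.0), 1)
  expect_gt(r95, r89)
  expect_lte(r95, tb$extrapolation$cap)
})

test_that("off-grid queries error with the missing cell when extrapolation is off", {
  m <- matrix(0.01, 10, 5)
  tb <- rateTable(list(male = m, female = m), 40:49, 1966:1970,
                  extrapolation = list(extrapolate = FALSE))
  expect_error(cumulativeHazard(tb, lexisPosition("male", 48, 1966.0), 5),
               "does not cover.*age=5[0-9]")
  expect_error(cumulativeHazard(tb, lexisPosition("male", 42, 1969.5), 4),
               "year=197[1-9]")
  expect_error(cumulativeHazard(tb, lexisPosition("badger", 42, 1966), 1),
               "no rates for sex")
})

test_that("inversion saturates explicitly at the table ceiling", {
  m <- matrix(1e-5, 101, 2)
  tb <- rateTable(list(male = m, female = m), 0:100, 1966:1967,
                  extrapolation = list(max_age = 105))
  pos <- lexisPosition("male", 95, 1966.0)
  expect_error(invertCumulativeHazard(tb, pos, 50), "saturated")
  expect_true(is.na(invertCumulativeHazard(tb, pos, 50,
                                           on_saturate = "NA")))
})

test_that("rate table files round-trip and malformed grids are rejected", {
  tb <- rateTable(list(male = matrix(c(0.01, 0.02, 0.03, 0.011, 0.021,
                                       0.031), 3, 2),
                       female = matrix(c(0.009, 0.019, 0.029, 0.01,
                                         0.02, 0.03), 3, 2)),
                  50:52, 1970:1971, cause = "lung cancer")
  path <- tempfile(fileext = ".txt")
  writeRateTable(tb, path)
  tb2 <- readRateTable(path)
  expect_identical(tb2$rates, tb$rates)
  expect_identical(tb2$cause, "lung cancer")
  expect_identical(tb2$ages, tb$ages)

  lines <- readLines(path)
  bad <- sub("0.019", "-0.019", lines, fixed = TRUE)
  writeLines(bad, path)
  expect_error(readRateTable(path), "line [0-9]+: negative rate")

  # drop one year column from a data row
  lines2 <- readLines(textConnection(c(
    "# sex: male", "age\t1970\t1971", "50\t0.01")))
  p2 <- tempfile(); writeLines(c(lines2[1:2], "50\t0.01"), p2)
  expect_error(readRateTable(p2), "missing year column")

  p3 <- tempfile()
  writeLines(c("# sex: male", "age\t1970\t1971",
               "50\t0.01\t0.02", "52\t0.01\t0.02"), p3)
  expect_error(readRateTable(p3), "gap in age axis")
})

test_that("constructor enforces the grid invariants", {
  expect_error(rateTable(list(male = matrix(-1, 2, 2)), 0:1, 1966:1967),
               "negative or non-finite")
  expect_error(rateTable(list(male = matrix(1, 2, 2)), c(0, 2), 1966:1967),
               "unit step")
  expect_error(rateTable(list(male = matrix(1, 2, 2)), 0:1, c(1966, 1968)),
               "unit step")
})
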