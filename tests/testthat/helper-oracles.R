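# Independent oracles and small fixtures shared across tests.

# Fine-grid Riemann sum along the Lexis diagonal: the brute-force
# counterpart of the exact piecewise integration.  Rates are looked up
# at the midpoint of each step; step = 1/3650 year.
riemann_cumhaz <- function(table, sex, a0, y0, t, step = 1 / 3650) {
  if (t <= 0) return(0)
  u <- seq(0, t, by = step)
  # include the Lexis cell boundaries so no step straddles a rate change
  age_br <- (ceiling(a0) - a0) + 0:ceiling(t)
  yr_br <- (ceiling(y0) - y0) + 0:ceiling(t)
  u <- sort(unique(c(u, age_br[age_br < t], yr_br[yr_br < t], t)))
  mid <- (u[-1] + u[-length(u)]) / 2
  du <- diff(u)
  m <- if (isTRUE(table$extrapolation$extrapolate)) table$extended[[sex]]
       else table$rates[[sex]]
  ages <- as.integer(rownames(m)); years <- table$years
  ai <- pmin(pmax(floor(a0 + mid), ages[1]), ages[length(ages)])
  yi <- pmin(pmax(floor(y0 + mid), years[1]), years[length(years)])
  sum(m[cbind(ai - ages[1] + 1L, yi - years[1] + 1L)] * du)
}

# Explicit Cox partial log-likelihood for one covariate, no ties
partial_loglik_1cov <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    rs <- which(time >= time[i])
    ll <- ll + x[i] * beta - log(sum(exp(x[rs] * beta)))
  }
  ll
}

# golden-section maximiser of the partial likelihood (the brute force
# oracle for fitCox on tiny data)
golden_max <- function(f, lo, hi, tol = 1e-9) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1) }
  }
  (a + b) / 2
}

# From-definition Schoenfeld residuals (Breslow, assumes no tied event
# times): covariate of the case minus the risk-set weighted mean.
schoenfeld_oracle <- function(time, event, X, beta) {
  X <- as.matrix(X)
  ev <- which(event == 1)
  ev <- ev[order(time[ev])]
  out <- matrix(NA_real_, length(ev), ncol(X))
  for (k in seq_along(ev)) {
    i <- ev[k]
    rs <- which(time >= time[i])
    w <- exp(as.numeric(X[rs, , drop = FALSE] %*% beta))
    xbar <- colSums(X[rs, , drop = FALSE] * w) / sum(w)
    out[k, ] <- X[i, ] - xbar
  }
  colnames(out) <- colnames(X)
  out
}

# small constant-rate table covering both sexes
const_table <- function(rate = 0.01, ages = 0:100, years = 1966:2007,
                        ...) {
  m <- matrix(rate, length(ages), length(years))
  rateTable(list(male = m, female = m), ages, years, ...)
}

# piecewise table: one rate below age 50, another from 50 up
step_table <- function(lo = 0.01, hi = 0.02, ages = 0:100,
                       years = 1966:2007) {
  m <- matrix(lo, length(ages), length(years))
  m[ages >= 50, ] <- hi
  rateTable(list(male = m, female = m), ages, years)
}

# deterministic "random-looking" grid with distinct rates per cell
varied_table <- function(ages = 0:100, years = 1966:2007) {
  f <- function(sx) {
    g <- outer(ages, years - years[1],
               function(a, y) 0.002 + 0.00035 * a + 0.0001 * y +
                 2e-4 * sin(a * 0.7 + y * 1.3 + sx))
    pmax(g, 1e-5)
  }
  rateTable(list(male = f(0), female = f(1)), ages, years)
}

# handcrafted 6-subject cohort covering deaths / embarked / alive
toy_subjects <- function() {
  data.frame(
    id = paste0("T", 1:6),
    sex = c("male", "female", "male", "female", "male", "female"),
    entry_age = c(40.2, 55.7, 33.1, 47.9, 61.3, 29.8),
    entry_year = c(1966.5, 1967.2, 1968.9, 1966.1, 1969.4, 1970.0),
    followup_years = c(12.3, 20.1, 35.6, 41.2, 8.7, 38.0),
    status = c("death", "death", "embarked", "embarked", "censored",
               "censored"),
    cause = c("all-cause", "all-cause", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

fixture_percentiles <- function() {
  readPercentileTable(system.file("extdata", "cotton_percentiles.csv",
                                  package = "lexisurv"))
}
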