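#' Quantile of the transformed time under a Weibull fit
#'
#' Closed-form quantile of Z given the covariates: with survival
#' `S(z | x) = exp(-lambda * z^k * exp(x'beta))`,
#' `z_p = (-log(1 - p) / (lambda * exp(x'beta)))^(1/k)`.
#'
#' @param fit a parametric `lexisurv_fit` ([fitWeibull()]).
#' @param x named covariate vector; coefficients absent from `x` are
#'   taken as 0 (the reference cell).
#' @param p probabilities in (0, 1).
#' @return numeric vector of Z-scale quantiles, one per `p`.
#' @export
zQuantile <- function(fit, x = NULL, p) {
  stopifnot(inherits(fit, "lexisurv_fit"))
  if (is.null(fit$shape)) stop("zQuantile needs a parametric (Weibull) fit")
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  lp <- 0
  if (!is.null(x) && length(x)) {
    if (is.null(names(x))) stop("'x' must be a named covariate vector")
    unknown <- setdiff(names(x), names(fit$coefficients))
    if (length(unknown)) stop("unknown covariates: ",
                              paste(unknown, collapse = ", "))
    lp <- sum(fit$coefficients[names(x)] * x)
  }
  (-log(1 - p) / (fit$rate * exp(lp)))^(1 / fit$shape)
}

# covariate vector for a (grade, sex) scenario: grade + female +
# interaction terms set, every other coefficient at its reference (0)
scenarioCovariates <- function(fit, grade, sex) {
  nm <- names(fit$coefficients)
  x <- stats::setNames(numeric(length(nm)), nm)
  gcol <- if (grade %in% c("medium", "heavy") && "medheavy" %in% nm)
    "medheavy" else grade
  if (grade != "never") {
    if (!gcol %in% nm) stop(sprintf("fit has no grade column for '%s'", grade))
    x[gcol] <- 1
  }
  if (sex == "female") {
    x["female"] <- 1
    icol <- paste0("female_", gcol)
    if (grade != "never") {
      if (!icol %in% nm) stop(sprintf("fit has no interaction column '%s'", icol))
      x[icol] <- 1
    }
  }
  x
}

#' Conditional residual-lifetime percentile table
#'
#' For each (entry age, smoking grade, sex, percentile) scenario,
#' computes the Z-scale quantile from the Weibull fit and maps it back
#' through the reference rate table to an age at death: entry age plus
#' the follow-up time at which the scenario's expected cumulative
#' hazard reaches the quantile.  All predictions are conditional on
#' being alive at the anchor date.  Cells whose quantile lies beyond
#' the rate table's extrapolation ceiling are flagged (`saturated`),
#' not capped.
#'
#' @param fit a parametric `lexisurv_fit`; confounders in the fit are
#'   held at their reference values.
#' @param table the [rateTable()] used for the back-transformation.
#' @param anchor anchor date in decimal years (default 1965.0, i.e.
#'   1st January 1965).
#' @param entry_ages ages at the anchor date.
#' @param grades,sexes scenario factors.
#' @param percentiles survival percentiles in (0, 1).
#' @return data.frame of class `percentile_table` with columns
#'   `entry_age`, `percentile`, `grade`, `sex`, `age_death`,
#'   `saturated`; attribute `anchor`.
#' @export
residualLifetimeTable <- function(fit, table, anchor = 1965.0,
                                  entry_ages = c(25, 45, 65),
                                  grades = c("never", "light", "medium",
                                             "heavy"),
                                  sexes = c("male", "female"),
                                  percentiles = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(table, "rate_table"))
  grid <- expand.grid(entry_age = entry_ages, percentile = percentiles,
                      grade = grades, sex = sexes,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  zp <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid)))
    zp[i] <- zQuantile(fit,
                       scenarioCovariates(fit, grid$grade[i], grid$sex[i]),
                       grid$percentile[i])
  t_res <- invertCumulativeHazard(
    table, lexisPosition(grid$sex, grid$entry_age, anchor), zp,
    on_saturate = "NA")
  grid$age_death <- grid$entry_age + t_res
  grid$saturated <- is.na(t_res)
  attr(grid, "anchor") <- anchor
  class(grid) <- c("percentile_table", "data.frame")
  grid
}

#' Validate monotonicity of a percentile table
#'
#' Within each (entry age, grade, sex) cell the predicted age at death
#' must be non-decreasing in the percentile; printed tables occasionally
#' carry transposed cells, which this check flags rather than corrects.
#'
#' @param tab a `percentile_table`.
#' @return data.frame of offending (entry_age, grade, sex) combinations
#'   (zero rows when the table is monotone).
#' @export
validatePercentileTable <- function(tab) {
  stopifnot(inherits(tab, "percentile_table"))
  key <- interaction(tab$entry_age, tab$grade, tab$sex, drop = TRUE)
  bad <- lapply(split(tab, key), function(d) {
    d <- d[order(d$percentile), ]
    if (any(diff(d$age_death) < 0, na.rm = TRUE))
      unique(d[, c("entry_age", "grade", "sex")]) else NULL
  })
  out <- do.call(rbind, bad)
  if (is.null(out))
    out <- data.frame(entry_age = numeric(), grade = character(),
                      sex = character())
  rownames(out) <- NULL
  out
}

#' Read a percentile table from CSV
#'
#' Expects columns `entry_age`, `percentile`, `grade`, `sex`,
#' `age_death` (and optionally `saturated`); `percentile` may be given
#' as a fraction (0.5) or percent (50).
#'
#' @param path CSV file.
#' @param anchor anchor date attribute to attach.
#' @return a `percentile_table`.
#' @export
readPercentileTable <- function(path, anchor = 1965.0) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("entry_age", "percentile", "grade", "sex", "age_death")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("percentile table missing columns: ",
                         paste(miss, collapse = ", "))
  if (max(tab$percentile) > 1) tab$percentile <- tab$percentile / 100
  if (!"saturated" %in% names(tab)) tab$saturated <- FALSE
  attr(tab, "anchor") <- anchor
  class(tab) <- c("percentile_table", "data.frame")
  tab
}

percentile_cell <- function(tab, grade, sex, entry_age, percentile) {
  i <- tab$grade == grade & tab$sex == sex &
    abs(tab$entry_age - entry_age) < 1e-9 &
    abs(tab$percentile - percentile) < 1e-9
  if (sum(i) != 1) stop(sprintf("no unique cell for (%s, %s, age %s, p %s)",
                                grade, sex, entry_age, percentile))
  if (isTRUE(tab$saturated[i]) || is.na(tab$age_death[i]))
    stop("cell is saturated/flagged; contrast refused")
  tab$age_death[i]
}

#' Median years of life lost relative to never smoking
#'
#' The never-smoked median predicted age at death minus the grade's
#' median, within the same sex and entry age; reported to 1 decimal
#' place.  Uses medians only, so flagged extreme-percentile cells do
#' not affect it.
#'
#' @param tab a `percentile_table`.
#' @param grade smoking grade to contrast against never.
#' @param sex `"male"` or `"female"`.
#' @param entry_age age at the anchor date (default 45).
#' @return years of life lost, rounded to 1 decimal.
#' @export
yearsOfLifeLost <- function(tab, grade, sex, entry_age = 45) {
  ref <- percentile_cell(tab, "never", sex, entry_age, 0.5)
  grd <- percentile_cell(tab, grade, sex, entry_age, 0.5)
  round(ref - grd, 1)
}

#' Gender gap in median years of life lost
#'
#' Female years of life lost minus male years of life lost for the same
#' grade and entry age.  Each sex's value is rounded to 1 decimal place
#' before differencing, matching how such contrasts are quoted from
#' published per-sex figures.
#'
#' @inheritParams yearsOfLifeLost
#' @return difference in years, to 1 decimal.
#' @export
genderYllGap <- function(tab, grade, entry_age = 45) {
  round(yearsOfLifeLost(tab, grade, "female", entry_age) -
          yearsOfLifeLost(tab, grade, "male", entry_age), 1)
}

#' Predicted cumulative mortality on the attained-age scale
#'
#' The mortality curve for a scenario: at attained age `a`, the
#' probability of having died is
#' `1 - exp(-lambda * Lambda*(a - entry)^k * exp(x'beta))`, where
#' `Lambda*` is the expected cumulative hazard along the scenario's
#' Lexis diagonal from the anchor.
#'
#' @inheritParams residualLifetimeTable
#' @param entry_age single age at the anchor date.
#' @param sex,grade scenario.
#' @param ages attained-age grid (defaults to entry age to 100 by 0.5).
#' @return data.frame with columns `age`, `mortality_pct`.
#' @export
mortalityCurve <- function(fit, table, anchor = 1965.0, entry_age = 45,
                           sex = "male", grade = "never", ages = NULL) {
  if (is.null(fit$shape)) stop("mortalityCurve needs a parametric fit")
  if (is.null(ages)) ages <- seq(entry_age, 100, by = 0.5)
  if (any(ages < entry_age)) stop("attained ages must be >= entry age")
  z <- cumulativeHazard(table, lexisPosition(sex, entry_age, anchor),
                        ages - entry_age)
  lp <- sum(fit$coefficients * scenarioCovariates(fit, grade, sex))
  mort <- 1 - exp(-fit$rate * z^fit$shape * exp(lp))
  data.frame(age = ages, mortality_pct = 100 * mort)
}
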