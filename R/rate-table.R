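#' Population mortality rate table on an age x calendar-year grid
#'
#' A rate table holds sex-specific central mortality rates (deaths per
#' person-year) indexed by single year of age (rows) and single calendar
#' year (columns).  It is the reference surface against which observed
#' survival is measured: a subject's expected cumulative hazard is the
#' integral of these rates along the diagonal of the Lexis diagram, age
#' and calendar time advancing together from the point of entry.
#'
#' Extrapolation policy (all configurable via `extrapolation`):
#' * calendar years outside the grid reuse the nearest edge column;
#' * ages above the top of the grid are extended log-linearly (a Gompertz
#'   tail fitted to the top `fit_ages` ages of each column), capped at
#'   `cap` deaths per person-year, up to age `max_age`;
#' * with `extrapolate = FALSE` any query off the grid is an error naming
#'   the missing cell.
#'
#' @param rates named list of numeric matrices, one per sex (`"male"`,
#'   `"female"`), each `length(ages)` x `length(years)`, all entries
#'   finite and non-negative.
#' @param ages integer vector of ages, strictly increasing by 1.
#' @param years integer vector of calendar years, strictly increasing by 1.
#' @param cause label of the cause of death the rates refer to
#'   (default `"all-cause"`).
#' @param extrapolation list with elements `extrapolate` (logical),
#'   `max_age`, `cap`, `fit_ages`.
#' @return an object of class `rate_table`.
#' @seealso [cumulativeHazard()], [readRateTable()]
#' @export
rateTable <- function(rates, ages, years, cause = "all-cause",
                      extrapolation = list()) {
  if (!is.list(rates) || is.null(names(rates)) || any(names(rates) == ""))
    stop("'rates' must be a named list of matrices, one per sex")
  ages <- as.integer(ages); years <- as.integer(years)
  if (length(ages) < 1L || any(diff(ages) != 1L))
    stop("age axis must be strictly increasing with unit step")
  if (length(years) < 1L || (length(years) > 1L && any(diff(years) != 1L)))
    stop("year axis must be strictly increasing with unit step")
  for (sx in names(rates)) {
    m <- rates[[sx]]
    if (!is.matrix(m) || nrow(m) != length(ages) || ncol(m) != length(years))
      stop(sprintf("rates[['%s']] must be a %d x %d matrix", sx,
                   length(ages), length(years)))
    if (any(!is.finite(m)) || any(m < 0))
      stop(sprintf("rates[['%s']] contains negative or non-finite rates", sx))
    dimnames(m) <- list(ages, years)
    storage.mode(m) <- "double"
    rates[[sx]] <- m
  }
  ex <- utils::modifyList(
    list(extrapolate = TRUE, max_age = 130L, cap = 1.0, fit_ages = 10L),
    extrapolation)
  obj <- structure(
    list(rates = rates, ages = ages, years = years, cause = cause,
         extrapolation = ex),
    class = "rate_table")
  obj$extended <- if (ex$extrapolate) lapply(rates, extend_ages, ages = ages,
                                             ex = ex) else NULL
  obj
}

# Gompertz (log-linear in age) extension of each column above the top age,
# fitted to the top ex$fit_ages ages, capped at ex$cap.
extend_ages <- function(m, ages, ex) {
  amax <- ages[length(ages)]
  if (ex$max_age <= amax) return(m)
  k <- min(ex$fit_ages, nrow(m))
  idx <- seq.int(nrow(m) - k + 1L, nrow(m))
  x <- ages[idx]
  xc <- x - mean(x)
  logm <- log(pmax(m[idx, , drop = FALSE], 1e-12))
  slope <- colSums(xc * logm) / sum(xc^2)
  inter <- colMeans(logm)                      # value at mean(x)
  new_ages <- seq.int(amax + 1L, ex$max_age)
  pred <- exp(outer(new_ages - mean(x), slope) +
                rep(inter, each = length(new_ages)))
  pred <- pmin(pred, ex$cap)
  out <- rbind(m, pred)
  dimnames(out) <- list(c(ages, new_ages), colnames(m))
  out
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("Rate table (%s): ages %d-%d, years %d-%d, sexes: %s\n",
              x$cause, x$ages[1], x$ages[length(x$ages)],
              x$years[1], x$years[length(x$years)],
              paste(names(x$rates), collapse = ", ")))
  if (x$extrapolation$extrapolate)
    cat(sprintf("  extrapolation: edge years reused; Gompertz tail to age %d, cap %.2g/yr\n",
                x$extrapolation$max_age, x$extrapolation$cap))
  else
    cat("  extrapolation: disabled (off-grid queries are errors)\n")
  invisible(x)
}

#' Lexis entry coordinates
#'
#' Bundles the coordinates from which follow-up is measured: sex, exact
#' (fractional) age at entry and the calendar date of entry in decimal
#' years (365.25-day year).  All arguments recycle to a common length.
#'
#' @param sex character, must name a sex present in the rate table used.
#' @param age age at entry in years, fractional allowed, `>= 0`.
#' @param year calendar date at entry in decimal years (e.g. `1966.5`).
#' @return a `data.frame` of class `lexis_position`.
#' @export
lexisPosition <- function(sex, age, year) {
  n <- max(length(sex), length(age), length(year))
  pos <- data.frame(sex = rep_len(as.character(sex), n),
                    age = rep_len(as.numeric(age), n),
                    year = rep_len(as.numeric(year), n))
  if (any(!is.finite(pos$age)) || any(pos$age < 0))
    stop("entry age must be finite and >= 0")
  if (any(!is.finite(pos$year)))
    stop("entry year must be finite")
  class(pos) <- c("lexis_position", "data.frame")
  pos
}

rate_matrix_for <- function(table, sex) {
  if (table$extrapolation$extrapolate) {
    m <- table$extended[[sex]]
  } else m <- table$rates[[sex]]
  if (is.null(m))
    stop(sprintf("rate table has no rates for sex '%s'", sex))
  m
}

# locate the first off-grid cell for a helpful error message
off_grid_error <- function(table, sex, a0, y0, t) {
  for (i in seq_along(a0)) {
    ages <- floor(a0[i] + c(0, seq_len(ceiling(t[i]))))
    yrs <- floor(y0[i] + c(0, seq_len(ceiling(t[i]))))
    bad_a <- ages[ages < table$ages[1] | ages > table$ages[length(table$ages)]]
    bad_y <- yrs[yrs < table$years[1] | yrs > table$years[length(table$years)]]
    if (length(bad_a) || length(bad_y))
      stop(sprintf(
        "rate table does not cover (sex=%s, age=%s, year=%s) and extrapolation is disabled",
        sex, if (length(bad_a)) bad_a[1] else floor(a0[i]),
        if (length(bad_y)) bad_y[1] else floor(y0[i])), call. = FALSE)
  }
  stop("query outside rate table span", call. = FALSE)
}

#' Expected cumulative hazard along the Lexis diagonal
#'
#' Integrates the reference-population hazard from the entry coordinates
#' for `t` years of follow-up, age and calendar time advancing together.
#' The hazard is piecewise constant within each 1-year-age x
#' 1-calendar-year cell, so the integral is continuous, non-decreasing
#' and piecewise linear in `t`, with breaks at the subject's fractional
#' birthdays and at new year.
#'
#' @param table a [rateTable()].
#' @param pos a [lexisPosition()] (or data.frame with columns `sex`,
#'   `age`, `year`); recycled against `t`.
#' @param t follow-up time in years, `>= 0`.
#' @return numeric vector of expected cumulative hazards (dimensionless).
#' @export
cumulativeHazard <- function(table, pos, t) {
  stopifnot(inherits(table, "rate_table"))
  pos <- as.data.frame(pos)
  n <- max(nrow(pos), length(t))
  a0 <- rep_len(pos$age, n); y0 <- rep_len(pos$year, n)
  sx <- rep_len(pos$sex, n); t <- rep_len(as.numeric(t), n)
  if (any(t < 0)) stop("follow-up time must be >= 0")
  ok <- table$extrapolation$extrapolate
  out <- numeric(n)
  for (s in unique(sx)) {
    i <- which(sx == s)
    m <- rate_matrix_for(table, s)
    h <- cpp_lexis_cumhaz(m, as.integer(rownames(m)[1]), table$years[1],
                          a0[i], y0[i], t[i], clamp_age = ok,
                          clamp_year = ok)
    if (anyNA(h)) {
      j <- i[which(is.na(h))[1]]
      off_grid_error(table, s, a0[j], y0[j], t[j])
    }
    out[i] <- h
  }
  out
}

#' Expected survival along the Lexis diagonal
#'
#' `exp(-cumulativeHazard(...))`: the survival a subject would have if
#' they died at exactly the reference-population rates for their sex,
#' age and era.
#'
#' @inheritParams cumulativeHazard
#' @return numeric vector in (0, 1].
#' @export
expectedSurvival <- function(table, pos, t) {
  exp(-cumulativeHazard(table, pos, t))
}

#' Invert the expected cumulative hazard
#'
#' Returns the follow-up time `t` at which the expected cumulative hazard
#' from `pos` reaches `z`.  Exact inverse of [cumulativeHazard()] over the
#' same piecewise-linear segments.  When `z` is not reached before the
#' attained age hits the extrapolation ceiling the query saturates:
#' an error by default, or `NA` with `on_saturate = "NA"` (used by the
#' prediction module to flag, rather than cap, off-table percentiles).
#'
#' @inheritParams cumulativeHazard
#' @param z target cumulative hazard, `>= 0`; recycled against `pos`.
#' @param on_saturate `"error"` or `"NA"`.
#' @return numeric vector of follow-up times in years.
#' @export
invertCumulativeHazard <- function(table, pos, z,
                                   on_saturate = c("error", "NA")) {
  stopifnot(inherits(table, "rate_table"))
  on_saturate <- match.arg(on_saturate)
  pos <- as.data.frame(pos)
  n <- max(nrow(pos), length(z))
  a0 <- rep_len(pos$age, n); y0 <- rep_len(pos$year, n)
  sx <- rep_len(pos$sex, n); z <- rep_len(as.numeric(z), n)
  if (any(z < 0)) stop("target cumulative hazard must be >= 0")
  ok <- table$extrapolation$extrapolate
  ceiling_age <- if (ok) table$extrapolation$max_age + 1
                 else table$ages[length(table$ages)] + 1
  out <- numeric(n)
  for (s in unique(sx)) {
    i <- which(sx == s)
    m <- rate_matrix_for(table, s)
    out[i] <- cpp_lexis_invert(m, as.integer(rownames(m)[1]), table$years[1],
                               a0[i], y0[i], z[i], clamp_year = ok,
                               age_ceiling = ceiling_age)
  }
  if (anyNA(out) && on_saturate == "error") {
    j <- which(is.na(out))[1]
    stop(sprintf(
      "cumulative hazard %.4g not reached before attained age %.0f (sex=%s, entry age %.2f): saturated",
      z[j], ceiling_age, sx[j], a0[j]))
  }
  out
}

#' Read a rate table from delimited text
#'
#' Format: comment lines `# cause: <label>` and `# sex: <label>` introduce
#' sections; each section is a tab-delimited block whose header row is
#' `age` followed by the calendar years and whose rows are one age each.
#' All sections must share the same axes.  Malformed grids (negative
#' rates, gaps in either axis) are rejected with the offending line
#' number.
#'
#' @param path file path.
#' @param extrapolation passed to [rateTable()].
#' @return a [rateTable()].
#' @export
readRateTable <- function(path, extrapolation = list()) {
  lines <- readLines(path)
  cause <- "all-cause"
  rates <- list(); ages <- NULL; years <- NULL
  cur_sex <- NULL; cur_rows <- list(); cur_ages <- integer()
  flush_section <- function() {
    if (is.null(cur_sex)) return()
    if (!length(cur_rows)) stop(sprintf("section '%s' has no rows", cur_sex))
    m <- do.call(rbind, cur_rows)
    if (!is.null(ages)) {
      if (!identical(cur_ages, ages))
        stop(sprintf("section '%s': age axis differs from previous section",
                     cur_sex))
    } else ages <<- cur_ages
    rates[[cur_sex]] <<- m
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      if (grepl("^cause:", kv)) cause <- trimws(sub("^cause:", "", kv))
      if (grepl("^sex:", kv)) {
        flush_section()
        cur_sex <- trimws(sub("^sex:", "", kv))
        cur_rows <- list(); cur_ages <- integer()
      }
      next
    }
    fields <- strsplit(ln, "[\t ]+")[[1]]
    if (identical(fields[1], "age")) {
      yrs <- suppressWarnings(as.integer(fields[-1]))
      if (anyNA(yrs) || (length(yrs) > 1 && any(diff(yrs) != 1L)))
        stop(sprintf("line %d: year header must be consecutive integers", i))
      if (!is.null(years) && !identical(yrs, years))
        stop(sprintf("line %d: year axis differs from previous section", i))
      years <- yrs
      next
    }
    if (is.null(cur_sex)) stop(sprintf("line %d: data before any '# sex:' header", i))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) stop(sprintf("line %d: non-numeric value", i))
    if (length(vals) != length(years) + 1L)
      stop(sprintf("line %d: expected %d rate columns, found %d (missing year column?)",
                   i, length(years), length(vals) - 1L))
    if (any(vals[-1] < 0)) stop(sprintf("line %d: negative rate", i))
    a <- as.integer(vals[1])
    if (length(cur_ages) && a != cur_ages[length(cur_ages)] + 1L)
      stop(sprintf("line %d: gap in age axis (%d after %d)", i, a,
                   cur_ages[length(cur_ages)]))
    cur_ages <- c(cur_ages, a)
    cur_rows[[length(cur_rows) + 1L]] <- vals[-1]
  }
  flush_section()
  if (!length(rates)) stop("no rate sections found")
  rateTable(rates, ages, years, cause = cause, extrapolation = extrapolation)
}

#' Write a rate table to delimited text
#'
#' Inverse of [readRateTable()]: `readRateTable(writeRateTable(x, p))`
#' reproduces the rate grid exactly.
#'
#' @param table a [rateTable()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeRateTable <- function(table, path) {
  stopifnot(inherits(table, "rate_table"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# cause: %s", table$cause), con)
  for (sx in names(table$rates)) {
    writeLines(sprintf("# sex: %s", sx), con)
    writeLines(paste(c("age", table$years), collapse = "\t"), con)
    m <- table$rates[[sx]]
    for (r in seq_len(nrow(m)))
      writeLines(paste(c(table$ages[r], format(m[r, ], digits = 17,
                                               scientific = FALSE,
                                               trim = TRUE)),
                       collapse = "\t"), con)
  }
  invisible(path)
}
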