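#' Schoenfeld residuals of a Cox fit
#'
#' The raw residual at each event time is the case's covariate vector
#' minus the risk-set weighted mean covariate; at the maximum partial
#' likelihood the residuals sum to zero column-wise (the score
#' equation).  Scaled residuals premultiply the raw residual by
#' (number of events) times the coefficient covariance, approximating a
#' time-varying coefficient path.
#'
#' @param fit a `lexisurv_fit` from [fitCox()].
#' @return list with components `raw` and `scaled` (matrices, one row
#'   per event, ordered by event time), and `time` (event times on the
#'   fitted scale).
#' @export
schoenfeldResiduals <- function(fit) {
  stopifnot(inherits(fit, "lexisurv_fit"))
  if (fit$family != "cox") stop("Schoenfeld residuals need a Cox fit")
  if (fit$nevent < 2) stop("need at least 2 events")
  raw <- stats::residuals(fit$fit, type = "schoenfeld")
  raw <- as.matrix(raw)
  colnames(raw) <- names(fit$coefficients)
  tm <- as.numeric(rownames(raw))
  o <- order(tm)
  raw <- raw[o, , drop = FALSE]
  d <- nrow(raw)
  scaled <- d * raw %*% fit$vcov
  colnames(scaled) <- colnames(raw)
  list(raw = raw, scaled = scaled, time = tm[o])
}

#' Proportional-hazards test by residual-time correlation
#'
#' For each covariate, the Pearson correlation coefficient rho between
#' its scaled Schoenfeld residuals and the transformed survival times at
#' the events, with a p-value from the t-approximation on
#' (events - 2) degrees of freedom.  Under proportional hazards rho is
#' near zero; a systematic trend of the residuals with time signals a
#' hazard ratio that changes over the transformed time scale.
#'
#' @param resids a [schoenfeldResiduals()] result, or a Cox
#'   `lexisurv_fit` (residuals are computed internally).
#' @param time_transform `"identity"` (default: correlate with the
#'   transformed times themselves) or `"rank"`.
#' @return data.frame of class `ph_test` with columns `term`, `rho`,
#'   `p`, `n_events`.
#' @export
phTest <- function(resids, time_transform = c("identity", "rank")) {
  time_transform <- match.arg(time_transform)
  if (inherits(resids, "lexisurv_fit")) resids <- schoenfeldResiduals(resids)
  s <- resids$scaled
  tt <- resids$time
  if (nrow(s) != length(tt)) stop("residual matrix and event times do not conform")
  if (time_transform == "rank") tt <- rank(tt)
  d <- nrow(s)
  rho <- rep(NA_real_, ncol(s)); p <- rep(NA_real_, ncol(s))
  for (j in seq_len(ncol(s))) {
    if (stats::sd(s[, j]) == 0 || stats::sd(tt) == 0) {
      warning(sprintf("zero-variance residuals for '%s': rho undefined",
                      colnames(s)[j]))
      next
    }
    r <- stats::cor(s[, j], tt)
    rho[j] <- r
    tstat <- r * sqrt((d - 2) / max(1 - r^2, .Machine$double.eps))
    p[j] <- 2 * stats::pt(-abs(tstat), df = d - 2)
  }
  out <- data.frame(term = colnames(s), rho = rho, p = p, n_events = d,
                    row.names = NULL)
  class(out) <- c("ph_test", "data.frame")
  out
}
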