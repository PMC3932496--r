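#' @importFrom survival coxph Surv coxph.control survreg survreg.control
#' @importFrom stats pnorm pt cor qnorm sd quantile rexp runif rbinom rnorm
NULL

# cheap fingerprint tying a fit to its data, for compareModels()
data_fingerprint <- function(time, event, X) {
  signif(c(length(time), sum(time), sum(time^2), sum(event),
           ncol(X), sum(X), sum(X^2)), 12)
}

wald_table <- function(beta, se, rrr_terms) {
  data.frame(term = names(beta),
             estimate = unname(beta),
             se = unname(se),
             hr = exp(unname(beta)),
             lo = exp(unname(beta) - 1.96 * unname(se)),
             hi = exp(unname(beta) + 1.96 * unname(se)),
             p = 2 * pnorm(-abs(unname(beta) / unname(se))),
             rrr = names(beta) %in% rrr_terms,
             row.names = NULL)
}

new_fit_result <- function(family, beta, vcov, loglik, table, rrr_terms,
                           scale, fingerprint, shape = NULL, rate = NULL,
                           fit = NULL, n = NA, nevent = NA) {
  structure(list(family = family, coefficients = beta, vcov = vcov,
                 loglik = loglik, table = table, rrr_terms = rrr_terms,
                 scale = scale, fingerprint = fingerprint, shape = shape,
                 rate = rate, fit = fit, n = n, nevent = nevent),
            class = "lexisurv_fit")
}

#' @export
print.lexisurv_fit <- function(x, ...) {
  cat(sprintf("%s proportional-hazards fit on the %s scale: %d subjects, %d events\n",
              x$family, toupper(x$scale), x$n, x$nevent))
  if (!is.null(x$shape))
    cat(sprintf("  shape k = %.4f, baseline rate lambda = %.4g\n",
                x$shape, x$rate))
  tab <- x$table
  tab$estimate <- NULL; tab$se <- NULL
  tab[-1] <- lapply(tab[-1], function(v) if (is.numeric(v)) round(v, 3) else v)
  print(tab, row.names = FALSE)
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' Cox regression of individual relative-survival times
#'
#' Fits Cox's proportional-hazards model to the transformed times with
#' the supplied design matrix.  Because the partial likelihood depends
#' on the time axis only through ranks, and Y and Z are related by a
#' strictly increasing map, fitting on either scale gives identical
#' coefficients.
#'
#' @param records a [transformCohort()] result (columns `y`, `z`,
#'   `event`).
#' @param X design matrix from [buildDesign()] (any numeric matrix with
#'   column names works).
#' @param scale `"z"` (default) or `"y"`: which transformed time to use.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param eps,iter.max convergence tolerance and iteration cap.
#' @return a fit object of class `lexisurv_fit` carrying coefficients,
#'   covariance, partial log-likelihood and a Wald hazard-ratio table
#'   with RRR rows flagged.
#' @export
fitCox <- function(records, X, scale = c("z", "y"),
                   ties = c("efron", "breslow"), eps = 1e-12,
                   iter.max = 100) {
  scale <- match.arg(scale); ties <- match.arg(ties)
  X <- as.matrix(X)
  if (sum(records$event) < 1) stop("no events to fit")
  time <- records[[scale]]
  dat <- data.frame(.time = time, .event = records$event, X,
                    check.names = FALSE)
  fml <- stats::as.formula(paste(
    "Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- withCallingHandlers(
    coxph(fml, data = dat, ties = ties,
          control = coxph.control(eps = eps, iter.max = iter.max)),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        stop("Cox fit diverged (monotone likelihood / separation): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("design matrix is rank deficient; collinear columns: ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  names(beta) <- colnames(X)
  V <- stats::vcov(fit)
  dimnames(V) <- list(colnames(X), colnames(X))
  rrr <- attr(X, "rrr_terms")
  new_fit_result("cox", beta, V, fit$loglik[2],
                 wald_table(beta, sqrt(diag(V)), rrr), rrr, scale,
                 data_fingerprint(time, records$event, X),
                 fit = fit, n = nrow(X), nevent = sum(records$event))
}

#' Weibull proportional-hazards regression of the Z-scale times
#'
#' Fits the fully parametric model with hazard
#' `h(z | x) = k * lambda * z^(k-1) * exp(x'beta)` to the Z-scale
#' transformed times, so `exp(beta)` are hazard ratios directly
#' comparable with the Cox fit.  The censored likelihood is maximised by
#' [survival::survreg()] in its accelerated-failure-time
#' parameterisation and re-expressed in proportional-hazards form
#' (`k = 1/sigma`, `beta = -gamma/sigma`, `log lambda = -mu/sigma`) with
#' a delta-method covariance.  `shape_fixed = 1` gives the exponential
#' model.
#'
#' @inheritParams fitCox
#' @param shape_fixed fix the Weibull shape (e.g. 1 for exponential);
#'   `NULL` (default) estimates it.
#' @return a `lexisurv_fit` with `shape` (k) and `rate` (lambda) filled
#'   in and the full log-likelihood.
#' @export
fitWeibull <- function(records, X, shape_fixed = NULL, eps = 1e-10,
                       iter.max = 100) {
  X <- as.matrix(X)
  if (sum(records$event) < 1) stop("no events to fit")
  time <- records$z   # parametric family is defined on the Z scale only
  if (any(time <= 0)) stop("Z-scale times must be positive")
  dat <- data.frame(.time = time, .event = records$event, X,
                    check.names = FALSE)
  rhs <- if (ncol(X)) paste(sprintf("`%s`", colnames(X)), collapse = " + ")
         else "1"
  fml <- stats::as.formula(paste("Surv(.time, .event) ~", rhs))
  exponential <- !is.null(shape_fixed) && abs(shape_fixed - 1) < 1e-12
  args <- list(fml, data = dat,
               dist = if (exponential) "exponential" else "weibull",
               control = survreg.control(rel.tolerance = eps,
                                         iter.max = iter.max))
  if (!is.null(shape_fixed) && !exponential)
    args$scale <- 1 / shape_fixed
  fit <- do.call(survreg, args)
  if (!is.null(fit$iter) && fit$iter >= iter.max)
    stop("Weibull fit did not converge within iteration cap")
  mu <- fit$coefficients[1]
  gam <- fit$coefficients[-1]
  sigma <- fit$scale
  k <- 1 / sigma
  beta <- -gam / sigma
  names(beta) <- colnames(X)
  lambda <- exp(-mu / sigma)
  Vs <- fit$var
  p <- length(gam)
  free_scale <- is.null(shape_fixed)
  # delta method to (log lambda, beta, [log k]); survreg params are
  # (mu, gamma, [log sigma])
  d <- if (free_scale) p + 2L else p + 1L
  J <- matrix(0, nrow = if (free_scale) p + 2L else p + 1L, ncol = d)
  J[1, 1] <- -1 / sigma                     # d loglambda / d mu
  for (j in seq_len(p)) J[1 + j, 1 + j] <- -1 / sigma
  if (free_scale) {
    J[1, d] <- mu / sigma                   # d loglambda / d log sigma
    for (j in seq_len(p)) J[1 + j, d] <- gam[j] / sigma
    J[p + 2L, d] <- -1                      # d log k / d log sigma
  }
  Vt <- J %*% Vs %*% t(J)
  nm <- c("log_lambda", colnames(X), if (free_scale) "log_shape")
  dimnames(Vt) <- list(nm, nm)
  Vbeta <- Vt[colnames(X), colnames(X), drop = FALSE]
  rrr <- attr(X, "rrr_terms")
  res <- new_fit_result("weibull", beta, Vbeta, fit$loglik[2],
                        wald_table(beta, sqrt(diag(Vbeta)), rrr), rrr, "z",
                        data_fingerprint(time, records$event, X),
                        shape = unname(k), rate = unname(lambda),
                        fit = fit, n = nrow(X),
                        nevent = sum(records$event))
  res$vcov_full <- Vt
  res$family <- if (exponential) "exponential" else "weibull"
  res$npar <- length(beta) + if (free_scale) 2L else 1L
  res
}

#' Female-to-male relative risk ratios from a fit
#'
#' The RRR for a smoking grade is the ratio of the female
#' smoker-vs-never hazard ratio to the male smoker-vs-never hazard
#' ratio; with the interaction design of [buildDesign()] it is exactly
#' the exponentiated gender-by-grade interaction coefficient.
#'
#' @param fit a `lexisurv_fit` from [fitCox()] or [fitWeibull()].
#' @return data.frame with one row per RRR: estimate, 95% Wald CI, p.
#' @export
extractRRR <- function(fit) {
  stopifnot(inherits(fit, "lexisurv_fit"))
  if (is.null(fit$rrr_terms) || !length(fit$rrr_terms))
    stop("fit has no interaction (RRR) columns")
  missing <- setdiff(fit$rrr_terms, names(fit$coefficients))
  if (length(missing)) stop("fit is missing interaction columns: ",
                            paste(missing, collapse = ", "))
  tab <- fit$table[fit$table$rrr, c("term", "hr", "lo", "hi", "p")]
  names(tab)[2] <- "rrr"
  tab$grade <- sub("^female_", "", tab$term)
  rownames(tab) <- NULL
  tab
}

#' Rank fitted models by log-likelihood
#'
#' All fits must come from the same data (checked by fingerprint).
#' Ties in log-likelihood are broken in favour of fewer parameters,
#' keeping input order among exact ties.
#'
#' @param fits list of `lexisurv_fit` objects sharing data and design.
#' @return data.frame ranked best-first: family, log-likelihood,
#'   number of parameters.
#' @export
compareModels <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  fps <- lapply(fits, function(f) f$fingerprint)
  for (i in seq_along(fps)[-1])
    if (!isTRUE(all.equal(fps[[1]], fps[[i]], tolerance = 1e-8)))
      stop("fits were not computed on the same data (fingerprint mismatch)")
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  np <- vapply(fits, function(f)
    if (!is.null(f$npar)) f$npar else length(f$coefficients), numeric(1))
  fam <- vapply(fits, function(f) f$family, character(1))
  ord <- order(-ll, np, seq_along(fits))
  data.frame(rank = seq_along(fits), family = fam[ord],
             loglik = ll[ord], npar = np[ord],
             index = ord, row.names = NULL)
}
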