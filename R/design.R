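#' Smoking grade from baseline cigarettes per day
#'
#' Grades consumption reported at the baseline examination:
#' never (0), light (1-14), medium (15-24), heavy (25 or more cigarettes
#' per day); a set `former` flag overrides the count.
#'
#' @param cpd non-negative integer count of cigarettes per day.
#' @param former logical, ex-smoker at baseline.
#' @return factor with levels never, light, medium, heavy, former.
#' @export
gradeFromCpd <- function(cpd, former = FALSE) {
  n <- max(length(cpd), length(former))
  cpd <- rep_len(cpd, n); former <- rep_len(as.logical(former), n)
  if (any(!is.finite(cpd)) || any(cpd < 0) || any(cpd != round(cpd)))
    stop("cigarettes per day must be a non-negative integer")
  g <- ifelse(former, "former",
       ifelse(cpd == 0, "never",
       ifelse(cpd <= 14, "light",
       ifelse(cpd <= 24, "medium", "heavy"))))
  factor(g, levels = smokingGrades())
}

#' @rdname gradeFromCpd
#' @export
smokingGrades <- function() c("never", "light", "medium", "heavy", "former")

#' Lung-function covariates on the per-10%-decrease scale
#'
#' `fev1_deficit = (100 - FEV1\% predicted) / 10`: 0 at 100% of the
#' predicted value, 1 at 90%, so the fitted hazard ratio reads as the
#' effect of a 10% reduction in FEV1 % predicted.
#' `ratio_deficit` scores the FEV1/FVC ratio the same way.  With the
#' default `ratio_sign = "interpretation"` it is
#' `(100 - 100 * FEV1/FVC) / 10`, i.e. +1 when FEV1 is 90% of FVC, so a
#' hazard ratio above 1 means reduced lung function increases mortality;
#' `"printed"` selects the opposite sign convention
#' `(100 * FEV1/FVC - 100) / 10`.
#'
#' @param fev1_pct_pred FEV1 as % of predicted, > 0.
#' @param fev1,fvc litres; `fvc > 0`, `0 < fev1 <= 1.1 * fvc` (small
#'   margin for measurement noise).
#' @param ratio_sign `"interpretation"` (default) or `"printed"`.
#' @return data.frame with columns `fev1_deficit`, `ratio_deficit`.
#' @export
lungCovariates <- function(fev1_pct_pred, fev1, fvc,
                           ratio_sign = c("interpretation", "printed")) {
  ratio_sign <- match.arg(ratio_sign)
  if (any(fvc <= 0) || any(fev1 <= 0) || any(fev1_pct_pred <= 0))
    stop("lung-function inputs must be positive")
  if (any(fev1 > 1.1 * fvc))
    stop("FEV1 exceeds FVC by more than the 10% measurement margin")
  rd <- (100 - 100 * fev1 / fvc) / 10
  if (ratio_sign == "printed") rd <- -rd
  data.frame(fev1_deficit = (100 - fev1_pct_pred) / 10, ratio_deficit = rd)
}

#' Build the regression design matrix
#'
#' Columns, in order: smoking-grade indicators relative to never-smokers;
#' the female indicator; the gender-by-grade interaction indicators whose
#' exponentiated coefficients are the female-to-male, smoker-to-never
#' relative risk ratios (RRRs); then any confounders.  Two interaction
#' parameterisations are supported: `"rrr4"` (light, medium, heavy,
#' former — 4 RRRs) and `"rrr3"`, which pools medium and heavy smokers
#' into one grade before forming interactions (used when events are
#' sparse, as in cause-specific analyses).
#'
#' Confounder sets: `"full"` = byssinosis, cough & phlegm, decades in
#' industry, and both lung-function covariates; `"no_lung"` drops the two
#' lung-function terms; `"none"` drops all confounders (grade + gender +
#' RRRs only).
#'
#' @param cohort data.frame with columns `smoking_grade` (or
#'   `smoking_cpd` + optional `former`), `sex`, and — for the confounder
#'   sets that need them — `byssinosis`, `cough_phlegm`,
#'   `years_in_industry`, `fev1_pct_pred`, `fev1`, `fvc`, `height_cm`.
#' @param scheme `"rrr4"` or `"rrr3"`.
#' @param confounders `"full"`, `"no_lung"` or `"none"`.
#' @param log_height add log(height) as an allometric size covariate.
#' @param ratio_sign passed to [lungCovariates()].
#' @return numeric matrix with attributes `scheme` and `rrr_terms`
#'   (the interaction column names).
#' @export
buildDesign <- function(cohort, scheme = c("rrr4", "rrr3"),
                        confounders = c("full", "no_lung", "none"),
                        log_height = FALSE,
                        ratio_sign = c("interpretation", "printed")) {
  scheme <- match.arg(scheme)
  confounders <- match.arg(confounders)
  ratio_sign <- match.arg(ratio_sign)
  cohort <- as.data.frame(cohort)
  if (!"smoking_grade" %in% names(cohort)) {
    if (!"smoking_cpd" %in% names(cohort))
      stop("cohort needs 'smoking_grade' or 'smoking_cpd'")
    cohort$smoking_grade <- gradeFromCpd(
      cohort$smoking_cpd,
      if ("former" %in% names(cohort)) cohort$former else FALSE)
  }
  g <- as.character(cohort$smoking_grade)
  if (any(!g %in% smokingGrades()))
    stop("unknown smoking grade: ",
         paste(setdiff(unique(g), smokingGrades()), collapse = ", "))
  female <- as.numeric(cohort$sex == "female")
  if (scheme == "rrr3") {
    gp <- ifelse(g %in% c("medium", "heavy"), "medheavy", g)
    glev <- c("light", "medheavy", "former")
  } else {
    gp <- g
    glev <- c("light", "medium", "heavy", "former")
  }
  grade_cols <- matrix(0, nrow(cohort), length(glev),
                       dimnames = list(NULL, glev))
  for (l in glev) grade_cols[, l] <- as.numeric(gp == l)
  inter <- grade_cols * female
  colnames(inter) <- paste0("female_", glev)
  X <- cbind(grade_cols, female = female, inter)
  empty <- colnames(inter)[colSums(inter) == 0]
  if (length(empty))
    warning("non-estimable RRR (empty interaction cell): ",
            paste(empty, collapse = ", "))
  if (confounders != "none") {
    need <- c("byssinosis", "cough_phlegm", "years_in_industry")
    miss <- setdiff(need, names(cohort))
    if (length(miss)) stop("cohort is missing confounders: ",
                           paste(miss, collapse = ", "))
    X <- cbind(X,
               byssinosis = as.numeric(cohort$byssinosis),
               cough_phlegm = as.numeric(cohort$cough_phlegm),
               decades_industry = cohort$years_in_industry / 10)
    if (confounders == "full") {
      lc <- lungCovariates(cohort$fev1_pct_pred, cohort$fev1, cohort$fvc,
                           ratio_sign = ratio_sign)
      X <- cbind(X, fev1_deficit = lc$fev1_deficit,
                 ratio_deficit = lc$ratio_deficit)
    }
  }
  if (isTRUE(log_height)) {
    if (!"height_cm" %in% names(cohort)) stop("cohort is missing 'height_cm'")
    X <- cbind(X, log_height = log(cohort$height_cm))
  }
  rownames(X) <- if ("id" %in% names(cohort)) as.character(cohort$id) else NULL
  attr(X, "scheme") <- scheme
  attr(X, "rrr_terms") <- colnames(inter)
  X
}
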