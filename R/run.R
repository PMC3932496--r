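#' Read a run configuration from YAML
#'
#' Keys: `rates` (path, or a list of per-cause paths), `cohort` (path),
#' `out` (output directory), `causes` (labels to analyse; default
#' all-cause only), `model` (`cox`/`weibull`/`both`), `scheme`
#' (`rrr4`/`rrr3`), `confounders` (`full`/`no_lung`/`none`),
#' `log_height`, `ratio_sign`, `predict` (list: `anchor`, `entry_ages`,
#' `grades`, `percentiles`, `curve_age`), `seed`.
#'
#' @param path YAML file.
#' @return named list (class `run_config`).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Read a cohort file
#'
#' Delimited text, one row per subject; required columns `id`, `sex`,
#' `entry_age`, `entry_year`, `followup_years`, `status`, plus `cause`
#' for deaths and whichever covariates the design needs (`smoking_grade`
#' or `smoking_cpd`, `byssinosis`, `cough_phlegm`, `years_in_industry`,
#' `fev1_pct_pred`, `fev1`, `fvc`, `height_cm`).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readCohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a cohort file
#'
#' @param cohort data.frame of subjects.
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

fmt_num <- function(x, digits) formatC(round(x, digits), format = "f",
                                       digits = digits)

# presentation table: HR/RRR to 2 dp, p to 3 dp, rho appended when given
presentation_table <- function(fit, ph = NULL) {
  tab <- fit$table
  out <- data.frame(term = tab$term,
                    hr = fmt_num(tab$hr, 2),
                    ci_low = fmt_num(tab$lo, 2),
                    ci_high = fmt_num(tab$hi, 2),
                    p = fmt_num(tab$p, 3),
                    rrr = ifelse(tab$rrr, "yes", ""))
  if (!is.null(ph)) {
    m <- match(out$term, ph$term)
    out$rho <- ifelse(is.na(m), "", fmt_num(ph$rho[m], 3))
    out$rho_p <- ifelse(is.na(m), "", fmt_num(ph$p[m], 3))
  }
  out
}

#' Run a full analysis from a configuration
#'
#' Orchestrates transform, fit, diagnose and predict for each requested
#' cause of death, writing to the output directory: per-cause
#' coefficient tables (with the proportional-hazards rho/P columns
#' appended for the Cox fit), RRR tables, a residual-lifetime percentile
#' table and mortality curves (Weibull runs), a run log, and a
#' full-precision JSON sidecar.  Outputs are deterministic given the
#' inputs.
#'
#' @param config a `run_config` list (see [readRunConfig()]); paths may
#'   also be passed pre-loaded as `rates_table` (a [rateTable()] or
#'   named list of them) and `cohort_data`.
#' @return invisibly, a list of per-cause results (fits, RRR tables,
#'   diagnostics, predictions).
#' @export
runAnalysis <- function(config) {
  cfg <- utils::modifyList(
    list(causes = "all-cause", model = "both", scheme = "rrr4",
         confounders = "full", log_height = FALSE,
         ratio_sign = "interpretation",
         predict = list(anchor = 1965.0, entry_ages = c(25, 45, 65),
                        grades = c("never", "light", "medium", "heavy"),
                        percentiles = c(0.05, 0.5, 0.95),
                        curve_age = 45)),
    unclass(config))
  out_dir <- cfg$out
  if (is.null(out_dir)) stop("config needs an 'out' directory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  cohort <- if (!is.null(cfg$cohort_data)) cfg$cohort_data
            else readCohort(cfg$cohort)
  tables <- if (!is.null(cfg$rates_table)) {
    if (inherits(cfg$rates_table, "rate_table"))
      stats::setNames(list(cfg$rates_table), cfg$rates_table$cause)
    else cfg$rates_table
  } else if (is.character(cfg$rates) && length(cfg$rates) == 1 &&
             is.null(names(cfg$rates))) {
    tb <- readRateTable(cfg$rates)
    stats::setNames(list(tb), tb$cause)
  } else {
    lapply(cfg$rates, readRateTable)
  }
  say("lexisurv run: %d subjects, causes: %s",
      nrow(cohort), paste(cfg$causes, collapse = ", "))
  say("scheme=%s confounders=%s log_height=%s ratio_sign=%s",
      cfg$scheme, cfg$confounders, cfg$log_height, cfg$ratio_sign)

  results <- list()
  sidecar <- list()
  for (cause in cfg$causes) {
    tb <- tables[[cause]]
    if (is.null(tb) && cause == "all-cause") tb <- tables[[1]]
    if (is.null(tb)) stop(sprintf("no rate table for cause '%s'", cause))
    tc <- transformCohort(cohort, tb, cause = cause)
    acct <- followupAccounting(tc)
    say("[%s] events: %d / %d", cause, sum(tc$event), acct[["n"]])
    X <- withCallingHandlers(
      buildDesign(cohort, scheme = cfg$scheme,
                  confounders = cfg$confounders,
                  log_height = isTRUE(cfg$log_height),
                  ratio_sign = cfg$ratio_sign),
      warning = function(w) {
        say("[%s] warning: %s", cause, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    res <- list(cause = cause, accounting = acct)
    fit_cox <- cfg$model %in% c("cox", "both")
    fit_wei <- cfg$model %in% c("weibull", "both")
    if (fit_cox) {
      fc <- fitCox(tc, X)
      ph <- phTest(fc)
      res$cox <- fc; res$ph <- ph
      res$rrr_cox <- extractRRR(fc)
      ptab <- presentation_table(fc, ph)
      utils::write.table(ptab, file.path(out_dir,
                                         sprintf("coefficients_cox_%s.tsv",
                                                 gsub("[^a-z0-9]+", "_",
                                                      tolower(cause)))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sidecar[[paste0("cox_", cause)]] <-
        list(coefficients = as.list(fc$coefficients),
             loglik = fc$loglik, rho = stats::setNames(
               as.list(ph$rho), ph$term))
    }
    if (fit_wei) {
      fw <- fitWeibull(tc, X)
      res$weibull <- fw
      res$rrr_weibull <- extractRRR(fw)
      utils::write.table(presentation_table(fw),
                         file.path(out_dir,
                                   sprintf("coefficients_weibull_%s.tsv",
                                           gsub("[^a-z0-9]+", "_",
                                                tolower(cause)))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sidecar[[paste0("weibull_", cause)]] <-
        list(coefficients = as.list(fw$coefficients),
             shape = fw$shape, rate = fw$rate, loglik = fw$loglik)
      if (cause == cfg$causes[1]) {
        pd <- cfg$predict
        ptab <- residualLifetimeTable(fw, tb, anchor = pd$anchor,
                                      entry_ages = pd$entry_ages,
                                      grades = pd$grades,
                                      percentiles = pd$percentiles)
        utils::write.csv(ptab, file.path(out_dir, "percentiles.csv"),
                         row.names = FALSE)
        if (any(ptab$saturated))
          say("[%s] %d saturated percentile cells flagged", cause,
              sum(ptab$saturated))
        res$percentiles <- ptab
        curves_dir <- file.path(out_dir, "curves")
        dir.create(curves_dir, showWarnings = FALSE)
        for (sx in c("male", "female")) for (g in pd$grades) {
          cv <- mortalityCurve(fw, tb, anchor = pd$anchor,
                               entry_age = pd$curve_age, sex = sx,
                               grade = g)
          utils::write.csv(cv, file.path(curves_dir,
                                         sprintf("%s_%s.csv", sx, g)),
                           row.names = FALSE)
        }
      }
    }
    # combined RRR row for the cause (Table-3-shaped output)
    rtab <- if (fit_cox) res$rrr_cox else res$rrr_weibull
    utils::write.table(
      data.frame(cause = cause, grade = rtab$grade,
                 rrr = fmt_num(rtab$rrr, 2),
                 ci_low = fmt_num(rtab$lo, 2), ci_high = fmt_num(rtab$hi, 2),
                 p = fmt_num(rtab$p, 3)),
      file.path(out_dir, sprintf("rrr_%s.tsv",
                                 gsub("[^a-z0-9]+", "_", tolower(cause)))),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results[[cause]] <- res
  }
  jsonlite::write_json(sidecar, file.path(out_dir, "full_precision.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(results)
}
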