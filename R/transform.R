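#' Individual relative-survival transformation of a cohort
#'
#' Each subject's observed follow-up time is replaced by the expected
#' cumulative hazard accumulated along their own Lexis diagonal:
#' `Z = integral of reference rates` and `Y = 1 - exp(-Z) = 1 - S*(t)`.
#' If a subject dies exactly like the reference population, Z is
#' unit-exponential and Y is uniform; departures are what the
#' proportional-hazards models downstream estimate.  Because each
#' subject is transformed with their own sex, entry age and era, the
#' transformation removes age and calendar-time effects at entry and
#' during follow-up, putting all subjects on one comparable scale.
#'
#' Follow-up is analysed to age 90: any subject whose exit lies beyond
#' attained age 90 (including deaths after 90 and late embarkations) is
#' censored at age 90 exactly, with the event indicator forced to 0.
#'
#' For a cause-specific analysis pass the cause-specific rate table and
#' the matching `cause` label: deaths from other causes are treated as
#' censored at the death time, and `Z` is computed from the
#' cause-specific rates.
#'
#' @param subjects data.frame with columns `id`, `sex`, `entry_age`,
#'   `entry_year` (decimal years), `followup_years` (> 0), `status`
#'   (one of `"death"`, `"censored"`, `"embarked"`) and, for deaths,
#'   `cause`.  Integer entry ages are taken as mid-year (`age + 0.5`).
#' @param table the [rateTable()] for the cause under analysis.
#' @param cause cause label of the analysis; defaults to the table's.
#'   `"all-cause"` counts every death as an event.
#' @param age_cap attained age at which follow-up is administratively
#'   truncated (default 90).
#' @return data.frame of class `transformed_cohort` with columns `id`,
#'   `y`, `z`, `event`, and an `"accounting"` attribute partitioning the
#'   cohort by follow-up outcome (see [followupAccounting()]).
#' @export
transformCohort <- function(subjects, table, cause = table$cause,
                            age_cap = 90) {
  stopifnot(inherits(table, "rate_table"))
  subjects <- as.data.frame(subjects)
  if (nrow(subjects) == 0L) stop("empty cohort")
  need <- c("id", "sex", "entry_age", "entry_year", "followup_years", "status")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("cohort is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(subjects$id))
    stop("duplicate subject ids: ",
         paste(utils::head(unique(subjects$id[duplicated(subjects$id)]), 5),
               collapse = ", "))
  if (any(subjects$followup_years <= 0))
    stop("follow-up must be > 0 for all subjects")
  bad <- !subjects$status %in% c("death", "censored", "embarked")
  if (any(bad)) stop("unknown status: ",
                     paste(unique(subjects$status[bad]), collapse = ", "))
  is_death <- subjects$status == "death"
  cz <- if ("cause" %in% names(subjects)) as.character(subjects$cause)
        else rep(NA_character_, nrow(subjects))
  if (cause != "all-cause" && any(is_death & is.na(cz)))
    stop("cause-specific analysis but some deaths have no cause label")

  # integer ages are taken as mid-year
  a0 <- subjects$entry_age
  whole <- abs(a0 - round(a0)) < 1e-9
  a0[whole] <- round(a0[whole]) + 0.5

  fu <- subjects$followup_years
  over_cap <- a0 + fu > age_cap
  fu[over_cap] <- age_cap - a0[over_cap]
  if (any(fu <= 0)) stop("subjects entering at or above the age cap")

  event <- as.integer(is_death & !over_cap)
  if (cause != "all-cause") event <- as.integer(event == 1L & cz == cause)

  pos <- lexisPosition(subjects$sex, a0, subjects$entry_year)
  z <- tryCatch(cumulativeHazard(table, pos, fu), error = function(e) {
    # rare path: re-run one by one to attach the offending subject's id
    for (i in seq_len(nrow(pos))) {
      ok <- tryCatch({cumulativeHazard(table, pos[i, ], fu[i]); TRUE},
                     error = function(e2) e2)
      if (!isTRUE(ok))
        stop(sprintf("subject %s: %s", subjects$id[i],
                     conditionMessage(ok)), call. = FALSE)
    }
    stop(e)
  })
  out <- data.frame(id = subjects$id, y = 1 - exp(-z), z = z, event = event)
  acct <- c(
    n = nrow(subjects),
    died_before_cap = sum(is_death & !over_cap),
    embarked_before_cap = sum(subjects$status == "embarked" & !over_cap),
    embarked_after_cap = sum(subjects$status == "embarked" & over_cap),
    censored_at_cap_died_later = sum(is_death & over_cap),
    censored_at_cap_alive = sum(subjects$status == "censored" & over_cap),
    alive_below_cap = sum(subjects$status == "censored" & !over_cap))
  attr(out, "accounting") <- acct
  attr(out, "cause") <- cause
  class(out) <- c("transformed_cohort", "data.frame")
  out
}

#' @rdname transformCohort
#' @param subject a single-row data.frame (or list coercible to one).
#' @export
transformSubject <- function(subject, table, cause = table$cause,
                             age_cap = 90) {
  transformCohort(as.data.frame(subject), table, cause = cause,
                  age_cap = age_cap)
}

#' Follow-up accounting of a transformed cohort
#'
#' The partition of the cohort by outcome at the analysis age cap:
#' deaths before the cap (events), embarkations before/after the cap,
#' subjects censored at the cap (who later died, or are still alive),
#' and subjects alive below the cap.  Categories sum to `n`.
#'
#' @param x a `transformed_cohort`.
#' @return named integer vector.
#' @export
followupAccounting <- function(x) {
  stopifnot(inherits(x, "transformed_cohort"))
  attr(x, "accounting")
}

#' @export
print.transformed_cohort <- function(x, ...) {
  a <- attr(x, "accounting")
  cat(sprintf("Transformed cohort: %d subjects, %d events (%s)\n",
              a[["n"]], sum(x$event), attr(x, "cause")))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
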