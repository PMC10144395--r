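#' Names of the eleven vaccination outcomes
#'
#' The eight per-antigen-dose coverage indicators plus the three
#' comprehensive statuses: ZERO (zero-dose), FULL (fully immunized for
#' age) and COMPLETE (completed schedule).
#'
#' @return Character vector of outcome column names.
#' @export
outcome_names <- function() {
  c(toupper(dose_names()), "ZERO", "FULL", "COMPLETE")
}

#' Which outcomes are adverse (burdens) rather than favorable (coverage)
#'
#' ZERO counts a burden — never having received a dose — whereas every
#' other outcome counts coverage. The distinction drives the sign
#' convention of the composite concentration index and the absolute
#' equity gap (see [rank_sample()]).
#'
#' @param outcome Outcome name(s).
#' @return Logical vector.
#' @export
is_adverse <- function(outcome) toupper(outcome) == "ZERO"

#' Derive vaccination statuses for a cohort
#'
#' Computes, for every child, the eleven binary outcomes with their
#' applicability masks, from the per-dose received flags, the child's age
#' and the immunization schedule:
#' \itemize{
#'   \item Per-antigen indicators (BCG ... MCV1): the received flag for
#'     children at or above the dose's eligibility age; `NA` (not
#'     applicable) for underage children, who are never counted as
#'     failures.
#'   \item ZERO: for children under 12 months, 1 if no dose of any antigen
#'     was ever received; `NA` at 12 months and older.
#'   \item FULL: for children under 24 months, 1 if every dose they are
#'     age-eligible for — excluding the schedule's `full_exclusions`
#'     (MCV1 by default) — was received; `NA` at 24 months and older.
#'   \item COMPLETE: for children at 24 months and older, 1 if all
#'     scheduled doses were received; `NA` below 24 months.
#' }
#' A child is eligible for a dose when `age_months >= ` the schedule age
#' (closed lower bound). `underage_count` — the number of scheduled doses
#' the child is not yet old enough for — is the analysis's sole fair
#' factor and feeds the decomposition.
#'
#' @param children Validated children tibble.
#' @param schedule A `vx_schedule`; default [default_schedule()].
#' @return A tibble with `child_id`, the 11 outcome columns (0/1/NA),
#'   `underage_count` and `n_doses_received`.
#' @export
status_table <- function(children, schedule = default_schedule()) {
  assert_that(nrow(children) > 0, "empty input: no child records")
  ages <- setNames(schedule$age_months, schedule$dose)
  excl <- attr(schedule, "full_exclusions")
  age <- children$age_months
  doses <- as.matrix(children[, dose_cols()])
  colnames(doses) <- dose_names()

  elig <- outer(age, ages[dose_names()], `>=`)  # n x 8 eligibility
  colnames(elig) <- dose_names()
  underage_count <- rowSums(!elig)
  n_received <- rowSums(doses)

  per_dose <- doses
  per_dose[!elig] <- NA_integer_

  non_excluded <- setdiff(dose_names(), excl)
  miss_full <- rowSums(elig[, non_excluded, drop = FALSE] *
                         (1 - doses[, non_excluded, drop = FALSE]))
  zero <- ifelse(age < 12, as.integer(n_received == 0), NA_integer_)
  full <- ifelse(age < 24, as.integer(miss_full == 0), NA_integer_)
  complete <- ifelse(age >= 24, as.integer(n_received == length(dose_names())),
                     NA_integer_)

  out <- tibble::as_tibble(per_dose)
  names(out) <- toupper(dose_names())
  dplyr::bind_cols(
    tibble::tibble(child_id = children$child_id),
    out,
    tibble::tibble(ZERO = zero, FULL = full, COMPLETE = complete,
                   underage_count = as.integer(underage_count),
                   n_doses_received = as.integer(n_received))
  )
}

#' Derive the status vector for a single child
#'
#' Single-record convenience wrapper around [status_table()].
#'
#' @param child A one-row validated children tibble.
#' @param schedule A `vx_schedule`.
#' @return A one-row status tibble plus an `eligible_set` attribute naming
#'   the doses the child is age-eligible for.
#' @export
derive_status <- function(child, schedule = default_schedule()) {
  assert_that(nrow(child) == 1, "derive_status expects a single child record")
  out <- status_table(child, schedule)
  ages <- setNames(schedule$age_months, schedule$dose)
  attr(out, "eligible_set") <- names(ages)[child$age_months >= ages]
  out
}

#' Attach derived statuses to child records
#'
#' Convenience join of [status_table()] output onto the covariate table,
#' as required by the ranking and reporting layers.
#'
#' @inheritParams status_table
#' @return The children tibble with the 11 outcome columns and
#'   `underage_count` appended.
#' @export
with_status <- function(children, schedule = default_schedule()) {
  st <- status_table(children, schedule)
  dplyr::bind_cols(children,
                   dplyr::select(st, -dplyr::all_of("child_id")))
}
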