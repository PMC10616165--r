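#' Code the modified Rankin Scale into favourable / unfavourable outcome
#'
#' Dichotomizes the 30-day modified Rankin Scale: mRS 4, 5 or 6 (moderately
#' severe disability through death) is an unfavourable outcome, mRS 0-3 a
#' favourable one.
#'
#' @param mrs Integer vector of mRS scores in 0-6. `NA` and out-of-range
#'   values are a domain error: missing functional outcome is never coded.
#' @return A factor with levels `favourable`, `unfavourable`.
#' @examples
#' dichotomize_outcome(c(0, 3, 4, 6))
#' @export
dichotomize_outcome <- function(mrs) {
  if (any(is.na(mrs)) || any(mrs != round(mrs)) ||
      any(mrs < 0 | mrs > 6)) {
    abort("`mrs` must be an integer in 0..6 with no missing values",
          class = c("nb_domain_error", "nb_error"))
  }
  factor(if_else(mrs >= 4, "unfavourable", "favourable"),
         levels = c("favourable", "unfavourable"))
}

#' Code ICU outcome status into death / non-death
#'
#' ICU discharge, transfer to another hospital and continued hospitalization
#' at day 30 all count as non-death, so the mortality denominator is the
#' full cohort.
#'
#' @param outcome_status Character vector with values `icu_discharge`,
#'   `transfer`, `continued_hospitalization` or `death`.
#' @return A factor with levels `non_death`, `death`.
#' @export
code_mortality <- function(outcome_status) {
  check_levels(outcome_status, outcome_status_levels(), "outcome_status")
  factor(if_else(outcome_status == "death", "death", "non_death"),
         levels = c("non_death", "death"))
}

#' Add coded outcomes to a cohort
#'
#' Convenience wrapper adding a logical `death` column for every patient and
#' a logical `unfavourable` column (`NA` where mRS is missing).
#'
#' @param cohort A validated cohort tibble.
#' @return The cohort with `death` and `unfavourable` columns appended.
#' @export
code_outcomes <- function(cohort) {
  cohort <- as_tibble(cohort)
  mutate(cohort,
         death = code_mortality(.data$outcome_status) == "death",
         unfavourable = if_else(is.na(.data$mrs), NA, .data$mrs >= 4))
}
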