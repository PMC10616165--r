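# Cohort table schema: one row per ICU admission. Fixed CSV dialect:
# comma-separated, UTF-8, "." decimal mark, snake_case headers, empty = missing.

#' Cohort schema vocabulary
#'
#' Column names and factor levels of the cohort table used throughout the
#' package. One row is one ICU admission of a patient with an acute
#' neurological disorder, followed for 30 days or until ICU discharge.
#'
#' @return `cohort_columns()` returns a character vector of all column names
#'   in schema order; the other helpers return the allowed levels of the
#'   corresponding categorical field.
#' @export
cohort_columns <- function() {
  c(
    "patient_id", "age", "sex", "diagnosis_group", "insurance",
    "admission_type", "location_before_icu", "gcs", "apache2", "saps3",
    "sofa",
    comorbidity_columns(),
    physiology_columns(),
    hs_columns(),
    "outcome_status", "mrs", "los_days"
  )
}

#' @rdname cohort_columns
#' @export
diagnosis_groups <- function() {
  c("NPO", "TBI", "IS", "ENC", "seizures", "ICH", "SAH", "SNI", "SCI", "NMD")
}

#' @rdname cohort_columns
#' @export
comorbidity_columns <- function() {
  paste0("cm_", c("hypertension", "cardiopathy", "copd", "renal",
                  "diabetes", "extracranial_neoplasia"))
}

#' @rdname cohort_columns
#' @export
physiology_columns <- function() {
  c("map_mmhg", "sbp_mmhg", "pao2_mmhg", "sao2_pct", "spo2_pct", "temp_c",
    "paco2_mmhg", "rr_ipm", "glucose_mg_dl", "sodium_mmol_l", "icp_mmhg",
    "herniation_clinical")
}

#' @rdname cohort_columns
#' @export
hs_names <- function() {
  c("hypotension", "hypoxemia", "hyperthermia", "hypercapnia", "hypocapnia",
    "hypoglycaemia", "hyponatremia", "hypothermia",
    "intracranial_hypertension", "herniation")
}

#' @rdname cohort_columns
#' @export
hs_columns <- function() paste0("hs_", hs_names())

#' @rdname cohort_columns
#' @export
hs_category_levels <- function() c("zero", "one", "two", "three_plus")

outcome_status_levels <- function() {
  c("icu_discharge", "transfer", "continued_hospitalization", "death")
}

# column -> readr type; categorical fields read as character then validated
cohort_col_types <- function() {
  flag_cols <- setNames(
    rep(list(readr::col_logical()),
        length(c(comorbidity_columns(), hs_columns()))),
    c(comorbidity_columns(), hs_columns()))
  rlang::exec(
    readr::cols,
    !!!flag_cols,
    patient_id = readr::col_character(),
    age = readr::col_integer(),
    sex = readr::col_character(),
    diagnosis_group = readr::col_character(),
    insurance = readr::col_character(),
    admission_type = readr::col_character(),
    location_before_icu = readr::col_character(),
    gcs = readr::col_integer(),
    apache2 = readr::col_integer(),
    saps3 = readr::col_integer(),
    sofa = readr::col_integer(),
    outcome_status = readr::col_character(),
    mrs = readr::col_integer(),
    los_days = readr::col_integer(),
    herniation_clinical = readr::col_logical(),
    .default = readr::col_double()
  )
}

stop_rows <- function(bad, msg, class) {
  rows <- which(bad)
  abort(
    sprintf("%s (row%s %s)", msg, if (length(rows) > 1) "s" else "",
            paste(head(rows, 10), collapse = ", ")),
    class = c(class, "nb_error")
  )
}

check_levels <- function(x, levels, field, allow_na = FALSE) {
  bad <- !(x %in% levels) & !(allow_na & is.na(x))
  if (any(bad)) {
    stop_rows(bad, sprintf("invalid value in `%s`: expected one of %s",
                           field, paste(levels, collapse = ", ")),
              "nb_validation_error")
  }
}

check_range <- function(x, field, lo = -Inf, hi = Inf) {
  bad <- !is.na(x) & (x < lo | x > hi | !is.finite(x))
  if (any(bad)) {
    stop_rows(bad, sprintf("`%s` outside [%s, %s]", field, lo, hi),
              "nb_validation_error")
  }
}

#' Validate a cohort table
#'
#' Checks the cohort schema invariants: categorical levels, numeric ranges
#' (age >= 18, GCS 3-15, mRS 0-6, length of stay 0-30 days, physiological
#' plausibility), and the cross-field rule that death as an outcome status
#' corresponds exactly to mRS 6 whenever mRS is recorded. Violations raise a
#' validation error naming the field and the offending rows; nothing is ever
#' silently clamped or imputed.
#'
#' @param cohort A data frame in the cohort schema (see [cohort_columns()]).
#'   Comorbidity and Hs flag columns may be absent; all other columns are
#'   mandatory.
#' @return The cohort as a tibble, invisibly, for use in pipes.
#' @export
validate_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  mandatory <- setdiff(cohort_columns(),
                       c(hs_columns(), comorbidity_columns(),
                         physiology_columns()))
  missing_cols <- setdiff(mandatory, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = c("nb_schema_error", "nb_error"))
  }
  has_phys <- all(physiology_columns() %in% names(cohort))
  has_flags <- all(hs_columns() %in% names(cohort))
  if (!has_phys && !has_flags) {
    abort(paste0("cohort must carry either the full physiology block (",
                 paste(physiology_columns(), collapse = ", "),
                 ") or the ten hs_* flag columns; neither is complete"),
          class = c("nb_schema_error", "nb_error"))
  }
  if (nrow(cohort) == 0) return(invisible(cohort))

  check_levels(cohort$sex, c("male", "female"), "sex")
  check_levels(cohort$diagnosis_group, diagnosis_groups(), "diagnosis_group")
  check_levels(cohort$insurance, c("public", "private"), "insurance")
  check_levels(cohort$admission_type, c("elective", "emergency"),
               "admission_type")
  check_levels(cohort$location_before_icu,
               c("emergency_department", "operating_room", "ward", "other"),
               "location_before_icu")
  check_levels(cohort$outcome_status, outcome_status_levels(),
               "outcome_status")

  check_range(cohort$age, "age", 18, 120)
  check_range(cohort$gcs, "gcs", 3, 15)
  check_range(cohort$apache2, "apache2", 0, Inf)
  check_range(cohort$saps3, "saps3", 0, Inf)
  check_range(cohort$sofa, "sofa", 0, 24)
  check_range(cohort$mrs, "mrs", 0, 6)
  check_range(cohort$los_days, "los_days", 0, 30)
  phys_ranges <- list(sao2_pct = c(0, 100), spo2_pct = c(0, 100),
                      temp_c = c(25, 45))
  for (col in setdiff(intersect(physiology_columns(), names(cohort)),
                      "herniation_clinical")) {
    r <- phys_ranges[[col]] %||% c(0, Inf)
    check_range(cohort[[col]], col, r[1], r[2])
  }

  # death <=> mRS 6 when mRS is recorded
  has_mrs <- !is.na(cohort$mrs)
  bad <- has_mrs &
    ((cohort$outcome_status == "death") != (cohort$mrs == 6))
  if (any(bad)) {
    stop_rows(bad,
              "`outcome_status` = death must coincide with `mrs` = 6",
              "nb_validation_error")
  }
  invisible(cohort)
}

#' Read and write cohort CSV files
#'
#' The on-disk format is a plain CSV in the documented schema: UTF-8,
#' comma-separated, "." decimal mark, lowercase snake_case headers, empty
#' cells for missing values. `read_cohort()` validates every row on entry;
#' `write_cohort()` then `read_cohort()` round-trips a valid cohort exactly.
#'
#' @param path Path to a cohort CSV file.
#' @param cohort A validated cohort tibble.
#' @return `read_cohort()` returns a validated cohort tibble;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: ", path),
          class = c("nb_io_error", "nb_error"))
  }
  cohort <- readr::read_csv(path, col_types = cohort_col_types(),
                            progress = FALSE)
  for (col in intersect(c(comorbidity_columns(), hs_columns()),
                        names(cohort))) {
    cohort[[col]] <- as.logical(cohort[[col]])
  }
  validate_cohort(cohort)
  cohort
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- as_tibble(cohort)[, intersect(cohort_columns(), names(cohort))]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
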