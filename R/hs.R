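# Secondary-injury ("Hs") classification from admission physiology.
# All threshold comparisons are strict; a value exactly at its threshold
# does not fire, and a missing measurement never fires ("not assessed").

#' Threshold definitions of the ten potential secondary injuries
#'
#' Returns the rule book of the ten "Hs": hypotension (MAP < 65 mmHg or
#' SBP < 90 mmHg), hypoxemia (PaO2 < 60 mmHg or SaO2 < 90% or SpO2 < 90%),
#' hyperthermia (temperature > 37.5 C), hypercapnia (PaCO2 > 45 mmHg or
#' respiratory rate < 8/min), hypocapnia (PaCO2 < 35 mmHg), hypoglycaemia
#' (glucose < 60 mg/dL), hyponatremia (sodium < 135 mmol/L), hypothermia
#' (temperature < 35 C), intracranial hypertension (ICP > 25 mmHg), and
#' clinical evidence of herniation (a recorded clinical judgement, not a
#' computed rule).
#'
#' @return A tibble with columns `hs`, `rule` (human-readable definition).
#' @export
hs_definitions <- function() {
  tibble(
    hs = hs_names(),
    rule = c(
      "MAP < 65 mmHg or SBP < 90 mmHg",
      "PaO2 < 60 mmHg or SaO2 < 90% or SpO2 < 90%",
      "body temperature > 37.5 C",
      "PaCO2 > 45 mmHg or respiratory rate < 8 /min",
      "PaCO2 < 35 mmHg",
      "glucose < 60 mg/dL",
      "sodium < 135 mmol/L",
      "body temperature < 35 C",
      "intracranial pressure > 25 mmHg",
      "clinical evidence of herniation"
    )
  )
}

# strict comparison that treats NA as "does not fire"
lt_ <- function(x, t) !is.na(x) & x < t
gt_ <- function(x, t) !is.na(x) & x > t

#' Classify potential secondary injuries (Hs) from physiology
#'
#' Applies the ten threshold rules of [hs_definitions()] to the physiology
#' columns of a cohort (or any data frame holding them) and appends one
#' logical `hs_*` column per injury plus the summary columns `hs_count`
#' (0-10) and `hs_category` (`zero`, `one`, `two`, `three_plus`). All
#' inequalities are strict, so a measurement exactly at its cut-off is
#' negative, and a missing measurement never fires a flag.
#'
#' @param data A data frame with the physiology columns
#'   ([physiology_columns()]). Existing `hs_*` columns are recomputed.
#' @return `data` with the ten `hs_*` flags, `hs_count` and `hs_category`
#'   appended (replacing any previous versions).
#' @examples
#' snap <- tibble::tibble(
#'   map_mmhg = 60, sbp_mmhg = 120, pao2_mmhg = 95, sao2_pct = 97,
#'   spo2_pct = 98, temp_c = 36.8, paco2_mmhg = 40, rr_ipm = 14,
#'   glucose_mg_dl = 110, sodium_mmol_l = 140, icp_mmhg = NA,
#'   herniation_clinical = FALSE
#' )
#' classify_hs(snap)[, c("hs_hypotension", "hs_count", "hs_category")]
#' @export
classify_hs <- function(data) {
  data <- as_tibble(data)
  missing_cols <- setdiff(physiology_columns(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("physiology column(s) absent: ",
                 paste(missing_cols, collapse = ", ")),
          class = c("nb_schema_error", "nb_error"))
  }
  phys <- data[, setdiff(physiology_columns(), "herniation_clinical")]
  uninformative <- rowSums(!is.na(phys)) == 0 & is.na(data$herniation_clinical)
  if (any(uninformative)) {
    warn(sprintf(
      "%d row(s) have no physiological measurement and no herniation record; classified as zero Hs (uninformative input)",
      sum(uninformative)))
  }

  flags <- tibble(
    hs_hypotension = lt_(data$map_mmhg, 65) | lt_(data$sbp_mmhg, 90),
    hs_hypoxemia = lt_(data$pao2_mmhg, 60) | lt_(data$sao2_pct, 90) |
      lt_(data$spo2_pct, 90),
    hs_hyperthermia = gt_(data$temp_c, 37.5),
    hs_hypercapnia = gt_(data$paco2_mmhg, 45) | lt_(data$rr_ipm, 8),
    hs_hypocapnia = lt_(data$paco2_mmhg, 35),
    hs_hypoglycaemia = lt_(data$glucose_mg_dl, 60),
    hs_hyponatremia = lt_(data$sodium_mmol_l, 135),
    hs_hypothermia = lt_(data$temp_c, 35),
    hs_intracranial_hypertension = gt_(data$icp_mmhg, 25),
    hs_herniation = !is.na(data$herniation_clinical) &
      data$herniation_clinical
  )
  data[hs_columns()] <- flags
  data$hs_count <- as.integer(rowSums(flags))
  data$hs_category <- hs_categorize(data$hs_count)
  data
}

#' Partition an Hs count into the reporting categories
#'
#' @param count Integer vector of Hs counts (0-10).
#' @return Factor with levels `zero`, `one`, `two`, `three_plus`.
#' @export
hs_categorize <- function(count) {
  if (any(is.na(count)) || any(count < 0 | count > 10)) {
    abort("`count` must be in 0..10", class = c("nb_domain_error", "nb_error"))
  }
  factor(case_when(count == 0 ~ "zero",
                   count == 1 ~ "one",
                   count == 2 ~ "two",
                   TRUE ~ "three_plus"),
         levels = hs_category_levels())
}

#' Resolve Hs flags for a cohort
#'
#' Uses precomputed `hs_*` flag columns when the cohort carries them and the
#' physiology block is absent; otherwise classifies from physiology via
#' [classify_hs()]. Ensures `hs_count` and `hs_category` are present and
#' consistent with the flags.
#'
#' @param cohort A validated cohort tibble.
#' @return The cohort with `hs_*`, `hs_count` and `hs_category` columns.
#' @export
resolve_hs <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (all(physiology_columns() %in% names(cohort))) {
    return(classify_hs(cohort))
  }
  if (!all(hs_columns() %in% names(cohort))) {
    abort("cohort has neither a full physiology block nor hs_* flags",
          class = c("nb_schema_error", "nb_error"))
  }
  flags <- cohort[, hs_columns()]
  if (any(is.na(flags))) {
    abort("hs_* flags must be TRUE/FALSE with no missing values",
          class = c("nb_validation_error", "nb_error"))
  }
  cohort$hs_count <- as.integer(rowSums(flags))
  cohort$hs_category <- hs_categorize(cohort$hs_count)
  cohort
}
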