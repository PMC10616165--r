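# Shared fixtures, all built in code.

# one fully-specified patient row; override any field by name
make_patient <- function(...) {
  row <- tibble::tibble(
    patient_id = "P1", age = 60L, sex = "male", diagnosis_group = "IS",
    insurance = "public", admission_type = "emergency",
    location_before_icu = "emergency_department",
    gcs = 14L, apache2 = 10L, saps3 = 40L, sofa = 2L,
    cm_hypertension = FALSE, cm_cardiopathy = FALSE, cm_copd = FALSE,
    cm_renal = FALSE, cm_diabetes = FALSE,
    cm_extracranial_neoplasia = FALSE,
    map_mmhg = 85, sbp_mmhg = 120, pao2_mmhg = 95, sao2_pct = 97,
    spo2_pct = 98, temp_c = 36.8, paco2_mmhg = 40, rr_ipm = 16,
    glucose_mg_dl = 110, sodium_mmol_l = 140, icp_mmhg = NA_real_,
    herniation_clinical = FALSE,
    outcome_status = "icu_discharge", mrs = 1L, los_days = 5L
  )
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}

# textbook-normal physiology snapshot
normal_snapshot <- function(...) {
  make_patient(...)[, physiology_columns()]
}

# toy life table: e_x = max((110 - age) / 2, 0.25), so e.g.
# e(60) = 25, e(70) = 20, e(99) = 5.5, e(109) = 0.5
toy_life_table <- function() {
  grid <- tidyr::expand_grid(sex = c("male", "female"), age = 0:110)
  grid$ex <- pmax((110 - grid$age) / 2, 0.25)
  life_table(grid)
}

# toy disability weights: mRS 0..5 -> 0, 0.1, 0.2, 0.3, 0.5, 0.6
toy_weights <- function() {
  disability_weights(dplyr::bind_rows(
    tibble::tibble(kind = "mrs", level = as.character(0:5),
                   weight = c(0, 0.1, 0.2, 0.3, 0.5, 0.6)),
    tibble::tibble(kind = "comorbidity",
                   level = c("hypertension", "cardiopathy", "copd", "renal",
                             "diabetes", "extracranial_neoplasia"),
                   weight = c(0.1, 0.2, 0.3, 0.05, 0.04, 0.25))
  ))
}

# five-patient cohort whose burden is hand-computable against toy tables:
#  P1 male dies at 70            -> YLL 20
#  P2 female dies at 90          -> YLL 10
#  P3 survivor mRS 3, COPD       -> YLD 1 - 0.7*0.7      = 0.51
#  P4 survivor mRS 0, nothing    -> YLD 0
#  P5 survivor mRS 5, HT + card. -> YLD 1 - 0.4*0.9*0.8  = 0.712
# totals at horizon 1: YLL 30, YLD 1.222, DALY 31.222
toy_burden_cohort <- function() {
  dplyr::bind_rows(
    make_patient(patient_id = "P1", age = 70L, sex = "male",
                 outcome_status = "death", mrs = 6L),
    make_patient(patient_id = "P2", age = 90L, sex = "female",
                 outcome_status = "death", mrs = 6L),
    make_patient(patient_id = "P3", age = 55L, mrs = 3L, cm_copd = TRUE),
    make_patient(patient_id = "P4", age = 40L, sex = "female", mrs = 0L),
    make_patient(patient_id = "P5", age = 65L, mrs = 5L,
                 cm_hypertension = TRUE, cm_cardiopathy = TRUE)
  )
}

# independent scalar re-implementation of the ten threshold rules, used as
# the brute-force oracle for classify_hs
oracle_hs_flags <- function(p) {
  lt <- function(x, t) !is.na(x) && x < t
  gt <- function(x, t) !is.na(x) && x > t
  c(
    hypotension = lt(p$map_mmhg, 65) || lt(p$sbp_mmhg, 90),
    hypoxemia = lt(p$pao2_mmhg, 60) || lt(p$sao2_pct, 90) ||
      lt(p$spo2_pct, 90),
    hyperthermia = gt(p$temp_c, 37.5),
    hypercapnia = gt(p$paco2_mmhg, 45) || lt(p$rr_ipm, 8),
    hypocapnia = lt(p$paco2_mmhg, 35),
    hypoglycaemia = lt(p$glucose_mg_dl, 60),
    hyponatremia = lt(p$sodium_mmol_l, 135),
    hypothermia = lt(p$temp_c, 35),
    intracranial_hypertension = gt(p$icp_mmhg, 25),
    herniation = isTRUE(p$herniation_clinical)
  )
}

# random physiology snapshots mixing normal, abnormal, boundary and missing
# values for every field
random_snapshots <- function(n, seed) {
  set.seed(seed)
  draw <- function(candidates, lo, hi) {
    pick <- sample(c("na", "bound", "unif"), n, replace = TRUE,
                   prob = c(0.2, 0.25, 0.55))
    out <- runif(n, lo, hi)
    out[pick == "na"] <- NA_real_
    nb <- sum(pick == "bound")
    out[pick == "bound"] <- sample(candidates, nb, replace = TRUE)
    out
  }
  tibble::tibble(
    map_mmhg = draw(c(65, 64.9, 65.1), 40, 110),
    sbp_mmhg = draw(c(90, 89.9, 90.1), 60, 180),
    pao2_mmhg = draw(c(60, 59.9, 60.1), 30, 120),
    sao2_pct = draw(c(90, 89.9, 90.1), 60, 100),
    spo2_pct = draw(c(90, 89.9, 90.1), 60, 100),
    temp_c = draw(c(35, 37.5, 34.9, 37.6), 30, 42),
    paco2_mmhg = draw(c(35, 45, 34.9, 45.1), 15, 90),
    rr_ipm = draw(c(8, 7.9, 8.1), 4, 40),
    glucose_mg_dl = draw(c(60, 59.9, 60.1), 20, 400),
    sodium_mmol_l = draw(c(135, 134.9, 135.1), 110, 160),
    icp_mmhg = draw(c(25, 24.9, 25.1), 2, 60),
    herniation_clinical = sample(c(TRUE, FALSE, NA), n, replace = TRUE,
                                 prob = c(0.15, 0.75, 0.1))
  )
}
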