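# Synthetic cohort generator. Defaults emulate the marginal structure of a
# 1194-patient multicentre Brazilian neurocritical-care cohort: the 10-group
# diagnosis mix, group-wise age/sex/severity distributions, the Hs category
# distribution per group, comorbidity prevalences, and a configurable
# logistic outcome model for death with an ordinal allocation of survivor
# mRS. Synthetic data only: no patient-level information is reproduced.

default_group_params <- function() {
  tibble(
    diagnosis_group = diagnosis_groups(),
    n_ref = c(317, 218, 211, 155, 91, 77, 70, 25, 19, 11),
    age_mean = c(53.4, 54.3, 69.3, 65.7, 58.7, 62, 57.6, 55.7, 36.5, 50),
    age_sd = c(14.7, 22.1, 16.9, 20.2, 22.7, 15.3, 14.2, 17.6, 18.5, 20.8),
    male_prob = c(0.413, 0.743, 0.507, 0.465, 0.505, 0.481, 0.314, 0.76,
                  0.737, 0.727),
    gcs_median = c(15, 9, 14, 13, 14, 10, 10, 10, 15, 15),
    gcs_iqr = c(1, 11, 3, 5, 4, 10, 11, 10, 0.5, 1),
    apache2_median = c(7, 14, 11, 15, 10, 15, 14, 20, 7, 7),
    apache2_iqr = c(6, 11, 9, 15, 9, 10, 12, 12, 9, 5),
    saps3_median = c(31, 47, 52, 57, 41, 54.5, 48, 59, 35, 42),
    saps3_iqr = c(15, 19, 16, 21, 21, 21.5, 20, 21, 16, 13),
    sofa_median = c(1, 5, 2, 4, 2, 4, 4, 6, 3, 0),
    sofa_iqr = c(3, 6, 4, 6, 4, 5, 6, 7.5, 3, 2),
    los_median = c(3, 11, 4, 6, 4, 16, 11.5, 13, 30, 4),
    los_q1 = c(2, 4, 3, 3, 2, 6, 4, 4, 7.5, 3),
    los_q3 = c(5, 29, 11, 17.5, 9, 30, 22, 26, 30, 30),
    hs_zero = c(162, 64, 109, 47, 44, 30, 24, 6, 8, 6),
    hs_one = c(96, 51, 55, 39, 24, 20, 20, 5, 5, 3),
    hs_two = c(41, 49, 30, 32, 14, 13, 14, 4, 5, 1),
    hs_three_plus = c(18, 54, 17, 37, 9, 14, 12, 10, 1, 1)
  )
}

default_comorbidity_prev <- function() {
  c(cm_hypertension = 0.505, cm_cardiopathy = 0.148, cm_copd = 0.043,
    cm_renal = 0.070, cm_diabetes = 0.183, cm_extracranial_neoplasia = 0.075)
}

# marginal frequencies of the ten Hs, used as sampling weights when choosing
# which injuries make up a patient's count
default_hs_weights <- function() {
  c(hypotension = 267, hypoxemia = 72, hyperthermia = 126, hypercapnia = 115,
    hypocapnia = 213, hypoglycaemia = 32, hyponatremia = 200,
    hypothermia = 121, intracranial_hypertension = 89, herniation = 77)
}

#' Configurable logistic outcome model for the generator
#'
#' Log-odds coefficients linking covariates to 30-day ICU death, plus a
#' second linear predictor used to allocate survivor mRS by an ordinal
#' (proportional-odds) rule. Defaults are the adjusted odds ratios of the
#' first prognostic model (age, male sex, GCS, Hs category, public
#' insurance, emergency admission), with the death intercept calibrated so
#' the default cohort has about 15.7% mortality (188/1194).
#'
#' @param death_intercept Intercept of the death model (log-odds).
#' @param death_coefs Named log-odds coefficients for terms `age`, `male`,
#'   `gcs`, `hs_one`, `hs_two`, `hs_three_plus`, `public`, `emergency`.
#' @param mrs_coefs Same terms, for the linear predictor behind the
#'   survivor mRS allocation.
#' @param mrs_targets Cumulative probabilities of mRS 0..5 among survivors
#'   used to centre the ordinal thresholds.
#' @return A list of class `nb_outcome_model`.
#' @export
outcome_model <- function(
    death_intercept = -4.668,
    death_coefs = c(age = log(1.022), male = log(1.222), gcs = log(0.895),
                    hs_one = log(1.978), hs_two = log(3.86),
                    hs_three_plus = log(8.663), public = log(2.353),
                    emergency = log(5.77)),
    mrs_coefs = c(age = log(1.021), male = log(1.03), gcs = log(0.835),
                  hs_one = log(1.259), hs_two = log(2.848),
                  hs_three_plus = log(4.761), public = log(2.784),
                  emergency = log(4.359)),
    mrs_targets = cumsum(c(283, 201, 121, 100, 154, 140)) / 999) {
  terms <- c("age", "male", "gcs", "hs_one", "hs_two", "hs_three_plus",
             "public", "emergency")
  for (cf in list(death_coefs, mrs_coefs)) {
    if (!setequal(names(cf), terms) || any(!is.finite(cf))) {
      abort("outcome-model coefficients must be finite and named after the model-1 terms",
            class = c("nb_config_error", "nb_error"))
    }
  }
  if (!is.finite(death_intercept)) {
    abort("`death_intercept` must be finite",
          class = c("nb_config_error", "nb_error"))
  }
  if (length(mrs_targets) != 6 || is.unsorted(mrs_targets) ||
      any(mrs_targets <= 0) || abs(mrs_targets[6] - 1) > 1e-9) {
    abort("`mrs_targets` must be 6 increasing cumulative probabilities ending at 1",
          class = c("nb_config_error", "nb_error"))
  }
  structure(list(death_intercept = death_intercept,
                 death_coefs = death_coefs[terms],
                 mrs_coefs = mrs_coefs[terms],
                 mrs_targets = mrs_targets),
            class = "nb_outcome_model")
}

#' Specify a synthetic cohort
#'
#' Bundles every tunable of the generator. All defaults emulate the study
#' conditions: the diagnosis mix is proportional to the published group
#' sizes (317, 218, 211, 155, 91, 77, 70, 25, 19, 11), ages are group-wise
#' truncated normals (18+), severity scores are discretised latent normals
#' matched to the group median/IQR, Hs categories follow the group-wise
#' category counts, comorbidity prevalences and insurance/admission
#' probabilities follow the cohort margins, and severity-score/mRS
#' missingness rates match the published footnotes.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer RNG seed; the cohort is a deterministic function of
#'   the spec including this seed.
#' @param diagnosis_mix Named probability vector over the 10 diagnosis
#'   groups (must sum to 1).
#' @param group_params Tibble of per-group distributional parameters; see
#'   the package source for the default.
#' @param comorbidity_prev Named prevalence vector for the 6 comorbidities.
#' @param insurance_public_prob,emergency_prob Cohort-level probabilities.
#' @param location_probs Probabilities of the 4 pre-ICU locations.
#' @param missing_saps3,missing_sofa,missing_mrs Missingness rates.
#' @param outcome An [outcome_model()].
#' @return A list of class `nb_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 1194,
                        seed = 1L,
                        diagnosis_mix = NULL,
                        group_params = default_group_params(),
                        comorbidity_prev = default_comorbidity_prev(),
                        insurance_public_prob = 0.495,
                        emergency_prob = 0.734,
                        location_probs = c(emergency_department = 567,
                                           operating_room = 428,
                                           ward = 81, other = 118) / 1194,
                        missing_saps3 = 35 / 1194,
                        missing_sofa = 54 / 1194,
                        missing_mrs = 7 / 1006,
                        outcome = outcome_model()) {
  if (n_patients < 1) {
    abort("`n_patients` must be at least 1",
          class = c("nb_config_error", "nb_error"))
  }
  if (is.null(diagnosis_mix)) {
    diagnosis_mix <- setNames(group_params$n_ref / sum(group_params$n_ref),
                              group_params$diagnosis_group)
  }
  if (!setequal(names(diagnosis_mix), diagnosis_groups()) ||
      abs(sum(diagnosis_mix) - 1) > 1e-9 || any(diagnosis_mix < 0)) {
    abort("`diagnosis_mix` must be a probability vector over the 10 groups",
          class = c("nb_config_error", "nb_error"))
  }
  if (any(group_params$age_sd <= 0)) {
    abort("group age SDs must be positive",
          class = c("nb_config_error", "nb_error"))
  }
  hs_mat <- as.matrix(group_params[, c("hs_zero", "hs_one", "hs_two",
                                       "hs_three_plus")])
  if (any(rowSums(hs_mat) <= 0) || any(hs_mat < 0)) {
    abort("each group needs a non-degenerate Hs category distribution",
          class = c("nb_config_error", "nb_error"))
  }
  if (abs(sum(location_probs) - 1) > 1e-9) {
    abort("`location_probs` must sum to 1",
          class = c("nb_config_error", "nb_error"))
  }
  stopifnot(inherits(outcome, "nb_outcome_model"))
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         diagnosis_mix = diagnosis_mix[diagnosis_groups()],
         group_params = group_params,
         comorbidity_prev = comorbidity_prev,
         insurance_public_prob = insurance_public_prob,
         emergency_prob = emergency_prob,
         location_probs = location_probs,
         missing_saps3 = missing_saps3, missing_sofa = missing_sofa,
         missing_mrs = missing_mrs,
         outcome = outcome),
    class = "nb_cohort_spec"
  )
}

# latent-normal draw discretised onto an integer lattice
draw_score <- function(n, med, iqr, lo, hi) {
  pmin(pmax(round(rnorm(n, med, pmax(iqr, 0.5) / 1.349)), lo), hi)
}

# truncated normal >= lo via inverse CDF
draw_trunc_normal <- function(n, mean, sd, lo) {
  u <- runif(n, pnorm((lo - mean) / sd), 1)
  mean + sd * qnorm(pmin(u, 1 - 1e-12))
}

# choose which Hs make up each patient's count, weighted by the marginal Hs
# frequencies, with hyper/hypothermia and hyper/hypocapnia kept mutually
# exclusive
draw_hs_flags <- function(counts, weights) {
  n <- length(counts)
  hs <- hs_names()
  flags <- matrix(FALSE, n, 10, dimnames = list(NULL, hs))
  partner <- c(hyperthermia = "hypothermia", hypothermia = "hyperthermia",
               hypercapnia = "hypocapnia", hypocapnia = "hypercapnia")
  one <- which(counts == 1)
  if (length(one) > 0) {
    idx <- sample.int(10, length(one), replace = TRUE, prob = weights[hs])
    flags[cbind(one, idx)] <- TRUE
  }
  for (i in which(counts >= 2)) {
    w <- weights[hs]
    pick <- character(0)
    for (j in seq_len(counts[i])) {
      s <- sample(names(w), 1, prob = w)
      pick <- c(pick, s)
      drop <- c(s, unname(partner[s]))
      w <- w[setdiff(names(w), drop)]
    }
    flags[i, pick] <- TRUE
  }
  flags
}

r1 <- function(x) round(x, 1)

# physiology consistent with the flag matrix: abnormal values strictly past
# the threshold where flagged, safe-side values (or missingness) elsewhere
draw_physiology <- function(flags) {
  n <- nrow(flags)
  f <- function(hs) flags[, hs]
  phys <- tibble(
    map_mmhg = r1(if_else(f("hypotension"), runif(n, 42, 64.4),
                          runif(n, 66, 110))),
    sbp_mmhg = r1(if_else(f("hypotension"), runif(n, 70, 89.4),
                          runif(n, 92, 165))),
    pao2_mmhg = r1(if_else(f("hypoxemia"), runif(n, 40, 59.4),
                           runif(n, 62, 110))),
    sao2_pct = r1(if_else(f("hypoxemia"), runif(n, 78, 89.4),
                          runif(n, 91, 99.9))),
    spo2_pct = r1(if_else(f("hypoxemia"), runif(n, 78, 89.4),
                          runif(n, 91, 99.9))),
    temp_c = r1(case_when(f("hyperthermia") ~ runif(n, 37.7, 40.5),
                          f("hypothermia") ~ runif(n, 30.5, 34.8),
                          TRUE ~ runif(n, 35.2, 37.4))),
    paco2_mmhg = r1(case_when(f("hypercapnia") ~ runif(n, 46, 70),
                              f("hypocapnia") ~ runif(n, 24, 34.4),
                              TRUE ~ runif(n, 35.6, 44.4))),
    rr_ipm = round(runif(n, 10, 24)),
    glucose_mg_dl = round(if_else(f("hypoglycaemia"), runif(n, 35, 58),
                                  runif(n, 72, 190))),
    sodium_mmol_l = r1(if_else(f("hyponatremia"), runif(n, 120, 134.4),
                               runif(n, 135.6, 146))),
    icp_mmhg = r1(runif(n, 26.2, 45)),
    herniation_clinical = f("herniation")
  )
  # ICP is only measured in monitored patients; unmonitored, unflagged
  # patients have it missing, a few carry a normal reading
  icp_measured <- f("intracranial_hypertension") | runif(n) < 0.06
  phys$icp_mmhg[!icp_measured] <- NA_real_
  normal_icp <- icp_measured & !f("intracranial_hypertension")
  phys$icp_mmhg[normal_icp] <- r1(runif(sum(normal_icp), 4, 22))
  # arterial blood gas not drawn for ~35% of patients with no gas-dependent
  # flag; a missing measurement never fires a flag
  no_gas_flag <- !(f("hypoxemia") | f("hypercapnia") | f("hypocapnia"))
  gas_missing <- no_gas_flag & runif(n) < 0.35
  phys$pao2_mmhg[gas_missing] <- NA_real_
  phys$sao2_pct[gas_missing] <- NA_real_
  phys$paco2_mmhg[gas_missing] <- NA_real_
  phys
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_spec()]: diagnosis group, then group-wise
#' age/sex/severity scores, an Hs category and a physiology snapshot that
#' [classify_hs()] maps back to exactly that category, comorbidities,
#' insurance and admission type; death is then drawn from the logistic
#' outcome model, survivors receive an mRS 0-5 from a proportional-odds
#' allocation (deaths are mRS 6), and length of stay is drawn and capped at
#' 30 days. Deterministic given the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return A validated cohort tibble with `hs_*`, `hs_count` and
#'   `hs_category` columns included.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 200, seed = 7))
#' dplyr::count(cohort, hs_category)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "nb_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  gp <- spec$group_params

  g_idx <- sample.int(10, n, replace = TRUE, prob = spec$diagnosis_mix)
  gp_row <- gp[g_idx, ]

  age <- pmin(pmax(round(draw_trunc_normal(n, gp_row$age_mean,
                                           gp_row$age_sd, 18)), 18L), 105L)
  sex <- if_else(runif(n) < gp_row$male_prob, "male", "female")
  gcs <- draw_score(n, gp_row$gcs_median, gp_row$gcs_iqr, 3, 15)
  apache2 <- draw_score(n, gp_row$apache2_median, gp_row$apache2_iqr, 0, 71)
  saps3 <- draw_score(n, gp_row$saps3_median, gp_row$saps3_iqr, 0, 217)
  sofa <- draw_score(n, gp_row$sofa_median, gp_row$sofa_iqr, 0, 24)
  saps3[runif(n) < spec$missing_saps3] <- NA_integer_
  sofa[runif(n) < spec$missing_sofa] <- NA_integer_

  cm <- map(spec$comorbidity_prev, function(p) runif(n) < p)
  insurance <- if_else(runif(n) < spec$insurance_public_prob,
                       "public", "private")
  admission_type <- if_else(runif(n) < spec$emergency_prob,
                            "emergency", "elective")
  location <- sample(names(spec$location_probs), n, replace = TRUE,
                     prob = spec$location_probs)

  hs_probs <- as.matrix(gp[, c("hs_zero", "hs_one", "hs_two",
                               "hs_three_plus")])
  hs_probs <- hs_probs / rowSums(hs_probs)
  u <- runif(n)
  cum <- t(apply(hs_probs, 1, cumsum))[g_idx, ]
  cat_idx <- rowSums(u > cum) + 1L # 1 = zero .. 4 = three_plus
  counts <- c(0L, 1L, 2L, 3L)[cat_idx]
  counts[cat_idx == 4L] <- 3L + rbinom(sum(cat_idx == 4L), 2, 0.25)
  flags <- draw_hs_flags(counts, default_hs_weights())
  phys <- draw_physiology(flags)

  lin <- tibble(
    age = as.numeric(age), male = as.numeric(sex == "male"),
    gcs = as.numeric(gcs),
    hs_one = as.numeric(cat_idx == 2L), hs_two = as.numeric(cat_idx == 3L),
    hs_three_plus = as.numeric(cat_idx == 4L),
    public = as.numeric(insurance == "public"),
    emergency = as.numeric(admission_type == "emergency")
  )
  X <- as.matrix(lin)
  om <- spec$outcome
  eta_death <- om$death_intercept + drop(X %*% om$death_coefs[colnames(X)])
  death <- runif(n) < plogis(eta_death)

  outcome_status <- rep("death", n)
  surv <- !death
  if (any(surv)) {
    outcome_status[surv] <- sample(
      c("icu_discharge", "transfer", "continued_hospitalization"),
      sum(surv), replace = TRUE, prob = c(832, 22, 152) / 1006)
  }

  mrs <- rep(NA_integer_, n)
  mrs[death] <- 6L
  if (any(surv)) {
    eta_u <- drop(X %*% om$mrs_coefs[colnames(X)])
    theta <- qlogis(pmin(om$mrs_targets[1:5], 1 - 1e-12)) +
      mean(eta_u[surv])
    cum_p <- outer(eta_u[surv], theta, function(e, t) plogis(t - e))
    mrs[surv] <- as.integer(rowSums(runif(sum(surv)) > cum_p))
    drop_mrs <- surv & runif(n) < spec$missing_mrs
    mrs[drop_mrs] <- NA_integer_
  }

  sdlog <- log(pmax(gp_row$los_q3 / pmax(gp_row$los_q1, 0.5), 1.05)) /
    (2 * 0.6745)
  los <- pmin(pmax(round(rlnorm(n, log(gp_row$los_median), sdlog)), 0L), 30L)

  cohort <- tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = as.integer(age), sex = sex,
    diagnosis_group = diagnosis_groups()[g_idx],
    insurance = insurance, admission_type = admission_type,
    location_before_icu = location,
    gcs = as.integer(gcs), apache2 = as.integer(apache2),
    saps3 = as.integer(saps3), sofa = as.integer(sofa),
    !!!cm,
    !!!phys,
    outcome_status = outcome_status, mrs = mrs,
    los_days = as.integer(los)
  )
  cohort <- classify_hs(cohort)
  validate_cohort(cohort)
  cohort
}

#' Parameter-recovery report for the generator
#'
#' Generates a cohort, fits the first prognostic model (age, male sex, GCS,
#' Hs category, public insurance, emergency admission) to 30-day mortality,
#' and tabulates the estimated odds ratios with Wald confidence intervals
#' against the odds ratios the generator was configured with. Separation in
#' the fit is flagged in the output rather than dropped.
#'
#' @param spec A [cohort_spec()].
#' @param n Cohort size for the recovery run (default 20000).
#' @param seed Seed for the recovery run (overrides the spec's seed).
#' @return A tibble with one row per model-1 term: `term`, `true_or`,
#'   `estimate_or`, `ci_low`, `ci_high`, `covered`, plus attributes
#'   `separation` and `converged`.
#' @export
recoverability_report <- function(spec, n = 20000, seed = spec$seed) {
  stopifnot(inherits(spec, "nb_cohort_spec"))
  spec$n_patients <- as.integer(n)
  spec$seed <- as.integer(seed)
  cohort <- generate_cohort(spec)
  frame <- model_frame(cohort)
  fit <- fit_logistic(frame[, model_specs()$model1_gcs_hs],
                      code_mortality(cohort$outcome_status) == "death",
                      on_separation = "flag")
  truth <- exp(spec$outcome$death_coefs)
  td <- filter(tidy(fit), .data$term != "(Intercept)")
  out <- tibble(
    term = td$term,
    true_or = unname(truth[td$term]),
    estimate_or = td$or,
    ci_low = td$or_low,
    ci_high = td$or_high
  )
  out$covered <- out$ci_low <= out$true_or & out$true_or <= out$ci_high
  attr(out, "separation") <- fit$separation
  attr(out, "converged") <- fit$converged
  out
}
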