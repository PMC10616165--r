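# DALY engine: life-table years of life lost, disability-weighted years
# lived with disability with multiplicative comorbidity correction, a
# beta-binomial prevalence estimator, and stratified aggregation.

#' Validate or read a life table
#'
#' A life table maps (sex, integer age) to residual life expectancy e_x in
#' years. The lookup domain must cover ages 18-110 for both sexes, all
#' e_x must be positive, and e_x must be non-increasing in age beyond age 1
#' (a small tolerance absorbs table artifacts).
#'
#' @param df A data frame with columns `sex` (`male`/`female`), `age`
#'   (integer years) and `ex` (residual life expectancy, years).
#' @param path Path to a CSV file with those columns.
#' @param tol Allowed increase between consecutive ages (default 0.05
#'   years).
#' @return A validated life-table tibble of class `nb_life_table`.
#' @export
life_table <- function(df, tol = 0.05) {
  df <- as_tibble(df)
  need <- c("sex", "age", "ex")
  if (!all(need %in% names(df))) {
    abort("life table needs columns sex, age, ex",
          class = c("nb_schema_error", "nb_error"))
  }
  check_levels(df$sex, c("male", "female"), "sex")
  if (any(is.na(df$age)) || any(df$age != round(df$age))) {
    abort("life-table ages must be integers",
          class = c("nb_validation_error", "nb_error"))
  }
  if (any(is.na(df$ex)) || any(df$ex <= 0)) {
    abort("residual life expectancy must be positive",
          class = c("nb_validation_error", "nb_error"))
  }
  for (s in c("male", "female")) {
    sub <- arrange(filter(df, .data$sex == s), .data$age)
    if (!all(18:110 %in% sub$age)) {
      abort(sprintf("life table for sex %s must cover ages 18..110", s),
            class = c("nb_validation_error", "nb_error"))
    }
    adult <- filter(sub, .data$age >= 1)
    if (any(diff(adult$ex) > tol)) {
      abort(sprintf(
        "life table for sex %s: e_x increases with age beyond tolerance", s),
        class = c("nb_validation_error", "nb_error"))
    }
  }
  structure(df, class = c("nb_life_table", class(df)))
}

#' @rdname life_table
#' @export
read_life_table <- function(path, tol = 0.05) {
  if (!file.exists(path)) {
    abort(paste0("life-table file not found: ", path),
          class = c("nb_io_error", "nb_error"))
  }
  life_table(readr::read_csv(path, col_types = "cid", progress = FALSE),
             tol = tol)
}

#' Synthetic complete life table
#'
#' Builds a plausible sex-specific complete (single-year) life table for
#' ages 0-110 from a Gompertz-Makeham hazard
#' \eqn{\mu(x) = A + B e^{Cx}} with parameters chosen to give life
#' expectancies at birth of about 73 (male) and 80 (female) years, the
#' order of magnitude of Brazilian period tables. This is a synthetic
#' stand-in for tests and examples; analyses of real cohorts should supply
#' the official national table via [read_life_table()].
#'
#' @return An `nb_life_table` tibble (sex, age, ex) for ages 0-110.
#' @export
synthetic_life_table <- function() {
  gompertz_ex <- function(A, B, C) {
    ages <- 0:111
    mu <- A + B * exp(C * ages)
    surv <- exp(-cumsum(c(0, mu[-length(mu)])))
    ex <- vapply(1:111, function(i) {
      tail_l <- surv[i:112]
      sum((tail_l[-1] + tail_l[-length(tail_l)]) / 2) / surv[i]
    }, numeric(1))
    tibble(age = 0:110, ex = round(ex, 2))
  }
  male <- mutate(gompertz_ex(A = 2.268e-3, B = 3.3e-5, C = 0.093),
                 sex = "male", .before = 1)
  female <- mutate(gompertz_ex(A = 5.31e-4, B = 1.8e-5, C = 0.099),
                   sex = "female", .before = 1)
  life_table(bind_rows(male, female))
}

#' Years of life lost for deaths
#'
#' For each death, YLL is the residual life expectancy at the (sex, age) of
#' death, looked up in a complete life table at the integer age
#' `floor(age)`; no interpolation is performed.
#'
#' @param age Age at death in years (vector).
#' @param sex `"male"` / `"female"` (vector, recycled against `age`).
#' @param lt An [life_table()] object.
#' @return Numeric vector of years of life lost per death.
#' @export
yll <- function(age, sex, lt) {
  stopifnot(inherits(lt, "nb_life_table"))
  if (any(is.na(age)) || any(is.na(sex))) {
    abort("age and sex must be known for every death",
          class = c("nb_domain_error", "nb_error"))
  }
  key <- tibble(sex = as.character(sex), age = floor(as.numeric(age)))
  lo <- min(lt$age); hi <- max(lt$age)
  if (any(key$age < lo | key$age > hi)) {
    abort(sprintf("age at death outside the life-table domain [%d, %d]",
                  lo, hi),
          class = c("nb_domain_error", "nb_error"))
  }
  left_join(key, lt, by = c("sex", "age"))$ex
}

#' Combine disability weights
#'
#' Combines several disability weights into one health-state weight. The
#' default is the multiplicative complement used for comorbidity correction
#' in burden-of-disease work, \eqn{1 - \prod_i (1 - w_i)}: independent
#' decrements of the remaining healthy fraction, bounded below 1. The raw
#' product \eqn{\prod_i w_i} is available for sensitivity analysis.
#'
#' @param w Numeric vector of weights, each in \[0, 1). Empty means no
#'   disability (returns 0).
#' @param method `"complement"` (default) or `"product"`.
#' @return A single combined weight in \[0, 1).
#' @examples
#' combine_weights(c(0.2, 0.5)) # 1 - 0.8 * 0.5 = 0.6
#' @export
combine_weights <- function(w, method = c("complement", "product")) {
  method <- arg_match(method)
  if (length(w) == 0) return(0)
  if (any(is.na(w)) || any(w < 0 | w >= 1)) {
    abort("disability weights must lie in [0, 1)",
          class = c("nb_domain_error", "nb_error"))
  }
  if (method == "complement") 1 - prod(1 - w) else prod(w)
}

#' Disability-weight map for mRS levels and comorbidities
#'
#' Validates a two-part weight map: one weight per modified Rankin Scale
#' level 0-5 (level 0, no symptoms, is fixed at 0) and one weight per
#' recorded comorbidity. All weights must lie in \[0, 1); a non-monotone
#' mRS sequence is only a warning, since published sequela weights are not
#' strictly ordered.
#'
#' @param df A data frame with columns `kind` (`mrs` or `comorbidity`),
#'   `level` (the mRS level 0-5, or the comorbidity name), `weight`.
#' @param path Path to a CSV file with those columns.
#' @return A validated tibble of class `nb_weights`.
#' @export
disability_weights <- function(df) {
  df <- as_tibble(df)
  need <- c("kind", "level", "weight")
  if (!all(need %in% names(df))) {
    abort("weight map needs columns kind, level, weight",
          class = c("nb_schema_error", "nb_error"))
  }
  check_levels(df$kind, c("mrs", "comorbidity"), "kind")
  if (any(is.na(df$weight)) || any(df$weight < 0 | df$weight >= 1)) {
    abort("disability weights must lie in [0, 1)",
          class = c("nb_validation_error", "nb_error"))
  }
  mrs <- filter(df, .data$kind == "mrs")
  if (!setequal(mrs$level, as.character(0:5))) {
    abort("mRS weights must cover levels 0..5 exactly",
          class = c("nb_validation_error", "nb_error"))
  }
  w <- mrs$weight[order(as.integer(mrs$level))]
  if (w[1] != 0) {
    abort("the weight of mRS 0 (no symptoms) must be 0",
          class = c("nb_validation_error", "nb_error"))
  }
  if (is.unsorted(w)) {
    warn("mRS disability weights are not monotone in severity")
  }
  cm <- filter(df, .data$kind == "comorbidity")
  bad <- setdiff(cm$level, sub("^cm_", "", comorbidity_columns()))
  if (length(bad) > 0) {
    abort(paste0("unknown comorbidity level(s): ",
                 paste(bad, collapse = ", ")),
          class = c("nb_validation_error", "nb_error"))
  }
  structure(df, class = c("nb_weights", class(df)))
}

#' @rdname disability_weights
#' @export
read_disability_weights <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("weights file not found: ", path),
          class = c("nb_io_error", "nb_error"))
  }
  disability_weights(readr::read_csv(path, col_types = "ccd",
                                     progress = FALSE))
}

#' Synthetic disability-weight map
#'
#' A synthetic weight map for tests and examples: mRS levels 1-5 carry the
#' published sequela weights commonly used for stroke severity levels
#' (0.019, 0.070, 0.316, 0.552, 0.588) and the six recorded comorbidities
#' carry plausible chronic-disease weights. Real analyses should supply
#' their own map via [read_disability_weights()].
#'
#' @return An `nb_weights` tibble.
#' @export
synthetic_disability_weights <- function() {
  disability_weights(bind_rows(
    tibble(kind = "mrs", level = as.character(0:5),
           weight = c(0, 0.019, 0.070, 0.316, 0.552, 0.588)),
    tibble(kind = "comorbidity",
           level = c("hypertension", "cardiopathy", "copd", "renal",
                     "diabetes", "extracranial_neoplasia"),
           weight = c(0.020, 0.072, 0.188, 0.104, 0.049, 0.288))
  ))
}

weight_lookup <- function(dw) {
  mrs <- filter(dw, .data$kind == "mrs")
  cm <- filter(dw, .data$kind == "comorbidity")
  list(
    mrs = setNames(mrs$weight, mrs$level),
    comorbidity = setNames(cm$weight, paste0("cm_", cm$level))
  )
}

#' Five-year age bands
#'
#' @param age Numeric ages in years.
#' @param width Band width in years (default 5).
#' @return Factor of half-open bands `[lo, lo+width)` labelled `"lo-hi"`.
#' @export
age_band <- function(age, width = 5) {
  lo <- floor(age / width) * width
  all_lo <- seq(0, max(c(lo, 0), na.rm = TRUE), by = width)
  labels <- sprintf("%d-%d", all_lo, all_lo + width - 1)
  factor(sprintf("%d-%d", lo, lo + width - 1), levels = labels)
}

#' Stratified prevalence by beta-binomial shrinkage
#'
#' Estimates, within each (sex, age band) stratum, the proportion of
#' patients carrying each diagnosis, as the posterior mean of a
#' beta-binomial model: a Beta prior of strength `prior_strength` centred
#' at `prior_mean` (by default the pooled proportion of that diagnosis)
#' shrinks small strata toward the pooled rate. The interval is the central
#' 95% of the posterior. This is a transparent shrinkage estimator for
#' within-cohort composition, not a population meta-regression.
#'
#' @param cohort A validated cohort tibble.
#' @param band_width Age-band width in years (default 5).
#' @param prior_strength Prior pseudo-count (default 2; `prior_strength = 2`
#'   with `prior_mean = 0.5` is the flat Beta(1,1) prior).
#' @param prior_mean Prior mean; `NULL` (default) uses each diagnosis's
#'   pooled proportion.
#' @return A tibble of class `nb_prevalence` with one row per
#'   (diagnosis_group, sex, age_band): `k`, `n`, `estimate`, `ci_low`,
#'   `ci_high`, `empty_stratum`.
#' @export
estimate_prevalence <- function(cohort, band_width = 5, prior_strength = 2,
                                prior_mean = NULL) {
  cohort <- as_tibble(cohort)
  if (nrow(cohort) == 0) {
    abort("cohort is empty", class = c("nb_domain_error", "nb_error"))
  }
  cohort$age_band <- age_band(cohort$age, band_width)
  strata <- tidyr::expand_grid(
    diagnosis_group = diagnosis_groups(),
    sex = c("male", "female"),
    age_band = levels(cohort$age_band)
  )
  totals <- count(cohort, .data$sex, .data$age_band,
                  name = "n", .drop = FALSE)
  totals$age_band <- as.character(totals$age_band)
  hits <- count(cohort, .data$diagnosis_group, .data$sex, .data$age_band,
                name = "k")
  hits$age_band <- as.character(hits$age_band)
  pooled <- count(cohort, .data$diagnosis_group, name = "k_all")
  pooled$pooled_rate <- pooled$k_all / nrow(cohort)
  out <- left_join(strata, totals, by = c("sex", "age_band"))
  out <- left_join(out, hits, by = c("diagnosis_group", "sex", "age_band"))
  out <- left_join(out, select(pooled, "diagnosis_group", "pooled_rate"),
                   by = "diagnosis_group")
  out$n[is.na(out$n)] <- 0L
  out$k[is.na(out$k)] <- 0L
  out$pooled_rate[is.na(out$pooled_rate)] <- 0
  pm <- if (is.null(prior_mean)) out$pooled_rate else
    rep(prior_mean, nrow(out))
  pm <- pmin(pmax(pm, 1e-6), 1 - 1e-6)
  a <- prior_strength * pm
  b <- prior_strength * (1 - pm)
  out <- mutate(out,
                empty_stratum = .data$n == 0,
                estimate = (.data$k + a) / (.data$n + a + b),
                ci_low = qbeta(0.025, .data$k + a, .data$n - .data$k + b),
                ci_high = qbeta(0.975, .data$k + a, .data$n - .data$k + b))
  out <- select(out, "diagnosis_group", "sex", "age_band", "k", "n",
                "estimate", "ci_low", "ci_high", "empty_stratum")
  structure(out, class = c("nb_prevalence", class(out)))
}

# per-patient disability weight: mRS weight combined with the patient's
# comorbidity weights
patient_weights <- function(cohort, dw, method) {
  lk <- weight_lookup(dw)
  cm_cols <- intersect(comorbidity_columns(), names(cohort))
  vapply(seq_len(nrow(cohort)), function(i) {
    mrs_i <- cohort$mrs[i]
    if (is.na(mrs_i) || mrs_i == 6) return(NA_real_)
    ws <- lk$mrs[[as.character(mrs_i)]]
    for (col in cm_cols) {
      if (isTRUE(cohort[[col]][i]) && col %in% names(lk$comorbidity)) {
        ws <- c(ws, lk$comorbidity[[col]])
      }
    }
    combine_weights(ws, method = method)
  }, numeric(1))
}

#' Years lived with disability for a cohort
#'
#' Each survivor contributes `combine_weights(mRS weight, comorbidity
#' weights) * horizon_years * prevalence scaling`; deaths contribute zero.
#' Survivors with missing mRS are excluded and counted, never imputed. With
#' `prev` supplied, each contribution is additionally scaled by the
#' prevalence estimate of that patient's (diagnosis, sex, age band)
#' stratum; by default the scaling is 1.
#'
#' @param cohort A validated cohort tibble.
#' @param dw A [disability_weights()] map.
#' @param prev Optional [estimate_prevalence()] result for stratum scaling.
#' @param horizon_years Duration in years each survivor is counted as
#'   living in the state (default 1; use `30 / 365.25` for the 30-day
#'   follow-up window).
#' @param method Weight combination rule, see [combine_weights()].
#' @return A list with `yld_total`, the per-patient tibble `contributions`
#'   (`patient_id`, `yld`), and `n_excluded_missing_mrs`.
#' @export
yld <- function(cohort, dw, prev = NULL, horizon_years = 1,
                method = c("complement", "product")) {
  method <- arg_match(method)
  stopifnot(inherits(dw, "nb_weights"))
  if (horizon_years <= 0) {
    abort("`horizon_years` must be positive",
          class = c("nb_domain_error", "nb_error"))
  }
  cohort <- as_tibble(cohort)
  if (nrow(cohort) == 0) {
    return(list(yld_total = 0,
                contributions = tibble(patient_id = character(), yld = double()),
                n_excluded_missing_mrs = 0L))
  }
  death <- code_mortality(cohort$outcome_status) == "death"
  missing_mrs <- !death & is.na(cohort$mrs)
  w <- patient_weights(cohort, dw, method)
  scale <- rep(1, nrow(cohort))
  if (!is.null(prev)) {
    stopifnot(inherits(prev, "nb_prevalence"))
    key <- tibble(diagnosis_group = cohort$diagnosis_group,
                  sex = cohort$sex,
                  age_band = as.character(age_band(cohort$age)))
    scale <- left_join(key, prev,
                       by = c("diagnosis_group", "sex", "age_band"))$estimate
    scale[is.na(scale)] <- 1
  }
  contrib <- if_else(death | missing_mrs, 0, w * horizon_years * scale)
  list(
    yld_total = sum(contrib),
    contributions = tibble(patient_id = cohort$patient_id, yld = contrib),
    n_excluded_missing_mrs = sum(missing_mrs)
  )
}

#' Disability-adjusted life-years for a cohort
#'
#' Computes DALY = YLL + YLD per patient and in aggregate. Deaths
#' contribute their residual life expectancy at the age and sex of death
#' (YLL); survivors contribute their disability-weighted, comorbidity-
#' corrected time lived (YLD). Results are stratified by primary diagnosis,
#' 5-year age band, age band within sex, and Hs category; every stratum
#' table sums back to the totals exactly.
#'
#' @inheritParams yld
#' @param lt A [life_table()].
#' @return An object of class `nb_burden`: `totals` (one-row tibble with
#'   `yll`, `yld`, `daly`), stratum tables `by_diagnosis`, `by_age_band`,
#'   `by_age_sex`, `by_hs`, the per-patient `ledger`, and
#'   `n_excluded_missing_mrs`.
#' @export
compute_dalys <- function(cohort, lt, dw, prev = NULL, horizon_years = 1,
                          method = c("complement", "product")) {
  method <- arg_match(method)
  stopifnot(inherits(lt, "nb_life_table"))
  cohort <- as_tibble(cohort)
  if (nrow(cohort) == 0) {
    zero <- tibble(yll = 0, yld = 0, daly = 0)
    empty <- tibble(stratum = character(), yll = double(), yld = double(),
                    daly = double())
    return(structure(list(totals = zero, by_diagnosis = empty,
                          by_age_band = empty, by_age_sex = empty,
                          by_hs = empty,
                          ledger = tibble(), n_excluded_missing_mrs = 0L),
                     class = "nb_burden"))
  }
  cohort <- resolve_hs(cohort)
  death <- code_mortality(cohort$outcome_status) == "death"
  yll_i <- rep(0, nrow(cohort))
  if (any(death)) {
    yll_i[death] <- yll(cohort$age[death], cohort$sex[death], lt)
  }
  yld_res <- yld(cohort, dw, prev = prev, horizon_years = horizon_years,
                 method = method)
  ledger <- tibble(
    patient_id = cohort$patient_id,
    diagnosis_group = cohort$diagnosis_group,
    sex = cohort$sex,
    age_band = as.character(age_band(cohort$age)),
    hs_category = as.character(cohort$hs_category),
    death = death,
    yll = yll_i,
    yld = yld_res$contributions$yld,
    daly = yll_i + yld_res$contributions$yld
  )
  strat <- function(...) {
    summarise(group_by(ledger, ...), yll = sum(.data$yll),
              yld = sum(.data$yld), daly = sum(.data$daly), .groups = "drop")
  }
  structure(
    list(
      totals = tibble(yll = sum(ledger$yll), yld = sum(ledger$yld),
                      daly = sum(ledger$daly)),
      by_diagnosis = strat(.data$diagnosis_group),
      by_age_band = strat(.data$age_band),
      by_age_sex = strat(.data$sex, .data$age_band),
      by_hs = strat(.data$hs_category),
      ledger = ledger,
      n_excluded_missing_mrs = yld_res$n_excluded_missing_mrs
    ),
    class = "nb_burden"
  )
}

#' @export
print.nb_burden <- function(x, ...) {
  cat(sprintf("<nb_burden> YLL %.3f + YLD %.3f = DALY %.3f (%d patients",
              x$totals$yll, x$totals$yld, x$totals$daly, nrow(x$ledger)))
  if (x$n_excluded_missing_mrs > 0) {
    cat(sprintf("; %d survivors excluded for missing mRS",
                x$n_excluded_missing_mrs))
  }
  cat(")\n")
  print(x$by_diagnosis, ...)
  invisible(x)
}

#' Tidy and summarise a burden result
#'
#' `tidy()` returns one stratum table in long form; `glance()` the totals.
#'
#' @param x An `nb_burden` object.
#' @param stratum One of `"diagnosis"`, `"age_band"`, `"age_sex"`, `"hs"`,
#'   `"patient"`.
#' @param ... Unused.
#' @method tidy nb_burden
#' @export
tidy.nb_burden <- function(x, stratum = c("diagnosis", "age_band",
                                          "age_sex", "hs", "patient"), ...) {
  stratum <- arg_match(stratum)
  switch(stratum,
         diagnosis = x$by_diagnosis,
         age_band = x$by_age_band,
         age_sex = x$by_age_sex,
         hs = x$by_hs,
         patient = x$ledger)
}

#' @rdname tidy.nb_burden
#' @method glance nb_burden
#' @export
glance.nb_burden <- function(x, ...) {
  mutate(x$totals, n_patients = nrow(x$ledger),
         n_excluded_missing_mrs = x$n_excluded_missing_mrs)
}
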