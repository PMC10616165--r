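# Report tables: cohort descriptives in the shape of a baseline table and
# the univariate odds-ratio table for both outcomes. Print precision is
# frozen (percent to 1 decimal, OR/CI to 3) so fixture diffs are meaningful.

fmt_count_pct <- function(k, n) sprintf("%d (%s)", k, format_num(proportion(k, n), 1))
fmt_num <- function(x, d) format_num(x, d)
format_num <- function(x, d) {
  formatC(round(x, d), format = "f", digits = d)
}
fmt_median_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE, type = 2)
  sprintf("%s (%s-%s)", format_num(q[2], 1), format_num(q[1], 1),
          format_num(q[3], 1))
}
fmt_mean_sd <- function(x) {
  sprintf("%s ± %s", format_num(mean(x, na.rm = TRUE), 1),
          format_num(sd(x, na.rm = TRUE), 1))
}

desc_row <- function(section, label, value, n_missing = 0L) {
  tibble(section = section, label = label, value = value,
         n_missing = as.integer(n_missing))
}

#' Cohort descriptive summary table
#'
#' Summarises a cohort in the layout of a baseline-characteristics table:
#' categorical rows as n (% within column), quantitative rows as
#' median (IQR) or mean +/- SD, with per-variable missing counts footnoted
#' in the `n_missing` column. Optional columns that are entirely absent are
#' suppressed with a message.
#'
#' @param cohort A validated cohort tibble.
#' @return A tibble with columns `section`, `label`, `value`, `n_missing`.
#' @export
report_descriptives <- function(cohort) {
  cohort <- resolve_hs(validate_cohort(cohort))
  n <- nrow(cohort)
  cat_rows <- function(section, x, levels, labels = levels) {
    map_dfr(seq_along(levels), function(i) {
      desc_row(section, labels[i], fmt_count_pct(sum(x == levels[i],
                                                     na.rm = TRUE), n),
               sum(is.na(x)))
    })
  }
  out <- bind_rows(
    desc_row("baseline", "n", as.character(n)),
    desc_row("baseline", "age_years_mean_sd", fmt_mean_sd(cohort$age)),
    desc_row("baseline", "male_sex", fmt_count_pct(sum(cohort$sex == "male"), n)),
    cat_rows("insurance", cohort$insurance, c("public", "private")),
    cat_rows("admission_type", cohort$admission_type,
             c("elective", "emergency")),
    cat_rows("location_before_icu", cohort$location_before_icu,
             c("emergency_department", "operating_room", "ward", "other")),
    desc_row("severity", "gcs_median_iqr", fmt_median_iqr(cohort$gcs)),
    desc_row("severity", "apache2_median_iqr", fmt_median_iqr(cohort$apache2),
             sum(is.na(cohort$apache2))),
    desc_row("severity", "saps3_median_iqr", fmt_median_iqr(cohort$saps3),
             sum(is.na(cohort$saps3))),
    desc_row("severity", "sofa_median_iqr", fmt_median_iqr(cohort$sofa),
             sum(is.na(cohort$sofa)))
  )
  cm_present <- intersect(comorbidity_columns(), names(cohort))
  if (length(cm_present) < length(comorbidity_columns())) {
    inform(paste0("comorbidity column(s) absent, rows suppressed: ",
                  paste(setdiff(comorbidity_columns(), cm_present),
                        collapse = ", ")))
  }
  for (col in cm_present) {
    out <- bind_rows(out, desc_row("comorbidities", sub("^cm_", "", col),
                                   fmt_count_pct(sum(cohort[[col]]), n)))
  }
  out <- bind_rows(
    out,
    cat_rows("diagnosis", cohort$diagnosis_group, diagnosis_groups()),
    map_dfr(hs_columns(), function(col) {
      desc_row("hs", sub("^hs_", "", col),
               fmt_count_pct(sum(cohort[[col]]), n))
    }),
    cat_rows("hs_count", as.character(cohort$hs_category),
             hs_category_levels()),
    cat_rows("outcome", cohort$outcome_status, outcome_status_levels()),
    cat_rows("mrs", cohort$mrs, 0:6, paste0("mrs_", 0:6)),
    desc_row("outcome", "unfavourable_mrs_4_6",
             fmt_count_pct(sum(cohort$mrs >= 4, na.rm = TRUE),
                           sum(!is.na(cohort$mrs))),
             sum(is.na(cohort$mrs))),
    desc_row("outcome", "los_days_median_iqr", fmt_median_iqr(cohort$los_days))
  )
  out
}

or_row <- function(factor_lbl, level_lbl, outcome_lbl, events, total,
                   or_tbl = NULL, note = "") {
  tibble(
    factor = factor_lbl, level = level_lbl, outcome = outcome_lbl,
    events = events, total = total,
    or = if (is.null(or_tbl)) NA_real_ else or_tbl$or,
    ci_low = if (is.null(or_tbl)) NA_real_ else or_tbl$ci_low,
    ci_high = if (is.null(or_tbl)) NA_real_ else or_tbl$ci_high,
    p_value = if (is.null(or_tbl)) NA_real_ else or_tbl$p_value,
    note = note
  )
}

# 2x2 OR rows of one categorical factor against one binary outcome vector,
# flagging degenerate strata instead of dropping them
categorical_or_rows <- function(factor_lbl, x, ref, levels_other, y,
                                outcome_lbl) {
  keep <- !is.na(y) & !is.na(x)
  x <- x[keep]; y <- y[keep]
  ref_events <- sum(x == ref & y)
  ref_non <- sum(x == ref & !y)
  rows <- or_row(factor_lbl, paste0(ref, " (ref)"), outcome_lbl,
                 ref_events, ref_events + ref_non)
  for (lv in levels_other) {
    ev <- sum(x == lv & y); non <- sum(x == lv & !y)
    cells <- c(ev, non, ref_events, ref_non)
    if (any(cells == 0)) {
      rows <- bind_rows(rows, or_row(factor_lbl, lv, outcome_lbl, ev,
                                     ev + non,
                                     note = "degenerate stratum (zero cell)"))
    } else {
      rows <- bind_rows(rows, or_row(factor_lbl, lv, outcome_lbl, ev,
                                     ev + non,
                                     odds_ratio(ev, non, ref_events, ref_non)))
    }
  }
  rows
}

# per-unit OR of a continuous covariate from a univariate logistic fit
continuous_or_row <- function(factor_lbl, x, y, outcome_lbl) {
  keep <- !is.na(y) & !is.na(x)
  if (sum(keep) == 0 || length(unique(y[keep])) < 2 ||
      length(unique(x[keep])) < 2) {
    return(or_row(factor_lbl, "per_unit", outcome_lbl, sum(y[keep],
                                                           na.rm = TRUE),
                  sum(keep), note = "degenerate (constant column)"))
  }
  fit <- fit_logistic(matrix(x[keep], dimnames = list(NULL, factor_lbl)),
                      y[keep], on_separation = "flag")
  td <- filter(tidy(fit), .data$term == factor_lbl)
  or_row(factor_lbl, "per_unit", outcome_lbl, sum(y[keep]), fit$n_used,
         tibble(or = td$or, ci_low = td$or_low, ci_high = td$or_high,
                p_value = td$p_value),
         note = if (fit$separation) "separation" else "")
}

#' Univariate odds-ratio table for both outcomes
#'
#' Builds the unadjusted prognostic-factor table: 2x2 odds ratios for sex
#' (male vs female), Hs category (one/two/three+ vs zero), insurance
#' (public vs private) and admission type (emergency vs elective), and
#' per-unit odds ratios from univariate logistic fits for age, GCS,
#' APACHE II, SAPS III and SOFA - each against 30-day ICU mortality and
#' against unfavourable outcome (mRS 4-6). Degenerate strata (a zero cell,
#' a single observed level) are flagged in the `note` column, never
#' silently dropped.
#'
#' @param cohort A validated cohort tibble.
#' @return A tidy tibble with one row per factor level and outcome.
#' @export
report_univariate <- function(cohort) {
  cohort <- code_outcomes(resolve_hs(validate_cohort(cohort)))
  outcomes <- list(mortality = cohort$death,
                   unfavourable = cohort$unfavourable)
  map_dfr(names(outcomes), function(o) {
    y <- outcomes[[o]]
    bind_rows(
      categorical_or_rows("sex", cohort$sex, "female", "male", y, o),
      categorical_or_rows("hs_category", as.character(cohort$hs_category),
                          "zero", c("one", "two", "three_plus"), y, o),
      categorical_or_rows("insurance", cohort$insurance, "private",
                          "public", y, o),
      categorical_or_rows("admission_type", cohort$admission_type,
                          "elective", "emergency", y, o),
      continuous_or_row("age", cohort$age, y, o),
      continuous_or_row("gcs", cohort$gcs, y, o),
      continuous_or_row("apache2", cohort$apache2, y, o),
      continuous_or_row("saps3", cohort$saps3, y, o),
      continuous_or_row("sofa", cohort$sofa, y, o)
    )
  })
}

#' Write a report table to CSV with a provenance header
#'
#' Prepends `#`-prefixed provenance lines (package version, seed if given)
#' and writes the table with the package's frozen print precision: odds
#' ratios and confidence bounds to 3 decimals.
#'
#' @param report A tibble from [report_descriptives()] or
#'   [report_univariate()].
#' @param path Output path.
#' @param seed Optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NULL) {
  header <- c(
    sprintf("# generated by neuroburden %s",
            as.character(utils::packageVersion("neuroburden"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed))
  )
  out <- mutate(report, across(dplyr::where(is.double),
                               ~ round(.x, 3)))
  body <- sub("\n$", "", readr::format_csv(out, na = ""))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}
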