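test_that("combine_weights follows the multiplicative-complement rule", {
  expect_identical(combine_weights(numeric(0)), 0)
  expect_equal(combine_weights(0.37), 0.37)
  expect_equal(combine_weights(c(0.2, 0.5)), 0.6)
  expect_equal(combine_weights(c(0.2, 0.5), method = "product"), 0.1)
  # order invariance, bounds: max(w) <= combined <= sum(w), and < 1
  set.seed(3)
  for (i in 1:30) {
    w <- runif(sample(1:5, 1), 0, 0.95)
    cw <- combine_weights(w)
    expect_equal(cw, combine_weights(sample(w)), tolerance = 1e-12)
    expect_gte(cw, max(w))
    expect_lte(cw, sum(w))
    expect_lt(cw, 1)
  }
  expect_error(combine_weights(1), class = "nb_domain_error")
  expect_error(combine_weights(-0.1), class = "nb_domain_error")
})

test_that("life-table validation enforces domain and monotonicity", {
  lt <- toy_life_table()
  expect_s3_class(lt, "nb_life_table")
  broken <- lt
  broken$ex[broken$sex == "male" & broken$age == 50] <- 99
  expect_error(life_table(broken), class = "nb_validation_error")
  short <- lt[lt$age <= 80, ]
  expect_error(life_table(short), class = "nb_validation_error")
})

test_that("yll is a floor-age life-table lookup", {
  lt <- toy_life_table()
  expect_equal(yll(70, "male", lt), 20)
  expect_equal(yll(70.9, "male", lt), 20) # floor, no interpolation
  expect_equal(sum(yll(c(70, 99, 109), c("male", "female", "male"), lt)),
               20 + 5.5 + 0.5)
  expect_error(yll(150, "male", lt), class = "nb_domain_error")
  expect_error(yll(NA, "male", lt), class = "nb_domain_error")
})

test_that("yld hand-computed cases and exclusion of missing mRS", {
  dw <- toy_weights()
  one <- make_patient(mrs = 3L) # weight 0.3, no comorbidity
  res <- yld(one, dw)
  expect_equal(res$yld_total, 0.3)

  two <- dplyr::bind_rows(
    make_patient(patient_id = "A", mrs = 3L, cm_hypertension = TRUE),
    make_patient(patient_id = "B", mrs = 0L))
  # 1 - 0.7 * 0.9 = 0.37 plus 0
  expect_equal(yld(two, dw)$yld_total, 0.37)

  missing <- make_patient(mrs = NA_integer_)
  res3 <- yld(missing, dw)
  expect_equal(res3$yld_total, 0)
  expect_identical(res3$n_excluded_missing_mrs, 1L)

  # doubling the horizon doubles YLD
  expect_equal(yld(two, dw, horizon_years = 2)$yld_total, 0.74)
})

test_that("the five-patient fixture matches the hand-computed burden", {
  res <- compute_dalys(toy_burden_cohort(), toy_life_table(), toy_weights())
  expect_equal(res$totals$yll, 30, tolerance = 1e-9)
  expect_equal(res$totals$yld, 0.51 + 0.712, tolerance = 1e-9)
  expect_equal(res$totals$daly, 31.222, tolerance = 1e-9)
  expect_identical(res$n_excluded_missing_mrs, 0L)
})

test_that("DALY additivity and stratum reconciliation hold exactly", {
  cohort <- generate_cohort(cohort_spec(n_patients = 600, seed = 27))
  res <- compute_dalys(cohort, toy_life_table(), toy_weights())
  expect_equal(res$totals$daly, res$totals$yll + res$totals$yld,
               tolerance = 1e-9)
  for (strat in c("diagnosis", "age_band", "age_sex", "hs", "patient")) {
    tb <- tidy(res, stratum = strat)
    expect_equal(sum(tb$yll), res$totals$yll, tolerance = 1e-9)
    expect_equal(sum(tb$yld), res$totals$yld, tolerance = 1e-9)
    expect_equal(sum(tb$daly), res$totals$daly, tolerance = 1e-9)
  }
})

test_that("degenerate cohorts reduce to pure-YLL or pure-YLD calculators", {
  # empty cohort
  empty <- compute_dalys(make_patient()[0, ], toy_life_table(),
                         toy_weights())
  expect_equal(empty$totals$daly, 0)
  # all survivors: no YLL
  surv <- dplyr::bind_rows(make_patient(mrs = 2L),
                           make_patient(patient_id = "P2", mrs = 4L))
  res_s <- compute_dalys(surv, toy_life_table(), toy_weights())
  expect_equal(res_s$totals$yll, 0)
  expect_gt(res_s$totals$yld, 0)
  # all deaths: no YLD
  dead <- dplyr::bind_rows(
    make_patient(outcome_status = "death", mrs = 6L),
    make_patient(patient_id = "P2", age = 80L, outcome_status = "death",
                 mrs = 6L))
  res_d <- compute_dalys(dead, toy_life_table(), toy_weights())
  expect_equal(res_d$totals$yld, 0)
  expect_equal(res_d$totals$daly, res_d$totals$yll)
  # all weights zero: engine is a YLL calculator
  dw0 <- disability_weights(dplyr::mutate(toy_weights(), weight = 0))
  mix <- dplyr::bind_rows(surv, dead)
  res0 <- compute_dalys(mix, toy_life_table(), dw0)
  expect_equal(res0$totals$yld, 0)
  expect_equal(res0$totals$daly, res0$totals$yll)
})

test_that("turning a survivor into a death never lowers the cohort DALY", {
  cohort <- generate_cohort(cohort_spec(n_patients = 300, seed = 41))
  lt <- toy_life_table(); dw <- toy_weights()
  base <- compute_dalys(cohort, lt, dw)
  surv_idx <- which(cohort$outcome_status != "death" & !is.na(cohort$mrs))
  for (i in surv_idx[1:10]) {
    flipped <- cohort
    flipped$outcome_status[i] <- "death"
    flipped$mrs[i] <- 6L
    res <- compute_dalys(flipped, lt, dw)
    expect_gte(res$totals$daly, base$totals$daly - 1e-9)
  }
})

test_that("horizon scaling moves YLD and only YLD", {
  cohort <- generate_cohort(cohort_spec(n_patients = 400, seed = 52))
  lt <- toy_life_table(); dw <- toy_weights()
  h1 <- compute_dalys(cohort, lt, dw, horizon_years = 1)
  h2 <- compute_dalys(cohort, lt, dw, horizon_years = 2)
  expect_equal(h2$totals$yld, 2 * h1$totals$yld, tolerance = 1e-9)
  expect_equal(h2$totals$yll, h1$totals$yll, tolerance = 1e-12)
  h30 <- compute_dalys(cohort, lt, dw, horizon_years = 30 / 365.25)
  expect_equal(h30$totals$yld, h1$totals$yld * 30 / 365.25,
               tolerance = 1e-9)
})

test_that("beta-binomial prevalence has the conjugate closed form", {
  cohort <- generate_cohort(cohort_spec(n_patients = 400, seed = 63))
  prev <- estimate_prevalence(cohort, prior_strength = 2, prior_mean = 0.5)
  expect_equal(prev$estimate, (prev$k + 1) / (prev$n + 2), tolerance = 1e-12)
  expect_true(all(prev$ci_low <= prev$estimate + 1e-12))
  expect_true(all(prev$estimate <= prev$ci_high + 1e-12))
  # empty strata fall back to the prior mean, flagged
  empty <- prev[prev$empty_stratum, ]
  if (nrow(empty) > 0) expect_true(all(abs(empty$estimate - 0.5) < 1e-9))
  # a stratum where everyone has the diagnosis tends to 1 with n
  uni <- make_patient()[rep(1, 2000), ]
  uni$patient_id <- sprintf("P%04d", 1:2000)
  p_uni <- estimate_prevalence(uni, prior_strength = 2, prior_mean = 0.5)
  big <- p_uni[p_uni$diagnosis_group == "IS" & p_uni$n == 2000, ]
  expect_equal(big$estimate, 2001 / 2002, tolerance = 1e-12)
})

test_that("prevalence estimates recover known stratum rates", {
  set.seed(17)
  n <- 50000
  sexes <- sample(c("male", "female"), n, TRUE)
  ages <- sample(20:79, n, TRUE)
  band <- floor(ages / 5) # 5-year bands
  # diagnosis rates vary smoothly by band; known truth per stratum
  p_tbi <- 0.1 + 0.004 * (15 - band)
  diag <- ifelse(runif(n) < p_tbi, "TBI", "IS")
  cohort <- make_patient()[rep(1, n), ]
  cohort$patient_id <- sprintf("P%05d", 1:n)
  cohort$sex <- sexes
  cohort$age <- as.integer(ages)
  cohort$diagnosis_group <- diag
  prev <- estimate_prevalence(cohort)
  tbi <- prev[prev$diagnosis_group == "TBI" & prev$n > 0, ]
  truth <- 0.1 + 0.004 *
    (15 - as.integer(sub("-.*", "", tbi$age_band)) / 5)
  expect_lt(mean(abs(tbi$estimate - truth)), 0.02)
})

test_that("weight maps are validated", {
  bad <- toy_weights()
  bad$weight[bad$kind == "mrs" & bad$level == "0"] <- 0.1
  expect_error(disability_weights(bad), class = "nb_validation_error")
  nonmono <- toy_weights()
  nonmono$weight[nonmono$kind == "mrs" & nonmono$level == "4"] <- 0.25
  expect_warning(disability_weights(nonmono), "monotone")
  expect_error(disability_weights(dplyr::tibble(kind = "mrs", level = "0",
                                                weight = 0)),
               class = "nb_validation_error")
})

test_that("bundled synthetic tables load through the file readers", {
  lt_path <- system.file("extdata", "life_table_synthetic.csv",
                         package = "neuroburden")
  dw_path <- system.file("extdata", "disability_weights_synthetic.csv",
                         package = "neuroburden")
  lt <- read_life_table(lt_path)
  dw <- read_disability_weights(dw_path)
  expect_s3_class(lt, "nb_life_table")
  expect_s3_class(dw, "nb_weights")
  expect_equal(as.data.frame(lt), as.data.frame(synthetic_life_table()))
  expect_equal(as.data.frame(dw),
               as.data.frame(synthetic_disability_weights()))
})
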