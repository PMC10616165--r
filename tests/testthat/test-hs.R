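test_that("classify_hs agrees with a brute-force oracle on random snapshots", {
  snaps <- random_snapshots(2000, seed = 101)
  got <- classify_hs(snaps)
  for (i in seq_len(nrow(snaps))) {
    want <- oracle_hs_flags(snaps[i, ])
    have <- unlist(got[i, hs_columns()])
    names(have) <- sub("^hs_", "", names(have))
    expect_identical(have, want)
  }
  expect_identical(got$hs_count,
                   as.integer(rowSums(got[, hs_columns()])))
  expect_identical(as.character(got$hs_category),
                   as.character(hs_categorize(got$hs_count)))
})

test_that("values exactly at a threshold never fire a flag", {
  at_threshold <- normal_snapshot(
    map_mmhg = 65, sbp_mmhg = 90, pao2_mmhg = 60, sao2_pct = 90,
    spo2_pct = 90, temp_c = 37.5, paco2_mmhg = 45, rr_ipm = 8,
    glucose_mg_dl = 60, sodium_mmol_l = 135, icp_mmhg = 25
  )
  res <- classify_hs(at_threshold)
  expect_identical(res$hs_count, 0L)
  expect_identical(as.character(res$hs_category), "zero")
  # PaCO2 = 35 sits between the hypocapnia and hypercapnia cut-offs
  res2 <- classify_hs(normal_snapshot(paco2_mmhg = 35))
  expect_false(res2$hs_hypocapnia)
  expect_false(res2$hs_hypercapnia)
  # one tenth past the threshold fires
  expect_true(classify_hs(normal_snapshot(map_mmhg = 64.9))$hs_hypotension)
  expect_true(classify_hs(normal_snapshot(temp_c = 37.6))$hs_hyperthermia)
})

test_that("single abnormal measurements map to the expected profile", {
  res <- classify_hs(normal_snapshot(map_mmhg = 60))
  expect_true(res$hs_hypotension)
  expect_identical(res$hs_count, 1L)
  expect_identical(as.character(res$hs_category), "one")

  res3 <- classify_hs(normal_snapshot(paco2_mmhg = 34, temp_c = 34.5,
                                      sodium_mmol_l = 130))
  expect_true(all(unlist(
    res3[, c("hs_hypocapnia", "hs_hypothermia", "hs_hyponatremia")])))
  expect_identical(res3$hs_count, 3L)
  expect_identical(as.character(res3$hs_category), "three_plus")
})

test_that("missing measurements never fire and all-missing input warns", {
  blank <- normal_snapshot()
  blank[1, setdiff(physiology_columns(), "herniation_clinical")] <- NA_real_
  blank$herniation_clinical <- NA
  expect_warning(res <- classify_hs(blank), "uninformative")
  expect_identical(res$hs_count, 0L)
})

test_that("pushing a measurement further past its threshold never removes a flag", {
  snaps <- random_snapshots(300, seed = 202)
  base <- classify_hs(snaps)
  # fields whose single rule fires in one direction: push further that way
  worsen <- list(map_mmhg = -5, sbp_mmhg = -5, pao2_mmhg = -5,
                 sao2_pct = -3, spo2_pct = -3, rr_ipm = -2,
                 glucose_mg_dl = -10, sodium_mmol_l = -4, icp_mmhg = 6)
  check_superset <- function(pushed, col) {
    res <- classify_hs(pushed)
    for (hc in hs_columns()) {
      expect_true(all(res[[hc]] >= base[[hc]], na.rm = TRUE),
                  info = paste("worsening", col, "lost flag", hc))
    }
  }
  for (col in names(worsen)) {
    pushed <- snaps
    pushed[[col]] <- pushed[[col]] + worsen[[col]]
    pushed$sao2_pct <- pmax(pushed$sao2_pct, 0)
    pushed$spo2_pct <- pmax(pushed$spo2_pct, 0)
    check_superset(pushed, col)
  }
  # temperature and PaCO2 have opposing thresholds: push each row further
  # past the threshold it has already crossed, leave the rest unchanged
  pushed <- snaps
  pushed$temp_c <- ifelse(!is.na(snaps$temp_c) & snaps$temp_c > 37.5,
                          snaps$temp_c + 1,
                          ifelse(!is.na(snaps$temp_c) & snaps$temp_c < 35,
                                 snaps$temp_c - 1, snaps$temp_c))
  check_superset(pushed, "temp_c")
  pushed <- snaps
  pushed$paco2_mmhg <- ifelse(
    !is.na(snaps$paco2_mmhg) & snaps$paco2_mmhg > 45, snaps$paco2_mmhg + 5,
    ifelse(!is.na(snaps$paco2_mmhg) & snaps$paco2_mmhg < 35,
           snaps$paco2_mmhg - 5, snaps$paco2_mmhg))
  check_superset(pushed, "paco2_mmhg")
})

test_that("hs category partition is exhaustive and exclusive", {
  counts <- 0:10
  cats <- hs_categorize(counts)
  expect_false(anyNA(cats))
  expect_identical(as.character(cats),
                   c("zero", "one", "two", rep("three_plus", 8)))
  expect_error(hs_categorize(11), class = "nb_domain_error")
  cohort <- generate_cohort(cohort_spec(n_patients = 500, seed = 5))
  expect_identical(sum(table(cohort$hs_category)), 500L)
})
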