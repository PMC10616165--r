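expand_2x2 <- function(a, b, c, d) {
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  list(x = matrix(x, dimnames = list(NULL, "exposed")), y = y)
}

test_that("intercept-only fit recovers the log-odds of the event rate", {
  y <- c(rep(1, 300), rep(0, 700))
  fit <- fit_logistic(matrix(numeric(0), nrow = 1000, ncol = 0), y)
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), log(0.3 / 0.7),
               tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("single-covariate fits reproduce the closed-form 2x2 odds ratio", {
  set.seed(31)
  tables <- c(list(c(35, 283, 22, 478)),
              replicate(10, rpois(4, 60) + 1, simplify = FALSE))
  for (cells in tables) {
    dd <- expand_2x2(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_logistic(dd$x, dd$y)
    td <- tidy(fit)[2, ]
    closed <- odds_ratio(cells[1], cells[2], cells[3], cells[4])
    expect_equal(td$or, closed$or, tolerance = 1e-6)
    expect_equal(td$or_low, closed$ci_low, tolerance = 1e-6)
    expect_equal(td$or_high, closed$ci_high, tolerance = 1e-6)
    expect_equal(td$p_value, closed$p_value, tolerance = 1e-6)
  }
})

test_that("IRLS agrees with the reference glm fitter on a random design", {
  set.seed(12)
  n <- 600
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4), x3 = runif(n))
  eta <- -0.5 + 0.8 * X[, 1] - 1.1 * X[, 2] + 0.3 * X[, 3]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(X, y)
  ref <- glm(y ~ X, family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("a pure-noise covariate earns a near-zero coefficient", {
  set.seed(77)
  n <- 10000
  x <- matrix(rnorm(n), dimnames = list(NULL, "noise"))
  y <- rbinom(n, 1, 0.3)
  fit <- fit_logistic(x, y)
  expect_lt(abs(fit$coefficients[["noise"]]), 0.1)
  expect_gt(tidy(fit)$p_value[2], 0.001)
})

test_that("perfect separation is detected and reported as an error or flag", {
  x <- matrix(c(rep(0, 20), rep(1, 20)), dimnames = list(NULL, "x"))
  y <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logistic(x, y), class = "nb_separation_error")
  fit <- fit_logistic(x, y, on_separation = "flag")
  expect_true(fit$separation)
})

test_that("rows with missing covariates are dropped and counted", {
  set.seed(9)
  x <- matrix(rnorm(100), dimnames = list(NULL, "x"))
  x[1:7] <- NA
  y <- rbinom(100, 1, 0.5)
  fit <- fit_logistic(x, y)
  expect_identical(fit$n_used, 93L)
  expect_identical(fit$n_dropped, 7L)
})

test_that("an intercept shift leaves covariate odds ratios unchanged", {
  set.seed(55)
  n <- 30000
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  eta <- -1 + 0.6 * X[, 1] + 0.9 * X[, 2]
  u <- runif(n)
  f1 <- fit_logistic(X, as.numeric(u < plogis(eta)))
  f2 <- fit_logistic(X, as.numeric(u < plogis(eta + 1)))
  expect_equal(f1$coefficients[["x1"]], f2$coefficients[["x1"]],
               tolerance = 0.12)
  expect_equal(f1$coefficients[["x2"]], f2$coefficients[["x2"]],
               tolerance = 0.12)
  expect_gt(f2$coefficients[["(Intercept)"]],
            f1$coefficients[["(Intercept)"]] + 0.5)
})

test_that("rank-based AUC equals brute-force pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(2, 3, 10, 20), c(0, 0, 1, 1)), 1)
  set.seed(13)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    s <- sample(round(runif(n), 2)) # ties on purpose
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    pos <- s[y == 1]; neg <- s[y == 0]
    brute <- mean(outer(pos, neg, function(p, q)
      (p > q) + 0.5 * (p == q)))
    expect_equal(roc_auc(s, y), brute, tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), class = "nb_domain_error")
})

test_that("the model suite reports complete-case bookkeeping per model", {
  spec <- cohort_spec(n_patients = 900, seed = 21, missing_saps3 = 0,
                      missing_sofa = 0, missing_mrs = 0)
  cohort <- generate_cohort(spec)
  suite <- run_model_suite(cohort, models = "model3_saps3",
                           outcomes = "mortality")
  expect_true(all(suite$n_used == 900))

  cohort$saps3[1:35] <- NA_integer_
  suite2 <- run_model_suite(cohort, models = "model3_saps3",
                            outcomes = "mortality")
  expect_true(all(suite2$n_used == 865))
  expect_true(all(suite2$n_dropped == 35))

  expect_error(run_model_suite(cohort, models = "model9"),
               class = "nb_config_error")
})

test_that("configured monotone Hs effects come out monotone in model 1", {
  cohort <- generate_cohort(cohort_spec(n_patients = 8000, seed = 33))
  suite <- run_model_suite(cohort, models = "model1_gcs_hs",
                           outcomes = "mortality")
  ors <- setNames(suite$or, suite$term)
  expect_gt(ors[["hs_three_plus"]], ors[["hs_two"]])
  expect_gt(ors[["hs_two"]], ors[["hs_one"]])
  expect_gt(ors[["hs_one"]], 1)
  expect_true(all(suite$converged))
})
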