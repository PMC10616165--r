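# Binary logistic regression by IRLS (Newton-Raphson on the Bernoulli
# log-likelihood) with Wald inference, plus the rank-based ROC AUC and the
# four prognostic model specifications.

#' Fit a binary logistic regression by IRLS
#'
#' Newton-Raphson on the Bernoulli log-likelihood, iterated to a relative
#' log-likelihood change below `tol`. Standard errors come from the inverse
#' observed information at the optimum; odds ratios are
#' `exp(coefficients)` with Wald confidence intervals. Coefficients start at
#' zero. Perfect separation is declared when any coefficient exceeds 30 in
#' absolute value (an odds ratio beyond e^30, beyond anything estimable from
#' cohort data).
#'
#' @param x Numeric design matrix with named columns (no intercept column;
#'   one is added as `(Intercept)`), or a data frame of numeric columns.
#' @param y Binary outcome vector (0/1 or logical), same length as
#'   `nrow(x)`.
#' @param tol Convergence tolerance on the relative change in
#'   log-likelihood (default 1e-10).
#' @param max_iter Maximum Newton iterations (default 100).
#' @param conf_level Confidence level for the Wald intervals.
#' @param on_separation `"error"` (default) to raise a separation error,
#'   `"flag"` to return the diverged fit with `separation = TRUE`.
#' @return An object of class `nb_logit`: coefficients, covariance,
#'   log-likelihood, fitted probabilities, ROC AUC, `n_used`, convergence
#'   flags. Use [tidy()] for the per-term table and [glance()] for the
#'   model-level summary.
#' @export
fit_logistic <- function(x, y, tol = 1e-10, max_iter = 100,
                         conf_level = 0.95,
                         on_separation = c("error", "flag")) {
  on_separation <- arg_match(on_separation)
  x <- as.matrix(x)
  if (ncol(x) > 0 && is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  y <- as.numeric(y)
  if (length(y) != nrow(x)) {
    abort("`y` must have one element per row of `x`",
          class = c("nb_domain_error", "nb_error"))
  }
  keep <- complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  if (!all(y %in% c(0, 1))) {
    abort("`y` must be binary (0/1)", class = c("nb_domain_error", "nb_error"))
  }
  if (length(unique(y)) < 2) {
    abort("outcome is constant; logistic model is not identifiable",
          class = c("nb_domain_error", "nb_error"))
  }
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  beta <- rep(0, p)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    # log(1 + e^eta) written to avoid overflow at large |eta|
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  ll <- loglik(beta)
  converged <- FALSE
  separation <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * sqrt(w))
    step <- tryCatch(solve(info, score), error = function(e) {
      abort("singular information matrix; check for collinear covariates",
            class = c("nb_domain_error", "nb_error"))
    })
    beta_new <- beta + step
    ll_new <- loglik(beta_new)
    # dampen if the full Newton step overshoots
    half <- 0
    while (ll_new < ll && half < 20) {
      step <- step / 2
      beta_new <- beta + step
      ll_new <- loglik(beta_new)
      half <- half + 1
    }
    rel_change <- abs(ll_new - ll) / (abs(ll) + .Machine$double.eps)
    beta <- beta_new
    ll <- ll_new
    if (max(abs(beta)) > 30) {
      separation <- TRUE
      break
    }
    if (rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  if (separation && on_separation == "error") {
    abort("perfect separation detected: a coefficient diverged beyond |30|",
          class = c("nb_separation_error", "nb_error"))
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  vcov_beta <- solve(crossprod(X * sqrt(w)))
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  structure(
    list(
      coefficients = setNames(drop(beta), colnames(X)),
      vcov = vcov_beta,
      loglik = ll,
      fitted = mu,
      y = y,
      auc = roc_auc(mu, y),
      n_used = length(y),
      n_dropped = sum(!keep),
      iter = iter,
      converged = converged,
      separation = separation,
      conf_level = conf_level
    ),
    class = "nb_logit"
  )
}

#' @export
print.nb_logit <- function(x, ...) {
  cat(sprintf(
    "<nb_logit> n = %d (%d dropped), logLik = %.3f, AUC = %.3f, %s\n",
    x$n_used, x$n_dropped, x$loglik, x$auc,
    if (x$separation) "SEPARATION" else if (x$converged)
      sprintf("converged in %d iterations", x$iter) else "NOT converged"))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a fitted logistic model
#'
#' @param x An `nb_logit` object.
#' @param ... Unused.
#' @return One row per term: `term`, `estimate` (log-odds), `std_error`,
#'   `statistic` (Wald z), `p_value`, `or`, `or_low`, `or_high`.
#' @method tidy nb_logit
#' @export
tidy.nb_logit <- function(x, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - x$conf_level) / 2)
  tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(est / se),
    p_value = unname(2 * pnorm(-abs(est / se))),
    or = exp(unname(est)),
    or_low = exp(unname(est - z * se)),
    or_high = exp(unname(est + z * se))
  )
}

#' @rdname tidy.nb_logit
#' @method glance nb_logit
#' @export
glance.nb_logit <- function(x, ...) {
  tibble(n_used = x$n_used, n_dropped = x$n_dropped, loglik = x$loglik,
         auc = x$auc, iter = x$iter, converged = x$converged,
         separation = x$separation)
}

#' Rank-based ROC AUC
#'
#' Area under the receiver operating characteristic curve computed from the
#' Mann-Whitney statistic: the proportion of (positive, negative) pairs in
#' which the positive scores higher, ties counting one half.
#'
#' @param scores Numeric scores (e.g. predicted probabilities).
#' @param outcome Binary outcome (0/1 or logical); both classes must occur.
#' @return The AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
#' @export
roc_auc <- function(scores, outcome) {
  outcome <- as.numeric(outcome)
  keep <- !is.na(scores) & !is.na(outcome)
  scores <- scores[keep]
  outcome <- outcome[keep]
  if (!all(outcome %in% c(0, 1))) {
    abort("`outcome` must be binary", class = c("nb_domain_error", "nb_error"))
  }
  n_pos <- sum(outcome == 1)
  n_neg <- sum(outcome == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("both outcome classes must be present to compute an AUC",
          class = c("nb_domain_error", "nb_error"))
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[outcome == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' The four prognostic model specifications
#'
#' Covariate sets of the four multivariable models fitted to each outcome:
#' model 1 uses age, male sex, GCS, Hs category (vs zero), public insurance
#' (vs private) and emergency admission (vs elective); model 2 swaps the
#' clinical covariates for APACHE II; model 3 for SAPS III; model 4 uses
#' age and SOFA. Each model is fitted on its own complete cases.
#'
#' @return A named list mapping model name to its covariate labels.
#' @export
model_specs <- function() {
  list(
    model1_gcs_hs = c("age", "male", "gcs", "hs_one", "hs_two",
                      "hs_three_plus", "public", "emergency"),
    model2_apache = c("male", "apache2", "public", "emergency"),
    model3_saps3 = c("male", "saps3", "public", "emergency"),
    model4_sofa = c("age", "male", "sofa", "public", "emergency")
  )
}

# numeric design columns derived from the cohort schema
model_frame <- function(cohort) {
  cohort <- resolve_hs(cohort)
  tibble(
    age = as.numeric(cohort$age),
    male = as.numeric(cohort$sex == "male"),
    gcs = as.numeric(cohort$gcs),
    apache2 = as.numeric(cohort$apache2),
    saps3 = as.numeric(cohort$saps3),
    sofa = as.numeric(cohort$sofa),
    hs_one = as.numeric(cohort$hs_category == "one"),
    hs_two = as.numeric(cohort$hs_category == "two"),
    hs_three_plus = as.numeric(cohort$hs_category == "three_plus"),
    public = as.numeric(cohort$insurance == "public"),
    emergency = as.numeric(cohort$admission_type == "emergency")
  )
}

#' Fit the prognostic model suite
#'
#' Fits each requested model specification to each requested outcome
#' (30-day ICU mortality; unfavourable outcome, mRS 4-6) by complete-case
#' IRLS logistic regression, reporting per-model `n_used` and dropped-row
#' counts, convergence, ROC AUC of the fitted probabilities, and the tidy
#' per-term odds-ratio table.
#'
#' @param cohort A validated cohort tibble.
#' @param models Character vector of model names from [model_specs()]
#'   (default: all four).
#' @param outcomes Which outcomes to fit: `"mortality"`,
#'   `"unfavourable"` or both (default).
#' @param ... Passed on to [fit_logistic()].
#' @return A tidy tibble with one row per model term: columns `model`,
#'   `outcome`, `n_used`, `n_dropped`, `converged`, `auc`, then the
#'   [tidy.nb_logit()] columns.
#' @export
run_model_suite <- function(cohort,
                            models = names(model_specs()),
                            outcomes = c("mortality", "unfavourable"),
                            ...) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  specs <- model_specs()
  bad <- setdiff(models, names(specs))
  if (length(bad) > 0) {
    abort(paste0("unknown model(s): ", paste(bad, collapse = ", ")),
          class = c("nb_config_error", "nb_error"))
  }
  cohort <- code_outcomes(resolve_hs(as_tibble(cohort)))
  frame <- model_frame(cohort)
  map_dfr(models, function(m) {
    covs <- specs[[m]]
    map_dfr(outcomes, function(o) {
      y <- if (o == "mortality") as.numeric(cohort$death) else
        as.numeric(cohort$unfavourable)
      fit <- fit_logistic(frame[, covs, drop = FALSE], y,
                          on_separation = "flag", ...)
      mutate(tidy(fit), model = m, outcome = o, n_used = fit$n_used,
             n_dropped = fit$n_dropped, converged = fit$converged,
             separation = fit$separation, auc = fit$auc,
             .before = 1)
    })
  })
}
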