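# Univariate 2x2 machinery: Wald odds ratios, chi-square homogeneity,
# percentage formatting at the report precision.

#' Odds ratio with Wald confidence interval from a 2x2 table
#'
#' Computes the cross-product odds ratio
#' \eqn{OR = (a d) / (b c)} for a 2x2 exposure-by-event table, its Wald
#' confidence interval \eqn{\exp(\log OR \pm z_{1-\alpha/2} \, SE)} with
#' \eqn{SE = \sqrt{1/a + 1/b + 1/c + 1/d}}, and the Wald test p-value of
#' \eqn{\log OR / SE} against the standard normal.
#'
#' @param exposed_events,exposed_nonevents Event and non-event counts in the
#'   exposed (index) group.
#' @param ref_events,ref_nonevents Event and non-event counts in the
#'   reference group.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @param zero_cell What to do when a cell is zero: `"error"` (default;
#'   degenerate-table error naming the cell) or `"haldane"` (add 0.5 to all
#'   four cells).
#' @return A one-row tibble with columns `or`, `ci_low`, `ci_high`,
#'   `p_value`, `zero_cell_corrected`.
#' @examples
#' odds_ratio(35, 283, 22, 478) # one secondary injury vs none, ICU death
#' @export
odds_ratio <- function(exposed_events, exposed_nonevents,
                       ref_events, ref_nonevents,
                       conf_level = 0.95,
                       zero_cell = c("error", "haldane")) {
  zero_cell <- arg_match(zero_cell)
  cells <- c(exposed_events = exposed_events,
             exposed_nonevents = exposed_nonevents,
             ref_events = ref_events, ref_nonevents = ref_nonevents)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("2x2 cells must be non-negative integers",
          class = c("nb_domain_error", "nb_error"))
  }
  if (sum(cells) == 0) {
    abort("2x2 table is empty", class = c("nb_domain_error", "nb_error"))
  }
  corrected <- FALSE
  if (any(cells == 0)) {
    if (zero_cell == "error") {
      abort(paste0("degenerate 2x2 table: zero cell(s) ",
                   paste(names(cells)[cells == 0], collapse = ", "),
                   "; use zero_cell = \"haldane\" to correct"),
            class = c("nb_degenerate_error", "nb_error"))
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  log_or <- log(cells[[1]]) - log(cells[[2]]) - log(cells[[3]]) +
    log(cells[[4]])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    or = exp(log_or),
    ci_low = exp(log_or - z * se),
    ci_high = exp(log_or + z * se),
    p_value = 2 * pnorm(-abs(log_or / se)),
    zero_cell_corrected = corrected
  )
}

#' Percentage at report precision
#'
#' @param numerator,denominator Non-negative counts with
#'   `0 <= numerator <= denominator` and `denominator > 0`.
#' @return `100 * numerator / denominator`, rounded to 1 decimal (the
#'   precision used throughout the descriptive tables).
#' @examples
#' proportion(1194, 4245)
#' @export
proportion <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    abort("`denominator` must be positive",
          class = c("nb_domain_error", "nb_error"))
  }
  if (any(numerator < 0 | numerator > denominator)) {
    abort("`numerator` must lie in [0, denominator]",
          class = c("nb_domain_error", "nb_error"))
  }
  round(100 * numerator / denominator, 1)
}

#' Pearson chi-square test of homogeneity with optional pairwise follow-up
#'
#' Tests whether the rows of an r x c count table share one column
#' distribution (Pearson statistic, no continuity correction). With
#' `pairwise = TRUE`, every pair of rows is compared by the same test on the
#' 2 x c subtable formed from those two rows, with Bonferroni adjustment
#' over the \eqn{\binom{r}{2}} pairs.
#'
#' @param tab A numeric matrix of non-negative counts, at least 2 x 2, with
#'   positive row and column margins.
#' @param pairwise Run all pairwise row comparisons (default `FALSE`).
#' @return A one-row tibble with `statistic`, `df`, `p_value`; when
#'   `pairwise = TRUE` it carries the pair table in the `pairwise`
#'   attribute (columns `row_a`, `row_b`, `statistic`, `p_value`,
#'   `p_bonferroni`).
#' @export
chi_square_homogeneity <- function(tab, pairwise = FALSE) {
  tab <- as.matrix(tab)
  if (any(is.na(tab)) || any(tab < 0)) {
    abort("counts must be non-negative", class = c("nb_domain_error", "nb_error"))
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("table must be at least 2x2", class = c("nb_domain_error", "nb_error"))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate table: a zero row or column margin",
          class = c("nb_degenerate_error", "nb_error"))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  out <- tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                p_value = unname(ct$p.value))
  if (pairwise) {
    pairs <- utils::combn(nrow(tab), 2)
    n_pairs <- ncol(pairs)
    pw <- map_dfr(seq_len(n_pairs), function(k) {
      sub <- tab[pairs[, k], , drop = FALSE]
      sub <- sub[, colSums(sub) > 0, drop = FALSE]
      ctk <- suppressWarnings(chisq.test(sub, correct = FALSE))
      tibble(row_a = pairs[1, k], row_b = pairs[2, k],
             statistic = unname(ctk$statistic),
             p_value = unname(ctk$p.value),
             p_bonferroni = pmin(1, unname(ctk$p.value) * n_pairs))
    })
    attr(out, "pairwise") <- pw
  }
  out
}
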