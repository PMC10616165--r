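# ggplot2 displays for fitted models and burden results.

#' Forest plot of a fitted logistic model
#'
#' Odds ratios with Wald confidence intervals on a log scale, one row per
#' covariate (the intercept is omitted).
#'
#' @param object An `nb_logit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nb_logit
#' @export
autoplot.nb_logit <- function(object, ...) {
  td <- filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$or,
                                   y = stats::reorder(.data$term, .data$or))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$or_low,
                                          xmax = .data$or_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of DALY burden by stratum
#'
#' Years of life lost (YLL) and years lived with disability (YLD) stacked
#' per stratum, in the layout used for burden figures: by diagnosis, age
#' band, age band within sex, or Hs category.
#'
#' @param object An `nb_burden` object from [compute_dalys()].
#' @param stratum Which stratification to draw (see [tidy.nb_burden()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nb_burden
#' @export
autoplot.nb_burden <- function(object,
                               stratum = c("diagnosis", "age_band",
                                           "age_sex", "hs"), ...) {
  stratum <- arg_match(stratum)
  df <- tidy(object, stratum = stratum)
  key <- setdiff(names(df), c("yll", "yld", "daly", "sex"))[1]
  long <- tidyr::pivot_longer(df, c("yll", "yld"), names_to = "component",
                              values_to = "years")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data[[key]],
                                          y = .data$years,
                                          fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "years (DALY = YLL + YLD)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (stratum == "age_sex") p <- p + ggplot2::facet_wrap(~sex)
  p
}
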