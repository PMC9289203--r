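#' Scatter plot of a harmonized instrument with fitted MR lines
#'
#' SNP-outcome betas against SNP-exposure betas (instruments oriented so
#' the exposure beta is positive), with the fixed-effect IVW
#' through-origin line and, when at least three instruments are present,
#' the MR-Egger line with its intercept.
#'
#' @param data Harmonized-instrument tibble.
#' @return A ggplot object.
#' @export
plot_instruments <- function(data) {
  data <- check_harmonized(data, 1, "plot_instruments")
  flip <- sign(data$beta_exposure)
  df <- tibble(
    snp = data$snp,
    bx = data$beta_exposure * flip,
    by = data$beta_outcome * flip,
    se_y = data$se_outcome
  )
  ivw_fit <- mr_ivw(data)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - Z95 * .data$se_y,
                                        ymax = .data$by + Z95 * .data$se_y),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw_fit$theta,
                         colour = "#2166AC") +
    ggplot2::labs(x = "SNP effect on exposure (SD per allele)",
                  y = "SNP effect on outcome (log-odds per allele)")
  if (nrow(df) >= 3) {
    eg <- mr_egger(data)
    p <- p + ggplot2::geom_abline(intercept = eg$intercept$estimate,
                                  slope = eg$slope$theta,
                                  colour = "#B2182B", linetype = "dashed")
  }
  p
}

#' Forest plot of an MR report
#'
#' Odds ratios with 95% CIs per outcome and method, on a log scale with a
#' reference line at OR = 1. Egger intercept rows are omitted (they are
#' not odds ratios).
#'
#' @param report An `mr_report` from [mr_run_analysis()].
#' @return A ggplot object.
#' @export
plot_forest <- function(report) {
  stopifnot(inherits(report, "mr_report"))
  est <- dplyr::filter(report$estimates, .data$term != "egger_intercept")
  ggplot2::ggplot(est, ggplot2::aes(x = .data$odds_ratio,
                                    y = .data$outcome,
                                    colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$or_conf_low,
                                          xmax = .data$or_conf_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR (95% CI) per 1-SD higher exposure", y = NULL,
                  colour = "method")
}

#' @method autoplot mr_report
#' @export
autoplot.mr_report <- function(object, ...) plot_forest(object)

#' @method autoplot mr_estimate
#' @export
autoplot.mr_estimate <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$odds_ratio, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$or_conf_low,
                                          xmax = .data$or_conf_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR (95% CI) per 1-SD higher exposure", y = NULL)
}
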