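#' Tidy an MR estimate
#'
#' One row per estimate in broom convention, with the odds-ratio scale
#' (per 1-SD genetically higher exposure) alongside the log-odds scale.
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_snps`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`, `odds_ratio`, `or_conf_low`,
#'   `or_conf_high`, `variance_model`.
#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble(
    method = x$method,
    n_snps = x$n_snps,
    estimate = x$theta,
    std.error = x$se,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    p.value = x$pvalue,
    odds_ratio = x$odds_ratio,
    or_conf_low = x$or_ci_low,
    or_conf_high = x$or_ci_high,
    variance_model = x$variance_model
  )
}

#' @method glance mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) tidy(x, ...)

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate (%s, %d SNP%s, %s variance)\n", x$method,
              x$n_snps, if (x$n_snps == 1) "" else "s", x$variance_model))
  cat(sprintf("  log-odds per SD: %.4f (SE %.4f)\n", x$theta, x$se))
  cat(sprintf("  OR %.2f (95%% CI %.2f-%.2f), p = %s\n", x$odds_ratio,
              x$or_ci_low, x$or_ci_high, format_p(x$pvalue)))
  invisible(x)
}

#' Tidy an MR-Egger fit
#'
#' Two rows, `term = "slope"` and `term = "intercept"`, in broom
#' convention. The slope row carries the odds-ratio scale; the intercept
#' (average directional pleiotropy, log-odds per allele) does not.
#'
#' @param x An `mr_egger` object.
#' @param ... Unused.
#' @return A two-row tibble.
#' @method tidy mr_egger
#' @export
tidy.mr_egger <- function(x, ...) {
  s <- x$slope
  i <- x$intercept
  tibble(
    term = c("slope", "intercept"),
    n_snps = x$n_snps,
    estimate = c(s$theta, i$estimate),
    std.error = c(s$se, i$se),
    conf.low = c(s$ci_low, i$ci_low),
    conf.high = c(s$ci_high, i$ci_high),
    p.value = c(s$pvalue, i$pvalue),
    odds_ratio = c(s$odds_ratio, NA_real_),
    or_conf_low = c(s$or_ci_low, NA_real_),
    or_conf_high = c(s$or_ci_high, NA_real_)
  )
}

#' @method glance mr_egger
#' @export
glance.mr_egger <- function(x, ...) {
  dplyr::bind_cols(method = "egger", tidy(x$slope)[-1],
                   intercept = x$intercept$estimate,
                   intercept_p = x$intercept$pvalue)
}

#' @export
print.mr_egger <- function(x, ...) {
  cat(sprintf("MR-Egger regression (%d SNPs)\n", x$n_snps))
  cat(sprintf("  slope: OR %.2f (95%% CI %.2f-%.2f), p = %s\n",
              x$slope$odds_ratio, x$slope$or_ci_low, x$slope$or_ci_high,
              format_p(x$slope$pvalue)))
  cat(sprintf("  intercept: %.3f (95%% CI %.3f, %.3f), p = %s\n",
              x$intercept$estimate, x$intercept$ci_low, x$intercept$ci_high,
              format_p(x$intercept$pvalue)))
  invisible(x)
}

format_p <- function(p) {
  ifelse(p < 1e-300, "<1e-300",
         ifelse(p < 0.001, format(p, digits = 2, scientific = TRUE),
                sprintf("%.3g", p)))
}
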