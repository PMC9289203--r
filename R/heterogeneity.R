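new_heterogeneity <- function(Q, df, contributions) {
  structure(list(
    Q = Q,
    df = as.integer(df),
    pvalue = pchisq(Q, df, lower.tail = FALSE),
    i_squared = i_squared(Q, df),
    contributions = contributions
  ), class = "mr_heterogeneity")
}

#' Cochran Q heterogeneity across an instrument set
#'
#' Dispersion of the per-SNP ratio estimates about the fixed-effect IVW
#' estimate: `Q = sum w_i (theta_i - theta_ivw)^2` with
#' `w_i = beta_exposure^2 / se_outcome^2`, referred to a chi-square with
#' `k - 1` degrees of freedom. Large Q flags invalid instruments or
#' pleiotropy. Q is invariant to rescaling all exposure betas by a common
#' positive factor, so the exposure's unit does not matter.
#'
#' @param data Harmonized-instrument tibble with at least 2 rows.
#' @return An object of class `mr_heterogeneity` with fields `Q`, `df`,
#'   `pvalue`, `i_squared` and a `contributions` tibble (`label`,
#'   `contribution`) summing to Q.
#' @export
#' @examples
#' cochran_q(fixture_instrument("IS"))
cochran_q <- function(data) {
  data <- check_harmonized(data, 2, "cochran_q")
  r <- ratio_estimates(data)
  theta_ivw <- sum(r$weight * r$theta) / sum(r$weight)
  contr <- r$weight * (r$theta - theta_ivw)^2
  new_heterogeneity(sum(contr), nrow(r) - 1,
                    tibble(label = r$snp, contribution = contr))
}

#' I-squared heterogeneity index
#'
#' Fraction of the dispersion in excess of its chi-square expectation:
#' `max(0, (Q - df)/Q)`, and 0 when Q = 0. Stored as a fraction;
#' reports print it as an integer percentage.
#'
#' @param Q Cochran Q statistic (non-negative).
#' @param df Degrees of freedom (at least 1).
#' @return A fraction in `[0, 1)`.
#' @export
#' @examples
#' i_squared(15.137, 1)
i_squared <- function(Q, df) {
  stopifnot(Q >= 0, df >= 1)
  if (Q == 0) return(0)
  max(0, (Q - df) / Q)
}

#' Heterogeneity between causal estimates
#'
#' Tests whether causal estimates for different outcomes (or from
#' different methods) are mutually compatible: fixed-effect pooled mean
#' with weights `1/se^2`, then Cochran Q, p and I-squared across the
#' estimates. Used to compare the effect of the exposure on coronary
#' disease against its effect on stroke. Input SEs should be the
#' fixed-model SEs of the per-outcome estimates.
#'
#' @param estimates Tibble (or data frame) with columns `label`, `theta`
#'   (or `estimate`) and `se` (or `std.error`); at least 2 rows, all SEs
#'   positive.
#' @return An object of class `mr_heterogeneity`.
#' @export
#' @examples
#' cad <- tidy(mr_ivw(fixture_instrument("CAD")))
#' is_ <- tidy(mr_ivw(fixture_instrument("IS")))
#' compare_estimates(tibble::tibble(label = c("CAD", "IS"),
#'                                  theta = c(cad$estimate, is_$estimate),
#'                                  se = c(cad$std.error, is_$std.error)))
compare_estimates <- function(estimates) {
  estimates <- as_tibble(estimates)
  if (!"theta" %in% names(estimates) && "estimate" %in% names(estimates)) {
    estimates$theta <- estimates$estimate
  }
  if (!"se" %in% names(estimates) && "std.error" %in% names(estimates)) {
    estimates$se <- estimates$std.error
  }
  if (!all(c("label", "theta", "se") %in% names(estimates))) {
    abort("compare_estimates needs columns label, theta (estimate), se (std.error)",
          class = "cecmr_usage_error")
  }
  if (nrow(estimates) < 2) {
    abort("compare_estimates needs at least 2 estimates",
          class = "cecmr_usage_error")
  }
  if (any(!is.finite(estimates$se) | estimates$se <= 0)) {
    abort("compare_estimates: all standard errors must be positive",
          class = "cecmr_validation_error")
  }
  w <- 1 / estimates$se^2
  pooled <- sum(w * estimates$theta) / sum(w)
  contr <- w * (estimates$theta - pooled)^2
  new_heterogeneity(sum(contr), nrow(estimates) - 1,
                    tibble(label = estimates$label, contribution = contr))
}

#' @method tidy mr_heterogeneity
#' @export
tidy.mr_heterogeneity <- function(x, ...) x$contributions

#' @method glance mr_heterogeneity
#' @export
glance.mr_heterogeneity <- function(x, ...) {
  tibble(Q = x$Q, df = x$df, p.value = x$pvalue, i_squared = x$i_squared)
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran Q = %.1f on %d df, p = %s, I2 = %d%%\n",
              x$Q, x$df, format_p(x$pvalue), round(100 * x$i_squared)))
  invisible(x)
}
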