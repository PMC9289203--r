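#' Exposure variance explained by a variant
#'
#' For a per-allele effect `beta` in SD units of the exposure and an
#' effect-allele frequency, the variance explained is
#' `2 * beta^2 * m * (1 - m)` with `m` the minor-allele frequency
#' `min(eaf, 1 - eaf)`. Vectorized.
#'
#' @param beta Per-allele effect(s) in SD units.
#' @param eaf Effect-allele frequency(ies) in (0, 1).
#' @return Fraction(s) of exposure variance explained.
#' @export
#' @examples
#' variance_explained(0.2833, 0.058)  # ~0.0088, i.e. 0.9%
variance_explained <- function(beta, eaf) {
  if (any(!is.finite(eaf) | eaf <= 0 | eaf >= 1)) {
    abort("variance_explained: eaf must lie in (0, 1)",
          class = "cecmr_validation_error")
  }
  m <- pmin(eaf, 1 - eaf)
  2 * beta^2 * m * (1 - m)
}

#' Instrument F statistic
#'
#' Strength of a k-variant instrument explaining a fraction `r2` of the
#' exposure variance in a sample of size `n`:
#' `(r2/k) / ((1 - r2)/(n - k - 1))`. Values below ~10 indicate a weak
#' instrument whose two-sample MR estimates are biased toward the null.
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n Exposure-GWAS sample size, must exceed `k + 1`.
#' @param k Number of variants in the instrument.
#' @return The F statistic.
#' @export
#' @examples
#' f_statistic(0.053, 5293, 5)
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0 | r2 >= 1)) {
    abort("f_statistic: r2 must lie in [0, 1)", class = "cecmr_validation_error")
  }
  if (any(n <= k + 1)) {
    abort("f_statistic: n must exceed k + 1", class = "cecmr_validation_error")
  }
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Strength summary of a harmonized instrument
#'
#' Per-SNP and total variance explained plus the instrument F statistic,
#' computed from the exposure-side columns of a harmonized table.
#'
#' @param data Harmonized-instrument tibble with a non-missing `eaf`.
#' @param n Exposure-GWAS sample size.
#' @return A list with `per_snp_r2` (tibble `snp`, `r2`), `total_r2`,
#'   `f_statistic`, `n` and `k`.
#' @export
#' @examples
#' instrument_strength(fixture_instrument("CAD"), n = 5293)
instrument_strength <- function(data, n) {
  data <- check_harmonized(data, 1, "instrument_strength")
  if (!"eaf" %in% names(data) || any(is.na(data$eaf))) {
    abort("instrument_strength needs non-missing eaf",
          class = "cecmr_validation_error")
  }
  r2 <- variance_explained(data$beta_exposure, data$eaf)
  total <- sum(r2)
  list(
    per_snp_r2 = tibble(snp = data$snp, r2 = r2),
    total_r2 = total,
    f_statistic = f_statistic(total, n, nrow(data)),
    n = n,
    k = nrow(data)
  )
}

#' Power of a two-sample MR analysis with a binary outcome
#'
#' Normal-approximation power to detect an odds ratio `or_alt` per SD of
#' exposure with an instrument explaining `r2` of the exposure variance,
#' in an outcome GWAS of `n_total` subjects with case fraction
#' `case_fraction`:
#' `Phi( sqrt(n * r2 * p * (1-p)) * |ln(or_alt)| - z_{1-alpha/2} )`.
#' At `or_alt = 1` this evaluates to `alpha/2` (the one-sided rejection
#' mass under the null), the documented limit rather than an error.
#' Vectorized over all arguments.
#'
#' @param n_total Outcome-GWAS sample size.
#' @param case_fraction Fraction of cases, in (0, 1).
#' @param r2 Exposure variance explained by the instrument, in (0, 1).
#' @param or_alt Alternative-hypothesis odds ratio per SD exposure.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power as a fraction.
#' @export
#' @examples
#' mr_power(411497, 5386 / 411497, r2 = 0.053, or_alt = 0.90)  # ~0.42
mr_power <- function(n_total, case_fraction, r2, or_alt, alpha = 0.05) {
  if (any(n_total <= 0)) {
    abort("mr_power: n_total must be positive", class = "cecmr_validation_error")
  }
  if (any(case_fraction <= 0 | case_fraction >= 1)) {
    abort("mr_power: case_fraction must lie in (0, 1)",
          class = "cecmr_validation_error")
  }
  if (any(r2 <= 0 | r2 >= 1)) {
    abort("mr_power: r2 must lie in (0, 1)", class = "cecmr_validation_error")
  }
  if (any(alpha <= 0 | alpha >= 1)) {
    abort("mr_power: alpha must lie in (0, 1)", class = "cecmr_validation_error")
  }
  ncp <- sqrt(n_total * r2 * case_fraction * (1 - case_fraction)) *
    abs(log(or_alt))
  pnorm(ncp - qnorm(1 - alpha / 2))
}
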