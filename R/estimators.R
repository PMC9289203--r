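new_mr_estimate <- function(method, n_snps, theta, se,
                            variance_model = "fixed") {
  stopifnot(is.finite(theta), is.finite(se), se > 0)
  ci_low <- theta - Z95 * se
  ci_high <- theta + Z95 * se
  structure(list(
    method = method,
    n_snps = as.integer(n_snps),
    theta = theta,
    se = se,
    ci_low = ci_low,
    ci_high = ci_high,
    pvalue = 2 * pnorm(-abs(theta / se)),
    odds_ratio = exp(theta),
    or_ci_low = exp(ci_low),
    or_ci_high = exp(ci_high),
    variance_model = variance_model
  ), class = "mr_estimate")
}

check_harmonized <- function(data, min_snps, what) {
  data <- as_tibble(data)
  needed <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0(what, ": input lacks column(s) ",
                 paste(missing, collapse = ", ")),
          class = "cecmr_usage_error")
  }
  if (nrow(data) < min_snps) {
    abort(paste0(what, " requires at least ", min_snps,
                 " instrument(s), got ", nrow(data)),
          class = c("cecmr_insufficient_instruments", "cecmr_usage_error"))
  }
  if (any(data$se_exposure <= 0) || any(data$se_outcome <= 0)) {
    abort(paste0(what, ": standard errors must be positive"),
          class = "cecmr_validation_error")
  }
  if (any(data$beta_exposure == 0)) {
    abort(paste0(what, ": degenerate instrument with zero exposure effect"),
          class = "cecmr_degenerate_instrument")
  }
  if (!"snp" %in% names(data)) data$snp <- paste0("snp_", seq_len(nrow(data)))
  data
}

#' Per-SNP Wald ratio estimates
#'
#' The building block of every summary-data MR estimator: for each SNP,
#' the causal effect implied by that SNP alone is the SNP-outcome estimate
#' divided by the SNP-exposure estimate, with a first-order delta-method
#' standard error `se_outcome / |beta_exposure|` (exposure-side
#' uncertainty ignored — the "no measurement error" simplification).
#'
#' @param data Harmonized-instrument tibble (see [harmonize()]).
#' @return Tibble with columns `snp`, `theta`, `se_theta` and
#'   `weight = 1/se_theta^2`.
#' @export
ratio_estimates <- function(data) {
  data <- check_harmonized(data, 1, "ratio_estimates")
  se_theta <- data$se_outcome / abs(data$beta_exposure)
  tibble(
    snp = data$snp,
    theta = data$beta_outcome / data$beta_exposure,
    se_theta = se_theta,
    weight = 1 / se_theta^2
  )
}

#' Wald ratio estimator (single instrument)
#'
#' Causal log-odds per SD exposure from one SNP: the ratio of the
#' SNP-outcome to the SNP-exposure association, delta-method SE, normal
#' 95% CI and two-sided p.
#'
#' @param data One-row harmonized-instrument tibble.
#' @return An object of class `mr_estimate`; see [tidy.mr_estimate()].
#' @export
#' @examples
#' mr_wald_ratio(fixture_instrument("CAD", instrument = "1snp"))
mr_wald_ratio <- function(data) {
  data <- check_harmonized(data, 1, "mr_wald_ratio")
  if (nrow(data) != 1) {
    abort("mr_wald_ratio takes exactly one instrument; use mr_ivw for several",
          class = "cecmr_usage_error")
  }
  r <- ratio_estimates(data)
  new_mr_estimate("wald", 1L, r$theta, r$se_theta)
}

#' Inverse-variance weighted (IVW) estimator
#'
#' Pools per-SNP ratio estimates with weights
#' `beta_exposure^2 / se_outcome^2` — algebraically identical to the
#' weighted through-origin regression of outcome betas on exposure betas
#' with weights `1/se_outcome^2`. With `variance_model = "fixed"` the SE
#' is `(sum of weights)^{-1/2}`; with `"multiplicative"` it is inflated
#' by `max(1, sqrt(Q/(k-1)))` where `Q` is the instrument Cochran Q, so
#' under-dispersion never shrinks the interval.
#'
#' @param data Harmonized-instrument tibble, at least one row.
#' @param variance_model `"fixed"` (default) or `"multiplicative"`.
#' @return An object of class `mr_estimate`.
#' @export
#' @examples
#' mr_ivw(fixture_instrument("CAD"))
mr_ivw <- function(data, variance_model = c("fixed", "multiplicative")) {
  variance_model <- match.arg(variance_model)
  data <- check_harmonized(data, 1, "mr_ivw")
  w <- data$beta_exposure^2 / data$se_outcome^2
  theta <- sum(data$beta_exposure * data$beta_outcome / data$se_outcome^2) /
    sum(w)
  se <- 1 / sqrt(sum(w))
  k <- nrow(data)
  if (variance_model == "multiplicative") {
    if (k < 2) {
      abort("multiplicative variance model needs at least 2 instruments",
            class = "cecmr_usage_error")
    }
    ratios <- data$beta_outcome / data$beta_exposure
    q <- sum(w * (ratios - theta)^2)
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  new_mr_estimate("ivw", k, theta, se, variance_model = variance_model)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept, weights `1/se_outcome^2`, after orienting every instrument
#' so the exposure beta is non-negative. The slope is the
#' pleiotropy-adjusted causal estimate (valid under the InSIDE
#' assumption); the intercept estimates average directional pleiotropy
#' and is the pleiotropy test. Standard errors use residual scaling
#' `sqrt(RSS_w/(k-2))` with no lower truncation at 1.
#'
#' @param data Harmonized-instrument tibble with at least 3 rows.
#' @return An object of class `mr_egger`: `$slope` is an `mr_estimate`,
#'   `$intercept` holds estimate, se, CI and p of the intercept.
#' @export
#' @examples
#' mr_egger(fixture_instrument("CAD"))
mr_egger <- function(data) {
  data <- check_harmonized(data, 3, "mr_egger")
  flip <- sign(data$beta_exposure)
  bx <- data$beta_exposure * flip
  by <- data$beta_outcome * flip
  w <- 1 / data$se_outcome^2
  k <- length(bx)
  X <- cbind(intercept = 1, slope = bx)
  fit <- stats::lm.wfit(X, by, w)
  rss_w <- sum(w * fit$residuals^2)
  sigma2 <- rss_w / (k - 2)
  xtx_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  ses <- sqrt(diag(xtx_inv) * sigma2)
  slope <- new_mr_estimate("egger_slope", k, fit$coefficients[["slope"]],
                           ses[2])
  b0 <- fit$coefficients[["intercept"]]
  intercept <- list(
    estimate = b0,
    se = ses[1],
    ci_low = b0 - Z95 * ses[1],
    ci_high = b0 + Z95 * ses[1],
    pvalue = 2 * pnorm(-abs(b0 / ses[1]))
  )
  structure(list(slope = slope, intercept = intercept, n_snps = k),
            class = "mr_egger")
}

# Weighted median of ratio estimates: order the ratios, form cumulative
# standardized weights p_j = (cumsum(w) - w_j/2)/sum(w), interpolate
# linearly at p = 0.5; clamped to the extreme ratio when 0.5 falls
# outside [p_1, p_k]. Ties broken by a stable sort on snp id.
weighted_median_point <- function(theta, w, snp = NULL) {
  ord <- if (is.null(snp)) order(theta) else order(theta, snp)
  theta <- theta[ord]
  w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(p)])
  approx(p, theta, xout = 0.5, ties = "ordered")$y
}

median_boot_se <- function(data, weighting, n_boot, seed) {
  run <- function() {
    reps <- vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(nrow(data), data$beta_exposure, data$se_exposure)
      by <- rnorm(nrow(data), data$beta_outcome, data$se_outcome)
      th <- by / bx
      w <- if (weighting == "weighted") bx^2 / data$se_outcome^2
           else rep(1, length(th))
      weighted_median_point(th, w, data$snp)
    }, numeric(1))
    stats::sd(reps)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Median-based estimators
#'
#' Median of the empirical distribution of per-SNP ratio estimates:
#' consistent when under half of the (weight in the) instruments are
#' invalid. The simple median uses equal weights `1/k`; the weighted
#' median uses the inverse-variance weights of the ratio estimates,
#' `beta_exposure^2 / se_outcome^2`. Both interpolate the weighted
#' empirical CDF at probability 0.5. The SE is a parametric bootstrap:
#' exposure and outcome betas are resampled from normal(beta, se),
#' the median recomputed, and the SD over replicates taken.
#'
#' @param data Harmonized-instrument tibble with at least 3 rows.
#' @param weighting `"weighted"` or `"simple"`.
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Optional integer seed making the bootstrap reproducible;
#'   the caller's RNG state is untouched.
#' @return An object of class `mr_estimate`.
#' @export
#' @examples
#' mr_weighted_median(fixture_instrument("CAD"), seed = 1)
mr_median <- function(data, weighting = c("weighted", "simple"),
                      n_boot = 1000, seed = NULL) {
  weighting <- match.arg(weighting)
  data <- check_harmonized(data, 3, paste0(weighting, " median"))
  r <- ratio_estimates(data)
  w <- if (weighting == "weighted") r$weight else rep(1, nrow(r))
  theta <- weighted_median_point(r$theta, w, r$snp)
  se <- median_boot_se(data, weighting, n_boot, seed)
  method <- if (weighting == "weighted") "weighted_median" else "simple_median"
  new_mr_estimate(method, nrow(data), theta, se)
}

#' @rdname mr_median
#' @export
mr_simple_median <- function(data, n_boot = 1000, seed = NULL) {
  mr_median(data, "simple", n_boot = n_boot, seed = seed)
}

#' @rdname mr_median
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL) {
  mr_median(data, "weighted", n_boot = n_boot, seed = seed)
}

#' Multivariable IVW estimator
#'
#' Weighted least squares of outcome betas on several exposures' betas
#' jointly, without intercept, weights `1/se_outcome^2`. Each slope is
#' the direct causal effect of its exposure conditional on the others.
#' With one exposure this reduces exactly to the fixed-effect [mr_ivw()].
#'
#' @param data Tibble with one row per SNP: the exposure beta columns
#'   named in `exposures`, plus `beta_outcome` and `se_outcome`.
#' @param exposures Character vector naming the exposure beta columns.
#' @return Tibble with one row per exposure: `exposure`, `n_snps`,
#'   `estimate`, `std.error`, `conf.low`, `conf.high`, `p.value`,
#'   `odds_ratio`.
#' @export
mr_mv_ivw <- function(data, exposures) {
  data <- as_tibble(data)
  missing <- setdiff(c(exposures, "beta_outcome", "se_outcome"), names(data))
  if (length(missing) > 0) {
    abort(paste0("mr_mv_ivw: input lacks column(s) ",
                 paste(missing, collapse = ", ")),
          class = "cecmr_usage_error")
  }
  k <- nrow(data)
  E <- length(exposures)
  if (k < E + 1) {
    abort(paste0("mr_mv_ivw needs at least ", E + 1, " instruments for ",
                 E, " exposures, got ", k),
          class = "cecmr_insufficient_instruments")
  }
  X <- as.matrix(data[, exposures, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < E) {
    dep <- exposures[-qrX$pivot[seq_len(qrX$rank)]]
    abort(paste0("mr_mv_ivw: exposure design is rank deficient; ",
                 "dependent column(s): ", paste(dep, collapse = ", ")),
          class = "cecmr_collinearity_error")
  }
  w <- 1 / data$se_outcome^2
  fit <- stats::lm.wfit(X, data$beta_outcome, w)
  xtx_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  ses <- sqrt(diag(xtx_inv))
  est <- fit$coefficients
  tibble(
    exposure = exposures,
    n_snps = k,
    estimate = unname(est),
    std.error = ses,
    conf.low = unname(est) - Z95 * ses,
    conf.high = unname(est) + Z95 * ses,
    p.value = 2 * pnorm(-abs(unname(est) / ses)),
    odds_ratio = exp(unname(est))
  )
}
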