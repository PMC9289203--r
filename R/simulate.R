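#' Configuration for the two-sample summary-statistic simulator
#'
#' Collects and validates the generative parameters of
#' [simulate_two_sample_summary()]. Defaults emulate the study design the
#' package is built around: a moderate exposure GWAS (~5,000 subjects), a
#' large case-control outcome GWAS, per-SNP exposure effects of a few
#' hundredths to a few tenths of an SD, and a protective causal effect.
#'
#' @param m_snps Number of independent SNPs.
#' @param maf_range Lower/upper bound of the uniform minor-allele
#'   frequency distribution; within (0, 0.5].
#' @param exposure_effect_sd SD of the true per-SNP exposure effects
#'   (SD units of exposure per allele).
#' @param theta True causal effect, log-odds of outcome per SD exposure.
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct effects centred
#'   on zero by random sign) or `"directional"` (one-sided).
#' @param pleiotropy_mean Mean magnitude of the direct (pleiotropic)
#'   effect on the outcome for invalid SNPs.
#' @param pleiotropy_sd SD of the direct effect around its mean.
#' @param prop_invalid Fraction of SNPs carrying a direct effect.
#' @param n_exposure Exposure-GWAS sample size.
#' @param n_outcome_cases,n_outcome_controls Outcome-GWAS counts.
#' @param scramble_alleles If `TRUE`, randomly swap the reported
#'   effect/other allele of outcome rows (negating betas and
#'   complementing frequencies) to exercise harmonization.
#' @param seed Integer seed; the simulation is deterministic given the
#'   config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(m_snps = 50,
                       maf_range = c(0.05, 0.5),
                       exposure_effect_sd = 0.15,
                       theta = -0.5,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0.05,
                       prop_invalid = 0,
                       n_exposure = 5000,
                       n_outcome_cases = 50000,
                       n_outcome_controls = 150000,
                       scramble_alleles = FALSE,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (!(maf_range[1] > 0 && maf_range[1] < maf_range[2] &&
        maf_range[2] <= 0.5)) {
    abort("sim_config: need 0 < maf low < maf high <= 0.5",
          class = "cecmr_validation_error")
  }
  if (prop_invalid < 0 || prop_invalid > 1) {
    abort("sim_config: prop_invalid must lie in [0, 1]",
          class = "cecmr_validation_error")
  }
  if (any(c(m_snps, n_exposure, n_outcome_cases, n_outcome_controls) <= 0)) {
    abort("sim_config: counts and sample sizes must be positive",
          class = "cecmr_validation_error")
  }
  structure(list(
    m_snps = as.integer(m_snps), maf_range = maf_range,
    exposure_effect_sd = exposure_effect_sd, theta = theta,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd, prop_invalid = prop_invalid,
    n_exposure = n_exposure, n_outcome_cases = n_outcome_cases,
    n_outcome_controls = n_outcome_controls,
    scramble_alleles = isTRUE(scramble_alleles), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Draws summary statistics directly from their asymptotic sampling
#' distributions, without individual-level genotypes. For each SNP j:
#' MAF `f_j ~ U(maf_range)`; true exposure effect
#' `b_j ~ |N(0, exposure_effect_sd)|` (exposure standardized to SD 1;
#' effects are reported for the exposure-increasing allele, the
#' convention of published instrument tables, so `b_j >= 0`); true
#' outcome effect `theta * b_j + alpha_j`, where the direct effect
#' `alpha_j` is zero for valid SNPs and normal with the configured
#' mean/SD (sign randomized under `"balanced"`, one-sided under
#' `"directional"`) for the invalid fraction. Observed betas add noise
#' with standard errors `se_X = 1/sqrt(2 f (1-f) n_exposure)` and
#' `se_Y = 1/sqrt(2 f (1-f) n_total p (1-p))`, `p` the case fraction —
#' the asymptotic SEs of linear and logistic per-allele regressions on a
#' standardized trait.
#'
#' @param config A [sim_config()].
#' @return A list of class `mr_simulation`:
#'   \describe{
#'     \item{truth}{list with `theta`, per-SNP `maf`,
#'       `beta_exposure_true`, `beta_outcome_true`, `pleiotropy`
#'       (direct effects), and the logical `invalid` flags.}
#'     \item{exposure_table, outcome_table}{summary-association tibbles
#'       in the standard column layout, ready for [harmonize()].}
#'   }
#' @export
#' @examples
#' sim <- simulate_two_sample_summary(sim_config(m_snps = 20, seed = 7))
#' dat <- harmonize(sim$exposure_table, sim$outcome_table)
#' mr_ivw(dat)
simulate_two_sample_summary <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(cf) {
  m <- cf$m_snps
  maf <- runif(m, cf$maf_range[1], cf$maf_range[2])
  # reported for the exposure-increasing allele, hence non-negative;
  # directional pleiotropy is defined relative to that allele
  b_true <- abs(rnorm(m, 0, cf$exposure_effect_sd))
  n_invalid <- round(cf$prop_invalid * m)
  invalid <- rep(FALSE, m)
  if (cf$pleiotropy_mode != "none" && n_invalid > 0) {
    invalid[sample.int(m, n_invalid)] <- TRUE
  }
  alpha <- numeric(m)
  if (any(invalid)) {
    sgn <- if (cf$pleiotropy_mode == "balanced") {
      sample(c(-1, 1), sum(invalid), replace = TRUE)
    } else 1
    alpha[invalid] <- rnorm(sum(invalid), sgn * cf$pleiotropy_mean,
                            cf$pleiotropy_sd)
  }
  y_true <- cf$theta * b_true + alpha

  n_total <- cf$n_outcome_cases + cf$n_outcome_controls
  p <- cf$n_outcome_cases / n_total
  var_g <- 2 * maf * (1 - maf)
  se_x <- 1 / sqrt(var_g * cf$n_exposure)
  se_y <- 1 / sqrt(var_g * n_total * p * (1 - p))
  bx <- rnorm(m, b_true, se_x)
  by <- rnorm(m, y_true, se_y)

  snp <- sprintf("sim%04d", seq_len(m))
  exposure <- tibble(
    snp = snp, effect_allele = "A", other_allele = "G", eaf = maf,
    beta = bx, se = se_x, pvalue = 2 * pnorm(-abs(bx / se_x)),
    trait = "sim_exposure")
  outcome <- tibble(
    snp = snp, effect_allele = "A", other_allele = "G", eaf = maf,
    beta = by, se = se_y, pvalue = 2 * pnorm(-abs(by / se_y)),
    trait = "sim_outcome")
  if (cf$scramble_alleles) {
    swap <- runif(m) < 0.5
    outcome$effect_allele[swap] <- "G"
    outcome$other_allele[swap] <- "A"
    outcome$beta[swap] <- -outcome$beta[swap]
    outcome$eaf[swap] <- 1 - outcome$eaf[swap]
  }
  structure(list(
    truth = list(theta = cf$theta, maf = maf, beta_exposure_true = b_true,
                 beta_outcome_true = y_true, pleiotropy = alpha,
                 invalid = invalid),
    exposure_table = exposure,
    outcome_table = outcome,
    config = cf
  ), class = "mr_simulation")
}
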