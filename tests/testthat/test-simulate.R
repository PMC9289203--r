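test_that("simulation is deterministic given the config seed", {
  cf <- sim_config(m_snps = 50, seed = 7)
  a <- simulate_two_sample_summary(cf)
  b <- simulate_two_sample_summary(cf)
  expect_identical(a$exposure_table, b$exposure_table)
  expect_identical(a$outcome_table, b$outcome_table)
  expect_identical(a$truth, b$truth)
  c <- simulate_two_sample_summary(sim_config(m_snps = 50, seed = 8))
  expect_false(identical(a$exposure_table, c$exposure_table))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(maf_range = c(0.3, 0.3)),
               class = "cecmr_validation_error")
  expect_error(sim_config(maf_range = c(0, 0.5)),
               class = "cecmr_validation_error")
  expect_error(sim_config(prop_invalid = 1.4),
               class = "cecmr_validation_error")
  expect_error(sim_config(n_exposure = 0), class = "cecmr_validation_error")
})

test_that("observed betas scatter around truth at the nominal SEs", {
  sim <- simulate_two_sample_summary(sim_config(m_snps = 5000, seed = 11))
  zx <- (sim$exposure_table$beta - sim$truth$beta_exposure_true) /
    sim$exposure_table$se
  zy <- (sim$outcome_table$beta - sim$truth$beta_outcome_true) /
    sim$outcome_table$se
  expect_lt(abs(sd(zx) - 1), 0.05)
  expect_lt(abs(sd(zy) - 1), 0.05)
  expect_lt(abs(mean(zx)), 0.05)
  expect_lt(abs(mean(zy)), 0.05)
})

test_that("IVW recovers the causal effect with valid instruments", {
  # 200 replicates at exposure n = 1e6: consistency of IVW when every
  # instrument is valid; the mean estimate must sit within Monte-Carlo
  # error of the generating theta
  ests <- vapply(1:200, function(i) {
    sim <- simulate_two_sample_summary(sim_config(
      m_snps = 50, theta = -0.5, n_exposure = 1e6,
      n_outcome_cases = 5e5, n_outcome_controls = 15e5, seed = 1000 + i))
    dat <- harmonize(sim$exposure_table, sim$outcome_table)
    mr_ivw(dat)$theta
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - (-0.5)), 3 * mc_se)
})

test_that("directional pleiotropy biases IVW but not the Egger slope", {
  theta <- -0.5
  res <- vapply(1:200, function(i) {
    sim <- simulate_two_sample_summary(sim_config(
      m_snps = 50, theta = theta, pleiotropy_mode = "directional",
      pleiotropy_mean = 0.03, pleiotropy_sd = 0.005, prop_invalid = 0.4,
      n_exposure = 1e6, n_outcome_cases = 2e6, n_outcome_controls = 6e6,
      seed = 2000 + i))
    dat <- harmonize(sim$exposure_table, sim$outcome_table)
    c(ivw = mr_ivw(dat)$theta,
      egger_slope = mr_egger(dat)$slope$theta,
      egger_int = mr_egger(dat)$intercept$estimate,
      wmed = mr_median(dat, "weighted", n_boot = 10, seed = 1)$theta,
      mean_pleio = mean(sim$truth$pleiotropy))
  }, numeric(5))
  mc <- function(x) sd(x) / sqrt(length(x))
  # IVW drawn upward, in the direction of the positive mean pleiotropy
  ivw_bias <- mean(res["ivw", ]) - theta
  expect_gt(ivw_bias, 3 * mc(res["ivw", ]))
  # Egger slope unbiased, intercept recovers the mean direct effect
  expect_lt(abs(mean(res["egger_slope", ]) - theta),
            3 * mc(res["egger_slope", ]))
  expect_lt(abs(mean(res["egger_int", ] - res["mean_pleio", ])),
            3 * mc(res["egger_int", ] - res["mean_pleio", ]))
  # weighted median robust to 40% invalid instruments: its residual bias
  # (the median sits above the centre of the valid cluster when the
  # invalid minority is one-sided) stays small in absolute terms and far
  # below the IVW bias
  wmed_bias <- abs(mean(res["wmed", ]) - theta)
  expect_lt(wmed_bias, 0.05)
  expect_lt(wmed_bias, ivw_bias / 3)
})

test_that("Q p-values are approximately uniform with no pleiotropy", {
  # large exposure sample: ratio-based Q ignores exposure-side noise
  # (first-order weights), so uniformity holds in the NOME regime
  pvals <- vapply(1:1000, function(i) {
    sim <- simulate_two_sample_summary(sim_config(
      m_snps = 20, theta = -0.3, n_exposure = 1e6, seed = 3000 + i))
    dat <- harmonize(sim$exposure_table, sim$outcome_table)
    cochran_q(dat)$pvalue
  }, numeric(1))
  ks <- max(abs(sort(pvals) - (seq_along(pvals) - 0.5) / length(pvals)))
  expect_lt(ks, 0.05)
})

test_that("scrambled allele orientation is undone by harmonization", {
  cf_plain <- sim_config(m_snps = 40, seed = 5)
  cf_scram <- sim_config(m_snps = 40, seed = 5, scramble_alleles = TRUE)
  plain <- simulate_two_sample_summary(cf_plain)
  scram <- simulate_two_sample_summary(cf_scram)
  h_plain <- harmonize(plain$exposure_table, plain$outcome_table)
  h_scram <- harmonize(scram$exposure_table, scram$outcome_table)
  expect_true(any(h_scram$flipped))
  expect_equal(h_scram$beta_outcome, h_plain$beta_outcome)
  expect_equal(mr_ivw(h_scram)$theta, mr_ivw(h_plain)$theta)
})
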