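fx_cad1 <- function() fixture_instrument("CAD", instrument = "1snp")
fx_cad5 <- function() fixture_instrument("CAD")

test_that("Wald ratio reproduces the delta-method formulas", {
  # rs141622900: beta_outcome/beta_exposure and se_outcome/|beta_exposure|
  # evaluated by hand from the fixture values -0.1421/0.2833, 0.0278/0.2833
  est <- mr_wald_ratio(fx_cad1())
  expect_equal(est$theta, -0.50159, tolerance = 1e-4)
  expect_equal(est$se, 0.09813, tolerance = 1e-4)
  expect_equal(est$odds_ratio, 0.6056, tolerance = 1e-4)

  is1 <- mr_wald_ratio(fixture_instrument("IS", instrument = "1snp"))
  expect_equal(is1$theta, -0.20438, tolerance = 1e-4)
  expect_equal(is1$odds_ratio, 0.8152, tolerance = 1e-4)

  null_inst <- make_harmonized(bx = 0.2, by = 0, sy = 0.01)
  expect_equal(mr_wald_ratio(null_inst)$odds_ratio, 1)

  degen <- make_harmonized(bx = 0, by = 0.1, sy = 0.01)
  expect_error(mr_wald_ratio(degen), class = "cecmr_degenerate_instrument")
})

test_that("IVW closed form agrees with through-origin WLS to 1e-12", {
  for (seed in 1:10) {
    dat <- random_instrument(k = 8, seed = seed)
    fit <- mr_ivw(dat)
    oracle <- stats::lm(beta_outcome ~ 0 + beta_exposure, data = dat,
                        weights = 1 / dat$se_outcome^2)
    expect_equal(fit$theta, unname(coef(oracle)), tolerance = 1e-12)
  }
})

test_that("IVW with one instrument equals the Wald ratio", {
  one <- fx_cad1()
  expect_equal(mr_ivw(one)$theta, mr_wald_ratio(one)$theta)
  expect_equal(mr_ivw(one)$se, mr_wald_ratio(one)$se)
})

test_that("IVW is invariant to joint sign relabeling of any instrument", {
  dat <- fx_cad5()
  for (i in seq_len(nrow(dat))) {
    flipped <- dat
    flipped$beta_exposure[i] <- -flipped$beta_exposure[i]
    flipped$beta_outcome[i] <- -flipped$beta_outcome[i]
    expect_equal(mr_ivw(flipped)$theta, mr_ivw(dat)$theta)
  }
})

test_that("multiplicative variance model inflates the SE under dispersion", {
  dat <- fx_cad5()
  fixed <- mr_ivw(dat, "fixed")
  mult <- mr_ivw(dat, "multiplicative")
  expect_equal(mult$theta, fixed$theta)
  q <- cochran_q(dat)$Q
  expect_equal(mult$se, fixed$se * sqrt(q / 4))
  # no deflation when Q is below its dof
  tight <- make_harmonized(bx = c(0.2, 0.25, 0.3),
                           by = c(-0.1, -0.125, -0.15) + c(1e-6, 0, -1e-6),
                           sy = c(0.05, 0.05, 0.05))
  expect_equal(mr_ivw(tight, "multiplicative")$se, mr_ivw(tight, "fixed")$se)
  expect_error(mr_ivw(fx_cad1(), "multiplicative"),
               class = "cecmr_usage_error")
})

test_that("MR-Egger recovers an exact linear relationship", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  dat <- make_harmonized(bx = bx, by = -0.7 * bx, sy = rep(0.02, 4))
  fit <- mr_egger(dat)
  expect_equal(fit$slope$theta, -0.7, tolerance = 1e-10)
  expect_equal(fit$intercept$estimate, 0, tolerance = 1e-10)

  dat2 <- make_harmonized(bx = bx, by = 0.05 - 0.7 * bx, sy = rep(0.02, 4))
  fit2 <- mr_egger(dat2)
  expect_equal(fit2$slope$theta, -0.7, tolerance = 1e-10)
  expect_equal(fit2$intercept$estimate, 0.05, tolerance = 1e-10)
})

test_that("MR-Egger orients instruments and refuses fewer than 3", {
  dat <- fx_cad5()
  flipped <- dat
  flipped$beta_exposure[2] <- -flipped$beta_exposure[2]
  flipped$beta_outcome[2] <- -flipped$beta_outcome[2]
  expect_equal(mr_egger(flipped)$slope$theta, mr_egger(dat)$slope$theta)
  expect_error(mr_egger(dat[1:2, ]),
               class = "cecmr_insufficient_instruments")
})

test_that("weighted-median interpolation matches the hand-evaluated rule", {
  # k = 5 equal-weight ratios; cumulative standardized weights are
  # (0.1, 0.3, 0.5, 0.7, 0.9), so p = 0.5 lands exactly on the 3rd order
  # statistic of {-0.3981, -0.2560, -0.2476, -0.2128, 0.2612}
  theta <- c(-0.3981, -0.2560, -0.2476, -0.2128, 0.2612)
  dat <- make_harmonized(bx = rep(1, 5), by = theta, sy = rep(1, 5))
  est <- mr_simple_median(dat, n_boot = 10, seed = 1)
  expect_equal(est$theta, -0.2476)
})

test_that("equal weights reduce the weighted median to the simple median", {
  dat <- make_harmonized(bx = rep(0.2, 5),
                         by = c(-0.05, 0.01, -0.03, -0.08, 0.02),
                         sy = rep(0.01, 5))  # equal ratio weights
  wm <- mr_weighted_median(dat, n_boot = 10, seed = 1)
  sm <- mr_simple_median(dat, n_boot = 10, seed = 1)
  expect_equal(wm$theta, sm$theta)
})

test_that("a dominant weight pins the weighted median to its ratio", {
  dat <- make_harmonized(bx = c(0.2, 0.2, 0.2),
                         by = c(-0.04, 0.02, 0.06),
                         sy = c(1e-5, 1, 1))  # first SNP carries >99.9% weight
  est <- mr_weighted_median(dat, n_boot = 10, seed = 1)
  expect_equal(round(est$theta, 4), round(-0.04 / 0.2, 4))
})

test_that("median estimates lie within the range of the per-SNP ratios", {
  for (seed in 1:8) {
    dat <- random_instrument(k = 7, seed = seed)
    r <- ratio_estimates(dat)$theta
    for (w in c("simple", "weighted")) {
      est <- mr_median(dat, w, n_boot = 10, seed = 1)
      expect_gte(est$theta, min(r))
      expect_lte(est$theta, max(r))
    }
  }
})

test_that("bootstrap SE is reproducible bit-for-bit under a fixed seed", {
  dat <- fx_cad5()
  a <- mr_weighted_median(dat, n_boot = 200, seed = 42)
  b <- mr_weighted_median(dat, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(dat, n_boot = 200, seed = 43)
  expect_false(identical(a$se, c$se))
})

test_that("multivariable IVW with one exposure reduces to fixed IVW", {
  dat <- fx_cad5()
  mv <- mr_mv_ivw(dplyr::rename(dat, beta_cec = beta_exposure),
                  exposures = "beta_cec")
  uv <- mr_ivw(dat, "fixed")
  expect_equal(mv$estimate, uv$theta)
  expect_equal(mv$std.error, uv$se)
})

test_that("multivariable IVW recovers a known effect vector from noiseless data", {
  withr::with_seed(9, {
    k <- 12
    b1 <- rnorm(k, 0.2, 0.05)
    b2 <- rnorm(k, -0.1, 0.08)
    dat <- tibble::tibble(
      beta_x1 = b1, beta_x2 = b2,
      beta_outcome = 0.5 * b1 - 0.2 * b2,
      se_outcome = runif(k, 0.01, 0.05))
  })
  mv <- mr_mv_ivw(dat, exposures = c("beta_x1", "beta_x2"))
  expect_equal(mv$estimate, c(0.5, -0.2), tolerance = 1e-6)
})

test_that("multivariable IVW detects rank deficiency", {
  dat <- tibble::tibble(beta_x1 = c(0.1, 0.2, 0.3, 0.4),
                        beta_x2 = 2 * c(0.1, 0.2, 0.3, 0.4),
                        beta_outcome = rnorm(4), se_outcome = rep(0.02, 4))
  err <- expect_error(mr_mv_ivw(dat, exposures = c("beta_x1", "beta_x2")),
                      class = "cecmr_collinearity_error")
  expect_match(conditionMessage(err), "beta_x2")
  expect_error(mr_mv_ivw(dat[1:2, ], exposures = c("beta_x1", "beta_x2")),
               class = "cecmr_insufficient_instruments")
})

test_that("tidy and glance return broom-shaped tibbles", {
  td <- tidy(mr_ivw(fx_cad5()))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("estimate", "std.error", "conf.low", "conf.high",
                    "p.value", "odds_ratio") %in% names(td)))
  expect_equal(td$odds_ratio, exp(td$estimate))
  expect_equal(td$or_conf_low, exp(td$conf.low))

  te <- tidy(mr_egger(fx_cad5()))
  expect_equal(te$term, c("slope", "intercept"))
  expect_true(te$conf.low[2] <= te$estimate[2] &&
              te$estimate[2] <= te$conf.high[2])
})
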