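# Build a harmonized-instrument tibble directly from numeric vectors,
# bypassing file IO and allele bookkeeping.
make_harmonized <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                            snp = sprintf("rs%03d", seq_along(bx)),
                            eaf = rep(0.3, length(bx))) {
  tibble::tibble(
    snp = snp,
    effect_allele = "A", other_allele = "G", eaf = eaf,
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy,
    palindromic = FALSE, flipped = FALSE
  )
}

# One-row summary-association records for harmonize_pair tests.
assoc_row <- function(snp = "rs1", ea = "A", oa = "G", eaf = 0.3,
                      beta = 0.1, se = 0.02, trait = "x") {
  tibble::tibble(snp = snp, effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = se, pvalue = NA_real_,
                 trait = trait)
}

# Random harmonized instrument sets for property-style loops.
random_instrument <- function(k, seed) {
  withr::with_seed(seed, make_harmonized(
    bx = rnorm(k, 0.2, 0.05),
    by = rnorm(k, -0.05, 0.03),
    sy = runif(k, 0.005, 0.03)
  ))
}
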