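---
title: "Methods: two-sample MR of cholesterol efflux capacity on cardiovascular disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR of cholesterol efflux capacity on cardiovascular disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cecmr)
library(dplyr)
```

## The question and the design

Cholesterol efflux capacity (CEC) measures how well a person's HDL
particles accept cholesterol from macrophages — a functional property of
HDL that observational cohorts have repeatedly found to predict
cardiovascular events independently of the HDL-cholesterol
concentration. Observational associations, however, are vulnerable to
confounding and reverse causation. Two-sample Mendelian randomization
(MR) sidesteps both by using genetic variants as instruments: alleles
are assorted at conception, so a variant that raises CEC provides a
randomized nudge to lifelong CEC, and its association with disease
reflects the causal pathway if the instrument assumptions hold.

`cecmr` implements the complete summary-statistic machinery for this
design: harmonization of exposure and outcome association tables to a
common effect allele, the standard estimator family (Wald ratio, IVW,
MR-Egger, simple and weighted median, multivariable IVW), heterogeneity
diagnostics (Cochran Q, I²), instrument-strength and power calculations,
and a calibrated synthetic-data generator used to validate every
estimator against known truth. The package ships the published
association tables for the CEC instruments (six SNPs from a GWAS of up
to 5,293 Europeans) against coronary artery disease (CAD) and myocardial
infarction (MI) from CARDIoGRAMplusC4D, and ischemic stroke (IS) with
its large-artery (LAS), small-vessel (SVS) and cardioembolic (CES)
subtypes from MEGASTROKE, as plain TSV fixtures diffable against the
printed tables.

## The estimators

All estimators consume a harmonized table with per-SNP exposure effects
$\hat\beta_{Xj}$ (SD units of CEC per allele), outcome effects
$\hat\beta_{Yj}$ (log-odds per allele) and their standard errors.

**Wald ratio** (single instrument):
$\hat\theta = \hat\beta_Y / \hat\beta_X$ with first-order delta SE
$\mathrm{se}_Y / |\hat\beta_X|$. This "no measurement error" (NOME)
simplification ignores exposure-side sampling error; it is the variance
model under which the published intervals reproduce, and it is
conservative only when instruments are strong (here F ≈ 46–59). The
exposure SE is carried in the data structures but deliberately not used
in any weight; this is a documented limitation, not an oversight.

**IVW**: the inverse-variance weighted combination of the per-SNP
ratios with weights $w_j = \hat\beta_{Xj}^2/\mathrm{se}_{Yj}^2$,
algebraically identical to weighted least squares of
$\hat\beta_Y$ on $\hat\beta_X$ through the origin with weights
$1/\mathrm{se}_{Yj}^2$. Both forms are implemented and compared to
1e-12 in the test suite — the closed form in the package, the
`lm(…, weights = )` regression as the independent oracle. The default
variance model is fixed-effect, $\mathrm{se} = (\sum w_j)^{-1/2}$,
because the published five-SNP confidence intervals (e.g. 0.79–0.90 for
CAD) match fixed-effect SEs; a multiplicative random-effects model that
inflates the SE by $\max(1, \sqrt{Q/(k-1)})$ is available via
`variance_model = "multiplicative"` and reported alongside.

**MR-Egger**: weighted least squares of $\hat\beta_Y$ on
$\hat\beta_X$ with a free intercept, after orienting every SNP so
$\hat\beta_X \ge 0$. Under the InSIDE assumption the slope is a
pleiotropy-corrected causal estimate and the intercept estimates the
average directional pleiotropic effect. SEs are scaled by
$\sqrt{\mathrm{RSS}_w/(k-2)}$ with no truncation at 1 — allowing the
scale to fall below 1 is what reproduces the published CAD row (slope OR
0.35, CI 0.14–0.89; intercept 0.156). The intercept's lower CI bound
evaluates to −0.006 at 3 decimals from the 4-decimal fixture betas.

**Medians**: per-SNP ratios are ordered and the weighted empirical CDF
interpolated at probability 0.5, with cumulative standardized weights
$p_j = (\sum_{i\le j} w_i - w_j/2)/\sum_i w_i$. The simple median uses
equal weights, the weighted median the inverse-variance ratio weights.
If 0.5 falls below $p_1$ or above $p_k$ the estimate clamps to the
extreme ratio; ties are broken by a stable sort on SNP id. The SE is a
parametric bootstrap (default 1000 replicates, seedable): both betas are
resampled from $N(\hat\beta, \mathrm{se})$, the median recomputed, and
the SD across replicates taken. The point estimate never depends on the
bootstrap.

**Multivariable IVW**: WLS of $\hat\beta_Y$ on several exposures'
betas jointly, no intercept, weights $1/\mathrm{se}_Y^2$; rank
deficiency of the exposure design is a hard error naming the dependent
columns. The covariate association tables needed to run this on the CEC
instruments are not published, so the estimator is validated on
synthetic designs only (exact recovery of a known effect vector from
noiseless data, and the single-exposure reduction to IVW).

## Heterogeneity and between-outcome comparison

Within an instrument set, $Q = \sum_j w_j(\hat\theta_j -
\hat\theta_{IVW})^2$ on $k-1$ df, and $I^2 = \max(0, (Q-df)/Q)$. Q is
invariant to rescaling all exposure betas by a positive constant — the
SD-unit ambiguity of the exposure cannot move it — and this is tested as
a property. The same machinery compares causal estimates *between*
outcomes (CAD vs ischemic stroke), pooling with weights $1/\mathrm{se}^2$;
fixed-model SEs are used on both sides because that choice reproduces
the published comparison I² values (80% for the single-SNP Wald
estimates, 93% for the five-SNP IVW estimates). Estimates are flagged
significant at the Bonferroni threshold p < 0.05/6 ≈ 0.0083 for the six
outcomes tested.

From the 4-decimal printed betas the CAD instrument Q evaluates to 42.4
against a published 42.5 — consistent with the original computation
using unrounded GWAS values; MI (35.4) and IS (5.3) reproduce exactly at
printed precision.

## Instrument strength and power

Variance explained per SNP is $2\hat\beta_X^2 m(1-m)$ with $m$ the
minor-allele frequency; the F statistic is
$(R^2/k)\,/\,((1-R^2)/(n-k-1))$. Evaluating these from the fixture
table: the single SNP rs141622900 explains 0.877% (prints as 0.9%) and
the five-SNP instrument 4.30% (the source prints 5.3%, which is not
recoverable from its own table — all six SNPs give 5.2%). The published
F labels are transposed relative to the formula: 59.2 arises for
(R² = 0.053, k = 5) and 45.9 for (R² ≈ 0.0086, k = 1). The package
computes both; it does not guess which label was intended.

Power for a binary outcome uses the normal-approximation
non-centrality form
$\Phi\!\left(\sqrt{n\,R^2\,p(1-p)}\,\,|\ln \mathrm{OR}|
 - z_{1-\alpha/2}\right)$
with $p$ the case fraction (cases / (cases + controls) from the study
descriptors). At OR = 1 this degenerates to $\alpha/2$, the documented
limit. All published power figures reproduce at integer rounding except
the small-vessel and cardioembolic entries for a 30% risk reduction,
which evaluate to 69% and 81% against printed 70% and 82%.

## The synthetic-data generator

`simulate_two_sample_summary()` draws summary statistics directly from
their asymptotic sampling distributions rather than simulating
individual-level genotypes — orders of magnitude faster and sufficient
to validate every estimator, since the estimators only ever see summary
rows. Per SNP: MAF uniform on the configured range; true exposure
effect half-normal (effects are emitted for the exposure-increasing
allele, the convention of published instrument tables — without this,
sign orientation inside MR-Egger would cancel directional pleiotropy by
construction); true outcome effect $\theta b_j + \alpha_j$ with the
direct effect $\alpha_j$ zero for valid SNPs and normal with configurable
mean, SD, sign structure (balanced/directional) and invalid fraction
otherwise; observed betas add noise at the asymptotic SEs
$1/\sqrt{2f(1-f)n_X}$ and $1/\sqrt{2f(1-f)n_Y p(1-p)}$. Everything is
deterministic given the config seed; an option scrambles outcome allele
orientation to exercise harmonization.

Defaults mirror the study the package is built around: an exposure GWAS
of ~5,000, a large case-control outcome GWAS, per-SNP exposure effects
of ~0.15 SD, and a protective causal effect of −0.5 log-odds per SD.
What the generator does **not** emulate: linkage disequilibrium between
instruments, sample overlap between the two GWAS, winner's curse in
instrument selection, and exposure-side weak-instrument bias beyond what
the noise model implies. Passing parameter-recovery tests therefore
demonstrates correctness of the estimators under the two-sample
summary-data model, not robustness to those real-data complications.

The validation suite checks, over seeded Monte-Carlo replicates: IVW
recovers the generating effect with valid instruments; under directional
pleiotropy (40% invalid) IVW is biased in the pleiotropy direction while
the Egger slope is not and the Egger intercept recovers the mean direct
effect; the weighted median's residual bias stays small in absolute
terms and well below the IVW bias (its textbook "consistency with <50%
invalid weight" is an asymptotic statement — at finite noise the
weighted median sits slightly off-centre within the valid cluster, so an
exact unbiasedness test would be wrong); and Cochran Q p-values are
uniform in the no-pleiotropy, negligible-exposure-noise (NOME) regime
where the ratio-based Q is calibrated. Problem sizes (50 SNPs, 200
replicates; 1,000 replicates for the uniformity check) keep the full
suite around two minutes while leaving Monte-Carlo error well below the
asserted margins.

## Numerical conventions and edge cases

* The 95% normal quantile is fixed at 1.959964 everywhere.
* Reports print ORs to 2 decimals, Egger intercepts to 3, Q to 1
  decimal and I² as integer percent; JSON serialization keeps full
  precision and round-trips exactly.
* p-values below 1e-300 render as "<1e-300"; no continuity corrections
  anywhere.
* A zero exposure beta is a degenerate instrument (hard error), not a
  silent infinity; fewer instruments than an estimator's minimum
  (1 for Wald/IVW, 3 for Egger and the medians, E+1 for multivariable)
  is a typed error.
* Palindromic SNPs (A/T, C/G) are dropped during harmonization only
  when both effect-allele frequencies lie inside (0.42, 0.58); with the
  window configurable. The packaged outcome tables print no frequencies,
  so fixture harmonization is by allele letters alone — for these
  pre-aligned tables that is exact.

## Reproduction scope

Every headline number that is computable from the printed tables is
reproduced by the test suite and by `scripts/acceptance.R`: the five-SNP
IVW ORs (0.85 CAD, 0.86 MI, 1.02 IS), the CAD sensitivity row (Egger
0.35, intercept 0.156, medians 0.78/0.79), instrument Q for MI and IS,
the between-outcome I² (93% and 80%), the SVS power figures (42%, 16%)
and the single-SNP variance explained (0.9%). The published single-SNP
odds ratios (0.55 CAD, 0.67 MI, 0.79 IS) are **not** reproducible from
the printed exposure beta 0.2833 — jointly, those ORs and their CI
widths imply an exposure beta near 0.24 — so the package computes what
the tables imply (e.g. OR 0.61 for CAD) and documents the discrepancy
rather than matching the figure. Scale-free statistics (Q, I², p) are
unaffected by that ambiguity.
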