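COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) {
  ea %in% names(COMPLEMENT) & COMPLEMENT[ea] == oa
}

flip_strand <- function(allele) {
  ifelse(allele %in% names(COMPLEMENT), unname(COMPLEMENT[allele]), allele)
}

#' Harmonize one exposure/outcome summary pair to a common effect allele
#'
#' Aligns the outcome association to the exposure's effect allele. If the
#' outcome reports the same alleles swapped, the outcome beta is negated
#' and its effect-allele frequency replaced by its complement
#' (`flipped = TRUE`). If the alleles only match after complementing the
#' outcome's strand, the strand is flipped first. Palindromic SNPs
#' (A/T or C/G) are flagged; they are returned with `palindromic = TRUE`
#' and `keep = FALSE` when both effect-allele frequencies lie inside the
#' ambiguity window around 0.5 (they cannot be oriented), otherwise kept.
#' When either frequency is missing, palindromic SNPs are oriented by
#' allele letters alone and kept.
#'
#' @param exposure,outcome One-row summary-association tibbles (or lists)
#'   for the same SNP, with fields `snp`, `effect_allele`, `other_allele`,
#'   `beta`, `se` and optional `eaf`.
#' @param palindromic_eaf_window Half-width of the frequency window around
#'   0.5 within which a palindromic SNP is considered unresolvable.
#'   Default 0.08, i.e. EAF in (0.42, 0.58).
#' @return A one-row tibble with columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `palindromic`, `flipped`, `keep`.
#' @export
#' @examples
#' e <- tibble::tibble(snp = "rs1", effect_allele = "A", other_allele = "G",
#'                     eaf = 0.3, beta = 0.1, se = 0.02)
#' o <- tibble::tibble(snp = "rs1", effect_allele = "G", other_allele = "A",
#'                     eaf = 0.7, beta = 0.05, se = 0.01)
#' harmonize_pair(e, o)$beta_outcome  # -0.05
harmonize_pair <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  e <- as.list(exposure)
  o <- as.list(outcome)
  if (!identical(as.character(e$snp), as.character(o$snp))) {
    abort(paste0("snp_id mismatch: exposure ", e$snp, " vs outcome ", o$snp),
          class = "cecmr_usage_error")
  }
  e_eaf <- if (is.null(e$eaf)) NA_real_ else e$eaf
  o_eaf <- if (is.null(o$eaf)) NA_real_ else o$eaf
  o_ea <- o$effect_allele
  o_oa <- o$other_allele
  o_beta <- o$beta

  same <- identical(o_ea, e$effect_allele) && identical(o_oa, e$other_allele)
  swapped <- identical(o_ea, e$other_allele) && identical(o_oa, e$effect_allele)
  if (!same && !swapped) {
    # try resolving a strand flip of the outcome record
    f_ea <- flip_strand(o_ea)
    f_oa <- flip_strand(o_oa)
    if (identical(f_ea, e$effect_allele) && identical(f_oa, e$other_allele)) {
      same <- TRUE
    } else if (identical(f_ea, e$other_allele) &&
               identical(f_oa, e$effect_allele)) {
      swapped <- TRUE
    } else {
      abort(paste0("irreconcilable alleles for ", e$snp, ": exposure ",
                   e$effect_allele, "/", e$other_allele, ", outcome ",
                   o_ea, "/", o_oa),
            class = "cecmr_harmonization_error")
    }
  }

  flipped <- FALSE
  if (swapped) {
    o_beta <- -o_beta
    o_eaf <- 1 - o_eaf
    flipped <- TRUE
  }

  palin <- unname(is_palindromic(e$effect_allele, e$other_allele))
  keep <- TRUE
  if (palin && !is.na(e_eaf) && !is.na(o_eaf)) {
    w <- palindromic_eaf_window
    if (abs(e_eaf - 0.5) < w && abs(o_eaf - 0.5) < w) keep <- FALSE
  }

  tibble(
    snp = as.character(e$snp),
    effect_allele = e$effect_allele,
    other_allele = e$other_allele,
    eaf = e_eaf,
    beta_exposure = e$beta,
    se_exposure = e$se,
    beta_outcome = o_beta,
    se_outcome = o$se,
    palindromic = palin,
    flipped = flipped,
    keep = keep
  )
}

#' Harmonize exposure and outcome summary tables
#'
#' Joins two summary-association tables on `snp` and applies
#' [harmonize_pair()] row by row. Palindromic SNPs that cannot be oriented
#' (both frequencies inside the ambiguity window) are dropped with a
#' message. SNPs absent from either table are dropped silently: the
#' instrument is the intersection.
#'
#' @param exposure,outcome Summary-association tibbles as returned by
#'   [read_summary_table()].
#' @param palindromic_eaf_window See [harmonize_pair()].
#' @return A harmonized-instrument tibble (one row per retained SNP) with
#'   columns `snp`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `palindromic`, `flipped`.
#' @export
#' @examples
#' fx <- mr_fixtures()
#' dat <- harmonize(fx$associations$CEC, fx$associations$CAD)
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  exposure <- as_tibble(exposure)
  outcome <- as_tibble(outcome)
  shared <- intersect(exposure$snp, outcome$snp)
  rows <- purrr::map(shared, function(s) {
    harmonize_pair(exposure[exposure$snp == s, ][1, ],
                   outcome[outcome$snp == s, ][1, ],
                   palindromic_eaf_window = palindromic_eaf_window)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(snp = character(), effect_allele = character(),
                  other_allele = character(), eaf = numeric(),
                  beta_exposure = numeric(), se_exposure = numeric(),
                  beta_outcome = numeric(), se_outcome = numeric(),
                  palindromic = logical(), flipped = logical()))
  }
  dropped <- out$snp[!out$keep]
  if (length(dropped) > 0) {
    inform(paste0("dropping palindromic SNP(s) with ambiguous strand: ",
                  paste(dropped, collapse = ", ")))
  }
  dplyr::select(out[out$keep, ], -"keep")
}
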