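#' Published CEC and cardiovascular-outcome summary statistics
#'
#' Loads the packaged GWAS summary-statistic tables for the exposure
#' (HDL cholesterol efflux capacity, CEC; 6 SNPs from a GWAS of up to
#' 5,293 Europeans) and the six binary outcomes: coronary artery disease
#' (CAD) and myocardial infarction (MI) from CARDIoGRAMplusC4D, and
#' ischemic stroke (IS) with its large-artery (LAS), small-vessel (SVS)
#' and cardioembolic (CES) subtypes from MEGASTROKE. Betas are per-allele
#' effects: SD units of CEC for the exposure, log-odds for the outcomes.
#' Outcome tables carry no effect-allele frequency; harmonization against
#' them relies on allele letters.
#'
#' @return A list with elements
#'   \describe{
#'     \item{studies}{tibble of study descriptors: `trait`, `consortium`,
#'       `n_cases`, `n_controls`, `n_total`, `ancestry`.}
#'     \item{associations}{named list of summary-association tibbles,
#'       one per trait (`CEC`, `CAD`, `MI`, `IS`, `LAS`, `SVS`, `CES`).}
#'   }
#' @export
#' @examples
#' fx <- mr_fixtures()
#' fx$associations$CEC
#' fx$studies
mr_fixtures <- function() {
  dir <- system.file("extdata", package = "cecmr")
  traits <- c(CEC = "cec", CAD = "cad", MI = "mi", IS = "is",
              LAS = "las", SVS = "svs", CES = "ces")
  assoc <- purrr::imap(traits, function(file, trait) {
    read_summary_table(file.path(dir, paste0(file, ".tsv")), trait = trait)
  })
  studies <- readr::read_tsv(file.path(dir, "studies.tsv"),
                             show_col_types = FALSE, progress = FALSE,
                             na = c("", "NA"))
  list(studies = studies, associations = assoc)
}

# rsIDs of the five-locus sensitivity instrument (LPL, LIPC, CETP,
# APOA1/C3/A4/A5, APOE/C1/C2/C4) and the single primary instrument.
FIVE_SNP_INSTRUMENT <- c("rs77069344", "rs2070895", "rs247616",
                         "rs964184", "rs445925")
ONE_SNP_INSTRUMENT <- "rs141622900"

#' Harmonized fixture instrument for one outcome
#'
#' Convenience wrapper: harmonizes the packaged CEC exposure table against
#' a packaged outcome table, restricted to either the 5-SNP instrument
#' (`rs77069344`, `rs2070895`, `rs247616`, `rs964184`, `rs445925`) or the
#' single-SNP instrument (`rs141622900`).
#'
#' @param outcome Trait label: one of `"CAD"`, `"MI"`, `"IS"`, `"LAS"`,
#'   `"SVS"`, `"CES"`.
#' @param instrument `"5snp"` (default) or `"1snp"`.
#' @return A harmonized-instrument tibble (see [harmonize()]).
#' @export
#' @examples
#' mr_ivw(fixture_instrument("CAD"))
fixture_instrument <- function(outcome = c("CAD", "MI", "IS", "LAS", "SVS", "CES"),
                               instrument = c("5snp", "1snp")) {
  outcome <- match.arg(outcome)
  instrument <- match.arg(instrument)
  fx <- mr_fixtures()
  snps <- if (instrument == "5snp") FIVE_SNP_INSTRUMENT else ONE_SNP_INSTRUMENT
  exposure <- dplyr::filter(fx$associations$CEC, .data$snp %in% snps)
  harmonize(exposure, fx$associations[[outcome]])
}
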