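#' Column aliases recognised when reading GWAS summary tables
#'
#' Maps common column-name variants found in GWAS summary-statistic files
#' onto the package's canonical names. Matching is case-insensitive.
#' Unknown extra columns are preserved on read but ignored downstream.
#'
#' @return A named list: canonical name -> character vector of accepted
#'   aliases (the canonical name itself is always accepted).
#' @export
#' @examples
#' summary_column_aliases()$se
summary_column_aliases <- function() {
  list(
    snp           = c("snp", "snp_id", "rsid", "rs_id", "marker", "markername", "variant", "variant_id"),
    effect_allele = c("effect_allele", "ea", "a1", "allele1", "alt"),
    other_allele  = c("other_allele", "oa", "a2", "allele2", "ref", "non_effect_allele"),
    eaf           = c("eaf", "effect_allele_freq", "freq", "af", "maf"),
    beta          = c("beta", "b", "effect", "effect_size"),
    se            = c("se", "stderr", "std_err", "standard_error", "se_beta"),
    pvalue        = c("pvalue", "p", "pval", "p_value"),
    trait         = c("trait", "phenotype", "outcome")
  )
}

canonical_names <- function(nms) {
  aliases <- summary_column_aliases()
  low <- tolower(nms)
  for (canon in names(aliases)) {
    hit <- which(low %in% aliases[[canon]])
    if (length(hit) > 0) nms[hit[1]] <- canon
  }
  nms
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-delimited file of per-SNP association rows
#' (one row per SNP for a single trait) and validates it. Column names are
#' mapped through [summary_column_aliases()]; `snp`, `effect_allele`,
#' `other_allele`, `beta` and `se` are mandatory, `eaf` and `pvalue`
#' optional. Rows violating the row invariants (`se > 0`,
#' `0 < eaf < 1`, `effect_allele != other_allele`) are rejected with their
#' row numbers. When a `pvalue` column is present, each p is checked for
#' consistency with the two-sided normal p of `beta/se`; disagreement
#' beyond printing precision raises a warning, not an error.
#'
#' @param path Path to a delimited text file with a header.
#' @param trait Trait label attached to every row (overrides any `trait`
#'   column in the file). `NULL` keeps the file's column or leaves `NA`.
#' @return A tibble with columns `snp`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, `trait`.
#' @export
#' @examples
#' path <- system.file("extdata", "cec.tsv", package = "cecmr")
#' read_summary_table(path)
read_summary_table <- function(path, trait = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "cecmr_io_error")
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, na = c("", "NA"))
  names(raw) <- canonical_names(names(raw))
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    abort(paste0("summary table ", path, " lacks mandatory column(s): ",
                 paste(missing, collapse = ", ")),
          class = "cecmr_format_error")
  }
  if (!"eaf" %in% names(raw)) raw$eaf <- NA_real_
  if (!"pvalue" %in% names(raw)) raw$pvalue <- NA_real_
  if (!"trait" %in% names(raw)) raw$trait <- NA_character_
  if (!is.null(trait)) raw$trait <- trait
  out <- dplyr::select(raw, dplyr::all_of(c(
    "snp", "effect_allele", "other_allele", "eaf", "beta", "se",
    "pvalue", "trait")))
  out <- dplyr::mutate(out,
    snp = as.character(.data$snp),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele)),
    dplyr::across(dplyr::all_of(c("eaf", "beta", "se", "pvalue")), as.numeric))
  validate_summary_table(out, context = path)
}

#' Validate a summary-association tibble
#'
#' Enforces the per-row invariants of a summary-association record and
#' returns the tibble unchanged on success. Used internally by
#' [read_summary_table()] and exported for data assembled in code.
#'
#' @param data Tibble with at least `snp`, `effect_allele`, `other_allele`,
#'   `beta`, `se`; optionally `eaf`, `pvalue`.
#' @param context Label used in error messages (e.g. a file name).
#' @return `data`, invisibly unchanged, as a tibble.
#' @export
validate_summary_table <- function(data, context = "summary table") {
  data <- as_tibble(data)
  bad_se <- which(!is.finite(data$se) | data$se <= 0)
  if (length(bad_se) > 0) {
    abort(paste0(context, ": non-positive or missing se in row(s) ",
                 paste(bad_se, collapse = ", ")),
          class = "cecmr_validation_error")
  }
  if ("eaf" %in% names(data)) {
    bad_eaf <- which(!is.na(data$eaf) & (data$eaf <= 0 | data$eaf >= 1))
    if (length(bad_eaf) > 0) {
      abort(paste0(context, ": eaf outside (0,1) in row(s) ",
                   paste(bad_eaf, collapse = ", ")),
            class = "cecmr_validation_error")
    }
  }
  bad_allele <- which(is.na(data$effect_allele) | is.na(data$other_allele) |
                      data$effect_allele == data$other_allele)
  if (length(bad_allele) > 0) {
    abort(paste0(context, ": identical or missing alleles in row(s) ",
                 paste(bad_allele, collapse = ", ")),
          class = "cecmr_validation_error")
  }
  bad_beta <- which(!is.finite(data$beta))
  if (length(bad_beta) > 0) {
    abort(paste0(context, ": missing beta in row(s) ",
                 paste(bad_beta, collapse = ", ")),
          class = "cecmr_validation_error")
  }
  if ("pvalue" %in% names(data)) {
    idx <- which(!is.na(data$pvalue))
    if (length(idx) > 0) {
      bad_p <- idx[data$pvalue[idx] <= 0 | data$pvalue[idx] > 1]
      if (length(bad_p) > 0) {
        abort(paste0(context, ": pvalue outside (0,1] in row(s) ",
                     paste(bad_p, collapse = ", ")),
              class = "cecmr_validation_error")
      }
      p_norm <- 2 * pnorm(-abs(data$beta[idx] / data$se[idx]))
      # consistent when the difference is within printing precision or a
      # factor of two on the log scale (tables print few significant digits)
      off <- abs(data$pvalue[idx] - p_norm) > 5e-4 &
             abs(log(data$pvalue[idx] / p_norm)) > log(2)
      if (any(off)) {
        warn(paste0(context, ": reported pvalue inconsistent with beta/se ",
                    "in row(s) ", paste(idx[off], collapse = ", ")))
      }
    }
  }
  out <- dplyr::select(data, dplyr::any_of(c(
    "snp", "effect_allele", "other_allele", "eaf", "beta", "se",
    "pvalue", "trait")), dplyr::everything())
  out
}

#' Write a summary-statistic table to TSV
#'
#' Round-trip companion to [read_summary_table()]: `read_summary_table()`
#' of a written file returns the written tibble.
#'
#' @param data A summary-association tibble.
#' @param path Output file path.
#' @return `data`, invisibly.
#' @export
write_summary_table <- function(data, path) {
  readr::write_tsv(as_tibble(data), path, progress = FALSE)
  invisible(data)
}
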