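METHOD_FUNS <- c("wald", "ivw", "egger", "simple_median", "weighted_median")

#' Run the full two-sample MR analysis across outcomes and methods
#'
#' Orchestrates the complete pipeline over an exposure instrument and a
#' set of outcomes: harmonization, every requested estimator, per-outcome
#' Cochran Q / I-squared (for multi-SNP instruments), and pairwise
#' between-outcome heterogeneity of the primary causal estimates.
#' Estimates are flagged significant at the Bonferroni-corrected
#' threshold p < 0.05/6 = 0.0083 for the six outcomes analysed.
#'
#' @param exposure A summary-association tibble, or a fixture instrument
#'   name: `"cec_5snp"` (the five-locus instrument) or `"cec_1snp"`
#'   (rs141622900).
#' @param outcomes Named list of summary-association tibbles, or a
#'   character vector of fixture trait names (`"CAD"`, `"MI"`, `"IS"`,
#'   `"LAS"`, `"SVS"`, `"CES"`).
#' @param methods Subset of `"wald"`, `"ivw"`, `"egger"`,
#'   `"simple_median"`, `"weighted_median"`. `"wald"` needs a single-SNP
#'   instrument; the others at their own minima.
#' @param variance_model Variance model passed to [mr_ivw()].
#' @param n_boot Bootstrap replicates for median SEs.
#' @param seed Seed for the bootstrap; required for reproducible median
#'   SEs.
#' @param palindromic_eaf_window Passed to [harmonize()].
#' @return An object of class `mr_report`: list with tibbles `estimates`
#'   (one row per outcome x method, including Egger intercepts and
#'   `significant` flags), `heterogeneity` (per outcome), `comparisons`
#'   (pairwise between-outcome Q/I-squared), and the call `options`.
#' @export
#' @examples
#' rep <- mr_run_analysis("cec_5snp", c("CAD", "IS"),
#'                        methods = c("ivw", "egger"), seed = 1)
#' rep$estimates
mr_run_analysis <- function(exposure,
                            outcomes,
                            methods = c("ivw", "egger", "simple_median",
                                        "weighted_median"),
                            variance_model = c("fixed", "multiplicative"),
                            n_boot = 1000,
                            seed = NULL,
                            palindromic_eaf_window = 0.08) {
  variance_model <- match.arg(variance_model)
  if (length(methods) == 0) {
    abort("mr_run_analysis: empty methods set", class = "cecmr_usage_error")
  }
  bad <- setdiff(methods, METHOD_FUNS)
  if (length(bad) > 0) {
    abort(paste0("unknown method(s): ", paste(bad, collapse = ", "),
                 "; available: ", paste(METHOD_FUNS, collapse = ", ")),
          class = "cecmr_usage_error")
  }
  fx <- NULL
  if (is.character(exposure)) {
    fx <- mr_fixtures()
    exposure <- switch(exposure,
      cec_5snp = dplyr::filter(fx$associations$CEC,
                               .data$snp %in% FIVE_SNP_INSTRUMENT),
      cec_1snp = dplyr::filter(fx$associations$CEC,
                               .data$snp %in% ONE_SNP_INSTRUMENT),
      abort(paste0("unknown exposure fixture: ", exposure,
                   " (use cec_5snp or cec_1snp)"),
            class = "cecmr_usage_error"))
  }
  if (is.character(outcomes)) {
    if (is.null(fx)) fx <- mr_fixtures()
    known <- setdiff(names(fx$associations), "CEC")
    bad <- setdiff(outcomes, known)
    if (length(bad) > 0) {
      abort(paste0("unknown outcome fixture(s): ", paste(bad, collapse = ", ")),
            class = "cecmr_usage_error")
    }
    outcomes <- fx$associations[outcomes]
  }
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    abort("outcomes must be named", class = "cecmr_usage_error")
  }

  estimates <- list()
  het <- list()
  primary <- list()
  for (out_name in names(outcomes)) {
    dat <- harmonize(exposure, outcomes[[out_name]],
                     palindromic_eaf_window = palindromic_eaf_window)
    rows <- purrr::map(methods, function(mth) {
      res <- withCallingHandlers(
        run_method(mth, dat, variance_model, n_boot, seed),
        error = function(e) {
          abort(paste0("method ", mth, " failed for outcome ", out_name,
                       ": ", conditionMessage(e)),
                class = "cecmr_pipeline_error", parent = e)
        })
      res
    })
    estimates[[out_name]] <- dplyr::bind_cols(outcome = out_name,
                                              dplyr::bind_rows(rows))
    if (nrow(dat) >= 2) {
      q <- cochran_q(dat)
      het[[out_name]] <- dplyr::bind_cols(outcome = out_name, glance(q))
    }
    # primary causal estimate per outcome: IVW for multi-SNP instruments,
    # Wald ratio for single-SNP; used for between-outcome comparisons
    primary[[out_name]] <- if (nrow(dat) == 1) {
      tidy(mr_wald_ratio(dat))
    } else {
      tidy(mr_ivw(dat, variance_model = "fixed"))
    }
  }
  estimates <- dplyr::bind_rows(estimates)
  estimates$significant <- !is.na(estimates$p.value) &
    estimates$p.value < BONFERRONI_P &
    estimates$term != "egger_intercept"

  comparisons <- NULL
  if (length(primary) >= 2) {
    pairs <- utils::combn(names(primary), 2, simplify = FALSE)
    comparisons <- purrr::map_dfr(pairs, function(pr) {
      cmp <- compare_estimates(tibble(
        label = pr,
        theta = c(primary[[pr[1]]]$estimate, primary[[pr[2]]]$estimate),
        se = c(primary[[pr[1]]]$std.error, primary[[pr[2]]]$std.error)))
      dplyr::bind_cols(outcome_a = pr[1], outcome_b = pr[2], glance(cmp))
    })
  }

  structure(list(
    estimates = estimates,
    heterogeneity = if (length(het) > 0) dplyr::bind_rows(het) else NULL,
    comparisons = comparisons,
    options = list(methods = methods, variance_model = variance_model,
                   n_boot = n_boot, seed = seed,
                   bonferroni_p = BONFERRONI_P)
  ), class = "mr_report")
}

run_method <- function(method, dat, variance_model, n_boot, seed) {
  switch(method,
    wald = dplyr::bind_cols(term = "estimate", tidy(mr_wald_ratio(dat))),
    ivw = dplyr::bind_cols(term = "estimate",
                           tidy(mr_ivw(dat, variance_model = variance_model))),
    egger = {
      td <- tidy(mr_egger(dat))
      td$term <- c("estimate", "egger_intercept")
      dplyr::bind_cols(method = "egger", td)
    },
    simple_median = dplyr::bind_cols(
      term = "estimate", tidy(mr_simple_median(dat, n_boot = n_boot,
                                               seed = seed))),
    weighted_median = dplyr::bind_cols(
      term = "estimate", tidy(mr_weighted_median(dat, n_boot = n_boot,
                                                 seed = seed)))
  )
}

#' Write an analysis report to disk
#'
#' TSV and markdown render with the print conventions used throughout
#' the package's reports (ORs to 2 decimals, Egger intercepts to 3, Q to
#' 1 decimal, I-squared as integer percent); JSON carries full precision
#' and round-trips exactly.
#'
#' @param report An `mr_report` from [mr_run_analysis()].
#' @param path Output file path.
#' @param format `"tsv"`, `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
mr_write_report <- function(report, path, format = c("tsv", "json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "mr_report"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(paste0("cannot write report: no such directory ", dir),
          class = "cecmr_io_error")
  }
  switch(format,
    tsv = readr::write_tsv(report$estimates, path, progress = FALSE),
    json = jsonlite::write_json(
      list(estimates = report$estimates,
           heterogeneity = report$heterogeneity,
           comparisons = report$comparisons),
      path, digits = NA, na = "null", auto_unbox = TRUE),
    markdown = writeLines(render_markdown(report), path)
  )
  invisible(path)
}

render_markdown <- function(report) {
  est <- report$estimates
  fmt_or <- function(or, lo, hi) {
    ifelse(is.na(or), "", sprintf("%.2f (%.2f-%.2f)", or, lo, hi))
  }
  lines <- c("# Two-sample MR report", "",
             "## Causal estimates (OR per 1-SD higher exposure)", "",
             "| Outcome | Method | OR (95% CI) | p | Significant |",
             "|---|---|---|---|---|")
  for (i in seq_len(nrow(est))) {
    r <- est[i, ]
    cell <- if (identical(r$term, "egger_intercept")) {
      sprintf("intercept %.3f (%.3f, %.3f)", r$estimate, r$conf.low,
              r$conf.high)
    } else {
      fmt_or(r$odds_ratio, r$or_conf_low, r$or_conf_high)
    }
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s |", r$outcome,
                              if (identical(r$term, "egger_intercept"))
                                "egger (intercept)" else r$method,
                              cell, format_p(r$p.value),
                              ifelse(r$significant, "yes", "no")))
  }
  if (!is.null(report$heterogeneity)) {
    h <- report$heterogeneity
    lines <- c(lines, "", "## Instrument heterogeneity", "",
               "| Outcome | Q | df | p | I2 |", "|---|---|---|---|---|",
               sprintf("| %s | %.1f | %d | %s | %d%% |", h$outcome, h$Q,
                       h$df, format_p(h$p.value), round(100 * h$i_squared)))
  }
  if (!is.null(report$comparisons)) {
    cmp <- report$comparisons
    lines <- c(lines, "", "## Between-outcome heterogeneity", "",
               "| Outcomes | Q | p | I2 |", "|---|---|---|---|",
               sprintf("| %s vs %s | %.1f | %s | %d%% |", cmp$outcome_a,
                       cmp$outcome_b, cmp$Q, format_p(cmp$p.value),
                       round(100 * cmp$i_squared)))
  }
  lines
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Two-sample MR report:", nrow(x$estimates), "estimate rows across",
      length(unique(x$estimates$outcome)), "outcome(s)\n")
  print(x$estimates, ...)
  invisible(x)
}
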