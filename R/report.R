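#' Bonferroni per-test threshold
#'
#' Divides the family-wise error level across `m` tests: with six exposure
#' traits at alpha = 0.05 the per-test bar is 0.05/6 = 8.33e-3.
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return The per-test threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / m
}

#' Assemble a study report
#'
#' Builds the result table of a univariable-plus-multivariable MR study:
#' one row per exposure x method carrying the instrument count, OR with
#' 95% CI and p-value, Cochran's Q with its p, and (for the Egger rows)
#' the intercept and its p. Exposures whose primary (IVW) p-value falls
#' below the Bonferroni threshold are flagged as significant.
#'
#' @param bundles Named list (one element per exposure); each element a
#'   list with components `ivw` (output of [mr_ivw()]), and optionally
#'   `egger` ([mr_egger()]), `wmedian` ([mr_weighted_median()]),
#'   `selection` (a selection report).
#' @param threshold Per-test significance threshold (e.g. from
#'   [bonferroni_threshold()]).
#' @param mvmr Optional [mvmr_ivw()] result.
#' @return A `study_report`: `table` (data frame), `bonferroni_threshold`,
#'   `significant_exposures`, `mvmr`, `selection` (per-exposure reports).
#' @export
assemble_table <- function(bundles, threshold, mvmr = NULL) {
  if (length(bundles) == 0L) stop("need at least one exposure bundle")
  if (is.null(names(bundles)) || any(!nzchar(names(bundles))))
    stop("bundles must be a named list (one name per exposure)")
  row_of <- function(exposure, est, q = NULL, intercept = NA_real_,
                     intercept_p = NA_real_) {
    data.frame(exposure = exposure, method = est$method, n_snp = est$n_snp,
               or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
               pval = est$pval,
               q = if (is.null(q)) NA_real_ else q$q,
               q_pval = if (is.null(q)) NA_real_ else q$pval,
               egger_intercept = intercept,
               egger_intercept_pval = intercept_p,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  sig <- character()
  for (exposure in names(bundles)) {
    b <- bundles[[exposure]]
    if (is.null(b$ivw)) stop("bundle for '", exposure, "' lacks an IVW result")
    rows[[length(rows) + 1L]] <-
      row_of(exposure, b$ivw$estimate, b$ivw$heterogeneity)
    if (b$ivw$estimate$pval < threshold) sig <- c(sig, exposure)
    if (!is.null(b$egger))
      rows[[length(rows) + 1L]] <-
        row_of(exposure, b$egger$slope, b$egger$q,
               b$egger$intercept, b$egger$intercept_pval)
    if (!is.null(b$wmedian))
      rows[[length(rows) + 1L]] <- row_of(exposure, b$wmedian)
  }
  structure(list(table = do.call(rbind, rows),
                 bonferroni_threshold = threshold,
                 significant_exposures = sig,
                 mvmr = mvmr,
                 selection = lapply(bundles, function(b) b$selection)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("MR study report (Bonferroni threshold ",
      format(x$bonferroni_threshold, digits = 3), ")\n", sep = "")
  print(format_report_table(x$table), row.names = FALSE)
  cat("Significant exposures:",
      if (length(x$significant_exposures)) paste(x$significant_exposures,
                                                 collapse = ", ")
      else "none", "\n")
  if (!is.null(x$mvmr)) print(x$mvmr)
  invisible(x)
}

# Table-1-style formatting: OR/CI to 3 decimals, p in scientific notation
# below 1e-3.
format_report_table <- function(tab) {
  fmt_p <- function(p) ifelse(is.na(p), "",
                              ifelse(p < 1e-3, sprintf("%.2e", p),
                                     sprintf("%.3f", p)))
  data.frame(exposure = tab$exposure, method = tab$method,
             n_snp = tab$n_snp,
             or = sprintf("%.3f", tab$or),
             ci = sprintf("%.3f-%.3f", tab$ci_low, tab$ci_high),
             pval = fmt_p(tab$pval),
             q = ifelse(is.na(tab$q), "", sprintf("%.2f", tab$q)),
             q_pval = fmt_p(tab$q_pval),
             egger_intercept = ifelse(is.na(tab$egger_intercept), "",
                                      sprintf("%.6f", tab$egger_intercept)),
             intercept_pval = fmt_p(tab$egger_intercept_pval),
             stringsAsFactors = FALSE)
}

#' Write a study report
#'
#' Serializes the formatted result table as tab-delimited text and/or the
#' full report as JSON. A JSON report read back with [read_report_json()]
#' reproduces the numeric table exactly.
#'
#' @param report A `study_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "study_report"))
  if (!is.null(tsv_path))
    utils::write.table(format_report_table(report$table), tsv_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- list(table = report$table,
                    bonferroni_threshold = report$bonferroni_threshold,
                    significant_exposures = report$significant_exposures,
                    mvmr = if (!is.null(report$mvmr))
                      list(estimates = report$mvmr$estimates,
                           q_a = report$mvmr$q_a,
                           dispersion = report$mvmr$dispersion,
                           n_snp = report$mvmr$n_snp))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(report)
}

#' Read a study report back from JSON
#'
#' @param json_path Path written by [write_report()].
#' @return A `study_report` (without per-exposure selection reports).
#' @export
read_report_json <- function(json_path) {
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  mv <- NULL
  if (!is.null(payload$mvmr)) {
    mv <- structure(list(estimates = as.data.frame(payload$mvmr$estimates),
                         q_a = payload$mvmr$q_a,
                         dispersion = payload$mvmr$dispersion,
                         n_snp = payload$mvmr$n_snp),
                    class = "mvmr_estimate")
  }
  structure(list(table = as.data.frame(payload$table),
                 bonferroni_threshold = payload$bonferroni_threshold,
                 significant_exposures =
                   as.character(unlist(payload$significant_exposures)),
                 mvmr = mv, selection = NULL),
            class = "study_report")
}
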