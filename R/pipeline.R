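#' Univariable MR analysis for one exposure
#'
#' Composes the module operations for a single exposure: instrument
#' selection (significance filter, LD clumping, confounder exclusion,
#' palindrome removal), harmonization against the outcome, then the
#' requested estimators and sensitivity analyses. Pure glue: every number
#' comes from the underlying module functions.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param ld An `ld_matrix` or `NULL`.
#' @param config A [selection_config()].
#' @param methods Character subset of `c("ivw", "egger", "wmedian")`.
#' @param ivw_model `"random"` or `"fixed"`.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param presso_n_sim MR-PRESSO simulations; `0` disables PRESSO.
#' @param leave_one_out Run the leave-one-out analysis?
#' @param seed Integer seed for all stochastic components.
#' @return List with `selection`, `harmonized`, `ivw`, `egger`,
#'   `wmedian`, `presso`, `loo` (absent components `NULL`).
#' @export
mr_univariable <- function(exposure, outcome, ld = NULL,
                           config = selection_config(),
                           methods = c("ivw", "egger", "wmedian"),
                           ivw_model = "random", n_boot = 1000,
                           presso_n_sim = 1000, leave_one_out = TRUE,
                           seed = 1L) {
  sel <- select_instruments(exposure, ld, config)
  hset <- harmonize(sel$stats, outcome, drop_palindromes = TRUE)
  J <- nrow(hset$rows)
  out <- list(selection = sel$report, harmonized = hset,
              ivw = NULL, egger = NULL, wmedian = NULL,
              presso = NULL, loo = NULL)
  if ("ivw" %in% methods) out$ivw <- mr_ivw(hset, ivw_model)
  if ("egger" %in% methods && J >= 3L) out$egger <- mr_egger(hset)
  if ("wmedian" %in% methods && J >= 3L)
    out$wmedian <- mr_weighted_median(hset, n_boot = n_boot, seed = seed)
  if (presso_n_sim > 0 && J >= 4L)
    out$presso <- mr_presso(hset, n_sim = presso_n_sim, seed = seed + 1L)
  if (leave_one_out && J >= 3L) out$loo <- mr_leave_one_out(hset)
  out
}

#' Run the full config-driven study pipeline
#'
#' Reproduces the complete study design from a single configuration: for
#' each exposure — instrument selection, harmonization, IVW / MR-Egger /
#' weighted median, Cochran's Q, MR-PRESSO, leave-one-out; then a
#' multivariable MR over all exposures (when at least two are given); then
#' a Bonferroni-corrected report with m = number of exposures. A stage
#' failure aborts with the stage name and offending exposure.
#'
#' The configuration is a YAML file or an equivalent nested list with
#' sections:
#' \describe{
#'   \item{inputs}{`exposures` (named list or vector of TSV paths),
#'     `outcome` (path), optional `ld` (path).}
#'   \item{selection}{fields of [selection_config()]; optional
#'     `exclusion_file` with one SNP id per line.}
#'   \item{methods}{`estimators` (subset of ivw/egger/wmedian),
#'     `ivw_model`, `n_boot`, `leave_one_out`.}
#'   \item{presso}{`n_sim` (0 disables).}
#'   \item{mvmr}{`enabled` (default TRUE when >= 2 exposures).}
#'   \item{report}{`alpha` (default 0.05).}
#'   \item{seeds}{`master` (integer).}
#' }
#'
#' @param config Path to a YAML file, or a list with the sections above.
#' @param out_dir Optional artifact directory; when given, the report
#'   (TSV + JSON) and a run manifest (seeds, stage counts, input file
#'   hashes) are written there.
#' @return A `study_report`; `attr(, "bundles")` carries the per-exposure
#'   results and `attr(, "manifest")` the run manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$inputs))
  seed <- as.integer(config$seeds$master %||% 1L)
  sel_cfg <- config$selection %||% list()
  exclusion_ids <- character()
  if (!is.null(sel_cfg$exclusion_file))
    exclusion_ids <- readLines(sel_cfg$exclusion_file)
  scfg <- selection_config(
    p_threshold = sel_cfg$p_threshold %||% 5e-8,
    r2_threshold = sel_cfg$r2_threshold %||% 0.01,
    window_kb = sel_cfg$window_kb %||% 10000,
    exclusion_ids = c(exclusion_ids, unlist(sel_cfg$exclusion_ids)),
    f_min = sel_cfg$f_min %||% 10)
  mcfg <- config$methods %||% list()
  methods <- unlist(mcfg$estimators) %||% c("ivw", "egger", "wmedian")
  presso_n_sim <- config$presso$n_sim %||% 1000
  alpha <- config$report$alpha %||% 0.05

  load_stats <- function(x, label) {
    if (inherits(x, "summary_stats")) x
    else read_summary_stats(x, trait_name = label)
  }
  exp_in <- config$inputs$exposures
  if (is.null(names(exp_in)))
    names(exp_in) <- if (is.character(exp_in))
      vapply(exp_in, function(p) sub("\\.[^.]*$", "", basename(p)), "")
    else paste0("exposure_", seq_along(exp_in))
  exposures <- lapply(seq_along(exp_in),
                      function(i) load_stats(exp_in[[i]], names(exp_in)[i]))
  names(exposures) <- names(exp_in)
  outcome <- load_stats(config$inputs$outcome, "outcome")
  ld <- if (!is.null(config$inputs$ld)) {
    if (inherits(config$inputs$ld, "ld_matrix")) config$inputs$ld
    else read_ld_matrix(config$inputs$ld)
  }

  bundles <- list()
  for (i in seq_along(exposures)) {
    nm <- names(exposures)[i]
    bundles[[nm]] <- tryCatch(
      mr_univariable(exposures[[i]], outcome, ld, scfg,
                     methods = methods,
                     ivw_model = mcfg$ivw_model %||% "random",
                     n_boot = mcfg$n_boot %||% 1000,
                     presso_n_sim = presso_n_sim,
                     leave_one_out = isTRUE(mcfg$leave_one_out %||% TRUE),
                     seed = seed + i),
      error = function(e) stop("univariable stage failed for exposure '",
                               nm, "': ", conditionMessage(e), call. = FALSE))
  }
  mv <- NULL
  mv_enabled <- config$mvmr$enabled %||% (length(exposures) >= 2)
  if (isTRUE(mv_enabled) && length(exposures) >= 2) {
    mv <- tryCatch({
      mvset <- build_mvmr_set(unname(exposures), outcome, scfg, ld)
      est <- mvmr_ivw(mvset)
      est$conditional_f <- conditional_f(mvset)
      est
    }, error = function(e) stop("MVMR stage failed: ",
                                conditionMessage(e), call. = FALSE))
  }
  thr <- bonferroni_threshold(alpha, length(exposures))
  report <- assemble_table(bundles, thr, mvmr = mv)
  manifest <- list(
    seed = seed, alpha = alpha, bonferroni_threshold = thr,
    n_exposures = length(exposures),
    methods = methods, presso_n_sim = presso_n_sim,
    selection = scfg[c("p_threshold", "r2_threshold", "window_kb", "f_min")],
    selection_counts = lapply(bundles, function(b)
      b$selection[c("n_input", "n_after_p", "n_after_clump",
                    "n_after_exclusion", "n_after_palindrome", "mean_f")]),
    inputs = if (all(vapply(exp_in, is.character, logical(1))))
      lapply(c(as.list(exp_in), list(outcome = config$inputs$outcome)),
             function(p) if (is.character(p))
               list(path = p, md5 = unname(tools::md5sum(p))) else NULL))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, tsv_path = file.path(out_dir, "report.tsv"),
                 json_path = file.path(out_dir, "report.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  attr(report, "bundles") <- bundles
  attr(report, "manifest") <- manifest
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
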