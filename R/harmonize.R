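COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_alleles <- function(x) unname(COMPLEMENT[toupper(x)])

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the two files onto a common effect allele per SNP, matching on
#' SNP id. For each shared SNP: identical allele pairs are copied; swapped
#' pairs (outcome effect allele equals exposure other allele and vice
#' versa) have the outcome beta negated and the outcome frequency reflected
#' (`1 - eaf`); pairs that match only after complementing the outcome
#' alleles (A<->T, C<->G) are strand-corrected and then aligned or swapped;
#' anything else is dropped as an allele mismatch. Palindromic SNPs (A/T,
#' C/G) cannot be strand-resolved from alleles and are dropped when
#' `drop_palindromes = TRUE` (the default, matching the analysis design
#' this package implements). Every shared SNP is assigned to exactly one
#' audit category.
#'
#' For non-palindromic SNPs with both frequencies present, an absolute
#' aligned-frequency discordance above `eaf_warn` emits a warning (data
#' quality signal only; the SNP is kept).
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param drop_palindromes Drop palindromic SNPs? Default `TRUE`.
#' @param eaf_warn Frequency-discordance warning threshold. Default `0.2`.
#' @return A `harmonized_set`: `exposure_name`, `outcome_name`, `rows`
#'   (data frame `snp_id beta_x se_x beta_y se_y eaf_x eaf_y`), and
#'   `audit` (named integer counts: `aligned`, `sign_flipped`,
#'   `strand_flipped`, `palindromic_dropped`, `allele_mismatch_dropped`,
#'   `missing_in_outcome`).
#' @export
harmonize <- function(exposure, outcome, drop_palindromes = TRUE,
                      eaf_warn = 0.2) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  ex <- exposure$records
  oy <- outcome$records[match(ex$snp_id, outcome$records$snp_id), , drop = FALSE]
  shared <- !is.na(oy$snp_id)
  audit <- c(aligned = 0L, sign_flipped = 0L, strand_flipped = 0L,
             palindromic_dropped = 0L, allele_mismatch_dropped = 0L,
             missing_in_outcome = sum(!shared))
  if (!any(shared))
    stop("no shared instruments between '", exposure$trait_name, "' and '",
         outcome$trait_name, "'")
  ex <- ex[shared, , drop = FALSE]
  oy <- oy[shared, , drop = FALSE]

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  n <- nrow(ex)
  flip_sign <- logical(n)     # negate outcome beta, reflect eaf
  keep <- logical(n)
  category <- character(n)

  o_ea <- oy$effect_allele; o_oa <- oy$other_allele
  o_ea_c <- complement_alleles(o_ea); o_oa_c <- complement_alleles(o_oa)
  same  <- o_ea == ex$effect_allele & o_oa == ex$other_allele
  swap  <- o_ea == ex$other_allele & o_oa == ex$effect_allele
  csame <- o_ea_c == ex$effect_allele & o_oa_c == ex$other_allele
  cswap <- o_ea_c == ex$other_allele & o_oa_c == ex$effect_allele

  for (i in seq_len(n)) {
    if (pal[i] && drop_palindromes) {
      category[i] <- "palindromic_dropped"
    } else if (same[i]) {
      keep[i] <- TRUE; category[i] <- "aligned"
    } else if (swap[i]) {
      keep[i] <- TRUE; flip_sign[i] <- TRUE; category[i] <- "sign_flipped"
    } else if (csame[i] || cswap[i]) {
      keep[i] <- TRUE; flip_sign[i] <- cswap[i]; category[i] <- "strand_flipped"
    } else {
      category[i] <- "allele_mismatch_dropped"
    }
  }
  tab <- table(factor(category, levels = names(audit)))
  audit[names(tab)] <- audit[names(tab)] + as.integer(tab)

  beta_y <- ifelse(flip_sign, -oy$beta, oy$beta)
  eaf_y <- ifelse(flip_sign, 1 - oy$eaf, oy$eaf)
  rows <- data.frame(snp_id = ex$snp_id, beta_x = ex$beta, se_x = ex$se,
                     beta_y = beta_y, se_y = oy$se,
                     eaf_x = ex$eaf, eaf_y = eaf_y,
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(rows) <- NULL
  disc <- !pal[keep] & !is.na(rows$eaf_x) & !is.na(rows$eaf_y) &
    abs(rows$eaf_x - rows$eaf_y) > eaf_warn
  if (any(disc))
    warning(sum(disc), " SNP(s) with aligned allele-frequency discordance > ",
            eaf_warn, ": ", paste(rows$snp_id[disc], collapse = ", "))
  harmonized_set(exposure$trait_name, outcome$trait_name, rows, audit)
}

#' Construct a harmonized instrument set
#'
#' Container for aligned exposure/outcome effect pairs ready for
#' estimation; see [harmonize()].
#'
#' @param exposure_name,outcome_name Trait labels.
#' @param rows Data frame with columns `snp_id beta_x se_x beta_y se_y`
#'   (optionally `eaf_x eaf_y`).
#' @param audit Named integer vector of harmonization counts.
#' @return A `harmonized_set` object.
#' @export
harmonized_set <- function(exposure_name, outcome_name, rows,
                           audit = c(aligned = nrow(rows), sign_flipped = 0L,
                                     strand_flipped = 0L,
                                     palindromic_dropped = 0L,
                                     allele_mismatch_dropped = 0L,
                                     missing_in_outcome = 0L)) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  needed <- c("snp_id", "beta_x", "se_x", "beta_y", "se_y")
  if (!all(needed %in% names(rows)))
    stop("harmonized rows need columns: ", paste(needed, collapse = ", "))
  if (!"eaf_x" %in% names(rows)) rows$eaf_x <- NA_real_
  if (!"eaf_y" %in% names(rows)) rows$eaf_y <- NA_real_
  if (anyDuplicated(rows$snp_id)) stop("duplicate snp_id in harmonized rows")
  if (nrow(rows) > 0L && (any(rows$se_x <= 0) || any(rows$se_y <= 0)))
    stop("harmonized rows require positive standard errors")
  rownames(rows) <- NULL
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 rows = rows, audit = audit),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set: ", x$exposure_name, " -> ", x$outcome_name, "\n",
      "  ", nrow(x$rows), " instruments\n", sep = "")
  cat("  audit:", paste(names(x$audit), x$audit, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
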