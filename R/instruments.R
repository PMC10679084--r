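#' Instrument-selection configuration
#'
#' Bundles the thresholds governing instrument selection: the genome-wide
#' significance cutoff, the LD-clumping r^2 cutoff and physical window, an
#' optional set of confounder-associated SNP ids to exclude, and the minimum
#' acceptable mean F statistic.
#'
#' @param p_threshold Significance cutoff; records with `pval < p_threshold`
#'   are retained (strict inequality). Default `5e-8`.
#' @param r2_threshold Clumping cutoff: a SNP within the window whose r^2
#'   with the index SNP is `>= r2_threshold` is discarded. Default `0.01`.
#' @param window_kb Clumping window in kilobases. Default `10000`.
#' @param exclusion_ids Character vector of SNP ids associated with
#'   confounders, to be removed.
#' @param f_min Weak-instrument bar on the mean F statistic. Default `10`.
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_threshold = 5e-8, r2_threshold = 0.01,
                             window_kb = 10000, exclusion_ids = character(),
                             f_min = 10) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_threshold >= 0, r2_threshold <= 1,
            window_kb > 0, f_min >= 0)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb,
                 exclusion_ids = as.character(exclusion_ids),
                 f_min = f_min),
            class = "selection_config")
}

#' Genome-wide significance filter
#'
#' Keeps exactly the records with `pval < p_threshold` (strict), preserving
#' input order.
#'
#' @param stats A `summary_stats` object.
#' @param p_threshold Significance cutoff.
#' @return A filtered `summary_stats` object.
#' @export
filter_significant <- function(stats, p_threshold = 5e-8) {
  stopifnot(inherits(stats, "summary_stats"), p_threshold > 0, p_threshold < 1)
  summary_stats(stats$trait_name,
                stats$records[stats$records$pval < p_threshold, , drop = FALSE])
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unassigned SNP with the lowest p-value as an index
#' SNP and discards all unassigned SNPs on the same chromosome within
#' `window_kb` kilobases whose r^2 with the index is `>= r2_threshold`.
#' Ties on p-value are broken by chromosome, position, then SNP id, so the
#' selected set is invariant to input row order. SNPs absent from the LD
#' matrix are treated as unlinked (r^2 = 0). The returned set contains no
#' same-chromosome pair within the window at or above the cutoff.
#'
#' @param stats A `summary_stats` object.
#' @param ld An `ld_matrix`, or `NULL` for all-independent SNPs.
#' @param r2_threshold Clumping r^2 cutoff in \[0, 1\].
#' @param window_kb Window in kilobases; must be positive.
#' @return A `summary_stats` object holding the index SNPs, in original
#'   input order.
#' @export
clump <- function(stats, ld = NULL, r2_threshold = 0.01, window_kb = 10000) {
  stopifnot(inherits(stats, "summary_stats"))
  if (window_kb <= 0) stop("clumping window must be positive")
  if (r2_threshold < 0 || r2_threshold > 1)
    stop("r2_threshold must lie in [0, 1]")
  rec <- stats$records
  if (nrow(rec) <= 1L) return(stats)
  ord <- order(rec$pval, rec$chrom, rec$pos, rec$snp_id)
  window_bp <- window_kb * 1000
  state <- rep.int(0L, nrow(rec))  # 0 unassigned, 1 index, -1 discarded
  for (i in ord) {
    if (state[i] != 0L) next
    state[i] <- 1L
    cand <- which(state == 0L & rec$chrom == rec$chrom[i] &
                    abs(rec$pos - rec$pos[i]) <= window_bp)
    if (length(cand) > 0L) {
      r2 <- ld_r2(ld, rec$snp_id[i], rec$snp_id[cand])
      state[cand[r2 >= r2_threshold]] <- -1L
    }
  }
  summary_stats(stats$trait_name, rec[state == 1L, , drop = FALSE])
}

#' Remove confounder-associated SNPs
#'
#' Drops records whose id is in the exclusion set (e.g. SNPs flagged as
#' confounder-associated by an annotation screen); the removal count is
#' attached as attribute `"n_excluded"`.
#'
#' @param stats A `summary_stats` object.
#' @param exclusion_ids Character vector of SNP ids to remove.
#' @return A filtered `summary_stats` object.
#' @export
exclude_confounder_snps <- function(stats, exclusion_ids) {
  stopifnot(inherits(stats, "summary_stats"))
  drop <- stats$records$snp_id %in% exclusion_ids
  out <- summary_stats(stats$trait_name, stats$records[!drop, , drop = FALSE])
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Palindromic (ambiguous-strand) allele test
#'
#' A SNP is palindromic when its allele pair is \{A,T\} or \{C,G\}: the two
#' strands carry the same pair, so strand cannot be resolved from alleles
#' alone. Vectorized.
#'
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T).
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele); oa <- toupper(other_allele)
  if (any(!ea %in% BASES) || any(!oa %in% BASES))
    stop("alleles must be single bases A, C, G or T")
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Per-SNP F statistic
#'
#' Instrument strength of a single variant, `(beta/se)^2` — the squared
#' Wald z of the SNP-exposure association. Vectorized.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s); must be positive.
#' @return Numeric F statistic(s).
#' @export
per_snp_f <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

#' Mean F statistic with weak-instrument flag
#'
#' Arithmetic mean of the per-SNP F statistics over an instrument set; a
#' mean of at least `f_min` (conventionally 10) indicates the set is not
#' materially affected by weak-instrument bias.
#'
#' @param stats A non-empty `summary_stats` object.
#' @param f_min Weak-instrument bar. Default 10.
#' @return List with `mean_f`, logical `strong`, and named `per_snp_f`.
#' @export
mean_f <- function(stats, f_min = 10) {
  stopifnot(inherits(stats, "summary_stats"))
  if (nrow(stats$records) == 0L) stop("cannot compute mean F of an empty set")
  f <- per_snp_f(stats$records$beta, stats$records$se)
  names(f) <- stats$records$snp_id
  list(mean_f = mean(f), strong = mean(f) >= f_min, per_snp_f = f)
}

#' Full instrument-selection pipeline
#'
#' Applies, in order: significance filter, greedy LD clumping, confounder
#' exclusion, palindrome removal; then computes instrument-strength
#' statistics. Stage-by-stage counts are returned as a selection report.
#'
#' @param stats Exposure `summary_stats`.
#' @param ld An `ld_matrix` or `NULL`.
#' @param config A [selection_config()].
#' @return List with `stats` (the selected instruments) and `report`
#'   (`n_input`, `n_after_p`, `n_after_clump`, `n_after_exclusion`,
#'   `n_after_palindrome`, `mean_f`, `strong`, `per_snp_f`).
#' @export
select_instruments <- function(stats, ld = NULL, config = selection_config()) {
  stopifnot(inherits(stats, "summary_stats"),
            inherits(config, "selection_config"))
  n_input <- nrow(stats$records)
  s1 <- filter_significant(stats, config$p_threshold)
  s2 <- clump(s1, ld, config$r2_threshold, config$window_kb)
  s3 <- exclude_confounder_snps(s2, config$exclusion_ids)
  pal <- is_palindromic(s3$records$effect_allele, s3$records$other_allele)
  s4 <- summary_stats(s3$trait_name, s3$records[!pal, , drop = FALSE])
  fres <- if (nrow(s4$records) > 0L) mean_f(s4, config$f_min) else
    list(mean_f = NA_real_, strong = NA, per_snp_f = numeric())
  report <- list(n_input = n_input,
                 n_after_p = nrow(s1$records),
                 n_after_clump = nrow(s2$records),
                 n_after_exclusion = nrow(s3$records),
                 n_after_palindrome = nrow(s4$records),
                 mean_f = fres$mean_f, strong = fres$strong,
                 per_snp_f = fres$per_snp_f)
  list(stats = s4, report = report)
}
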