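#' Construct a multivariable MR input set
#'
#' Holds J instruments by K exposures: the J x K matrices of SNP-exposure
#' effects and standard errors, and the length-J outcome effects and
#' standard errors, all aligned to a common effect allele per SNP.
#'
#' @param exposure_names Length-K labels.
#' @param beta_x,se_x J x K numeric matrices.
#' @param beta_y,se_y Length-J numeric vectors.
#' @param snp_ids Length-J ids (unique).
#' @return An `mvmr_set` object.
#' @export
mvmr_set <- function(exposure_names, beta_x, se_x, beta_y, se_y, snp_ids) {
  beta_x <- as.matrix(beta_x); se_x <- as.matrix(se_x)
  J <- nrow(beta_x); K <- ncol(beta_x)
  stopifnot(length(exposure_names) == K, all(dim(se_x) == c(J, K)),
            length(beta_y) == J, length(se_y) == J, length(snp_ids) == J,
            !anyDuplicated(snp_ids))
  if (J <= K) stop("MVMR requires more instruments than exposures (J > K)")
  if (any(se_x <= 0) || any(se_y <= 0)) stop("all SEs must be positive")
  colnames(beta_x) <- colnames(se_x) <- exposure_names
  structure(list(exposure_names = exposure_names, beta_x = beta_x,
                 se_x = se_x, beta_y = as.numeric(beta_y),
                 se_y = as.numeric(se_y), snp_ids = as.character(snp_ids)),
            class = "mvmr_set")
}

#' Assemble an MVMR set from per-exposure summary statistics
#'
#' The instrument set is the union of SNPs genome-wide significant for any
#' exposure, jointly clumped: each SNP is scored by its minimum p-value
#' across exposures and the greedy clumping of [clump()] is applied to
#' that score. Confounder-listed SNPs and palindromes are removed. Every
#' retained SNP must have a record in every exposure file and in the
#' outcome file (full genome-wide files are expected, so off-target
#' effects are present even when near zero); SNPs missing anywhere are
#' dropped and counted. All files are harmonized to the first exposure's
#' allele orientation using the rules of [harmonize()].
#'
#' @param exposures List of at least two `summary_stats` objects.
#' @param outcome A `summary_stats` object.
#' @param config A [selection_config()].
#' @param ld An `ld_matrix` or `NULL`.
#' @return An `mvmr_set`; `attr(, "n_dropped_missing")` counts SNPs lost
#'   to missing records, `attr(, "n_dropped_mismatch")` to irreconcilable
#'   alleles.
#' @export
build_mvmr_set <- function(exposures, outcome, config = selection_config(),
                           ld = NULL) {
  if (length(exposures) < 2L) stop("MVMR needs at least two exposures")
  stopifnot(all(vapply(exposures, inherits, logical(1), "summary_stats")),
            inherits(outcome, "summary_stats"))
  K <- length(exposures)
  sig <- lapply(exposures, filter_significant, p_threshold = config$p_threshold)
  ids <- unique(unlist(lapply(sig, function(s) s$records$snp_id)))
  if (length(ids) == 0L) stop("no genome-wide-significant SNPs in any exposure")

  # joint clumping: score each union SNP by min p across exposures, take
  # coordinates from the first exposure that carries it
  min_p <- rep(Inf, length(ids))
  coord <- NULL
  for (ex in exposures) {
    m <- match(ids, ex$records$snp_id)
    p <- ex$records$pval[m]
    upd <- !is.na(p) & p < min_p
    min_p[upd] <- p[upd]
    if (is.null(coord)) coord <- ex$records[m, c("chrom", "pos",
                                                "effect_allele",
                                                "other_allele", "eaf",
                                                "beta", "se", "n")]
    else {
      fill <- is.na(coord$chrom) & !is.na(m)
      coord[fill, ] <- ex$records[m[fill], names(coord)]
    }
  }
  union_stats <- summary_stats("mvmr_union", data.frame(
    snp_id = ids, chrom = coord$chrom, pos = coord$pos,
    effect_allele = coord$effect_allele, other_allele = coord$other_allele,
    eaf = coord$eaf, beta = coord$beta, se = coord$se, pval = min_p,
    n = coord$n, stringsAsFactors = FALSE))
  clumped <- clump(union_stats, ld, config$r2_threshold, config$window_kb)
  clumped <- exclude_confounder_snps(clumped, config$exclusion_ids)
  pal <- is_palindromic(clumped$records$effect_allele,
                        clumped$records$other_allele)
  keep_ids <- clumped$records$snp_id[!pal]

  # harmonize every file to the reference orientation (first exposure),
  # requiring a record everywhere
  ref <- exposures[[1L]]$records
  ref <- ref[match(keep_ids, ref$snp_id), , drop = FALSE]
  present <- !is.na(ref$snp_id)
  n_missing <- sum(!present)
  ref <- ref[present, , drop = FALSE]
  ref_stats <- summary_stats("mvmr_reference", ref)

  aligned <- vector("list", K + 1L)
  sources <- c(exposures, list(outcome))
  ok <- rep(TRUE, nrow(ref))
  for (i in seq_along(sources)) {
    h <- suppressWarnings(harmonize(ref_stats, sources[[i]],
                                    drop_palindromes = TRUE))
    m <- match(ref$snp_id, h$rows$snp_id)
    aligned[[i]] <- h$rows[m, , drop = FALSE]
    ok <- ok & !is.na(m)
  }
  n_mismatch_or_missing <- sum(!ok)
  if (sum(ok) <= K)
    stop("too few complete MVMR instruments after harmonization (J <= K)")
  beta_x <- sapply(aligned[seq_len(K)], function(a) a$beta_y[ok])
  se_x <- sapply(aligned[seq_len(K)], function(a) a$se_y[ok])
  out_rows <- aligned[[K + 1L]]
  mv <- mvmr_set(vapply(exposures, function(e) e$trait_name, character(1)),
                 beta_x, se_x, out_rows$beta_y[ok], out_rows$se_y[ok],
                 ref$snp_id[ok])
  attr(mv, "n_dropped_missing") <- n_missing
  attr(mv, "n_dropped_mismatch") <- n_mismatch_or_missing
  mv
}

#' Multivariable IVW estimator
#'
#' Weighted least squares of the SNP-outcome effects on the K columns of
#' SNP-exposure effects, no intercept, weights `1/se_y^2`; each
#' coefficient is the direct effect of its exposure on the outcome holding
#' the other exposures fixed. Standard errors carry multiplicative
#' overdispersion `phi = max(1, sqrt(Q_A/(J-K)))`, where `Q_A` is the
#' weighted residual sum of squares on `J - K` df; p-values are two-sided
#' normal; odds ratios by exponentiation.
#'
#' @param mvset An `mvmr_set`.
#' @param level Confidence level. Default 0.95.
#' @return An `mvmr_estimate`: data frame `estimates` (per-exposure
#'   `exposure theta se or ci_low ci_high pval`), `q_a` (`q`, `df`,
#'   `pval`), `dispersion`, `n_snp`.
#' @export
mvmr_ivw <- function(mvset, level = 0.95) {
  stopifnot(inherits(mvset, "mvmr_set"))
  X <- mvset$beta_x; y <- mvset$beta_y
  J <- nrow(X); K <- ncol(X)
  w <- 1 / mvset$se_y^2
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < K) {
    dep <- setdiff(seq_len(K), qrX$pivot[seq_len(qrX$rank)])
    stop("rank-deficient MVMR design; collinear exposure(s): ",
         paste(mvset$exposure_names[dep], collapse = ", "))
  }
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * y)
  theta <- solve(XtWX, XtWy)[, 1L]
  resid <- y - X %*% theta
  q_a <- sum(w * resid^2)
  phi <- max(1, sqrt(q_a / (J - K)))
  se <- sqrt(diag(solve(XtWX))) * phi
  pval <- 2 * stats::pnorm(-abs(theta / se))
  ci <- or_ci(theta, se, level)
  est <- data.frame(exposure = mvset$exposure_names, theta = theta, se = se,
                    or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
                    pval = pval, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(estimates = est,
                 q_a = list(q = q_a, df = J - K,
                            pval = stats::pchisq(q_a, J - K,
                                                 lower.tail = FALSE)),
                 dispersion = phi, n_snp = J),
            class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat("Multivariable IVW (", x$n_snp, " SNPs):\n", sep = "")
  print(x$estimates, digits = 4)
  cat(sprintf("  Q_A = %.4g on %d df (p = %.3g)\n",
              x$q_a$q, x$q_a$df, x$q_a$pval))
  invisible(x)
}

#' Conditional instrument strength for MVMR
#'
#' For each exposure k, its SNP-effect column is regressed on the other
#' K - 1 columns (weights `1/se_xk^2`); the conditional F statistic is the
#' mean squared standardized residual, `mean((r_jk / se_xjk)^2)` — the
#' instrument signal for exposure k not explained by the other exposures.
#' Cross-exposure covariances of the effect estimates are taken as zero.
#' For an exposure whose instruments are independent of the others this
#' approaches the univariable mean F; perfectly collinear columns give 0.
#'
#' @param mvset An `mvmr_set` with K >= 2.
#' @return Named numeric vector of conditional F statistics (length K,
#'   all non-negative).
#' @export
conditional_f <- function(mvset) {
  stopifnot(inherits(mvset, "mvmr_set"))
  X <- mvset$beta_x; S <- mvset$se_x
  K <- ncol(X)
  if (K < 2L) stop("conditional F requires at least two exposures")
  out <- vapply(seq_len(K), function(k) {
    yk <- X[, k]; Z <- X[, -k, drop = FALSE]
    wk <- 1 / S[, k]^2
    fit <- stats::lm.wfit(Z, yk, wk)
    mean((fit$residuals / S[, k])^2)
  }, numeric(1))
  names(out) <- mvset$exposure_names
  out
}
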