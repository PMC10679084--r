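# Leave-one-out IVW slopes on the regression scale:
# theta_(-j) = (S_xy - w_j bx_j by_j) / (S_xx - w_j bx_j^2), w = 1/se_y^2.
loo_ivw_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

# One simulation pass for the PRESSO null: returns the J x n_sim matrix of
# weighted squared leave-one-out residuals of simulated data.
presso_sim_residuals <- function(bx, by, sex, sey, n_sim) {
  J <- length(bx)
  w <- 1 / sey^2
  theta_loo <- loo_ivw_slopes(bx, by, w)
  mu_y <- theta_loo * bx
  bx_star <- matrix(stats::rnorm(J * n_sim, mean = bx, sd = sex), nrow = J)
  by_star <- matrix(stats::rnorm(J * n_sim, mean = mu_y, sd = sey), nrow = J)
  sxy <- colSums(w * bx_star * by_star)
  sxx <- colSums(w * bx_star^2)
  theta_star <- (rep(sxy, each = J) - w * bx_star * by_star) /
    (rep(sxx, each = J) - w * bx_star^2)
  w * (by_star - theta_star * bx_star)^2
}

#' MR-PRESSO global heterogeneity test
#'
#' The observed residual sum of squares is
#' `RSS_obs = sum_j w_j (beta_yj - theta_(-j) beta_xj)^2`, with `theta_(-j)`
#' the IVW estimate excluding SNP j and weights `w_j = 1/se_yj^2`. Its null
#' distribution is obtained by simulation: effects are redrawn as
#' `beta_yj* ~ N(theta_(-j) beta_xj, se_yj^2)` and
#' `beta_xj* ~ N(beta_xj, se_xj^2)` and the statistic recomputed `n_sim`
#' times. The empirical p-value uses the plus-one estimator
#' `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`, so it is never zero.
#'
#' @param hset A `harmonized_set` with at least 4 instruments.
#' @param n_sim Simulations; default 1000.
#' @param seed Integer seed.
#' @return List with `rss_obs` and `global_pval`.
#' @export
presso_global <- function(hset, n_sim = 1000, seed) {
  r <- presso_check(hset)
  if (missing(seed)) stop("a simulation seed is required")
  w <- 1 / r$se_y^2
  theta_loo <- loo_ivw_slopes(r$beta_x, r$beta_y, w)
  rss_obs <- sum(w * (r$beta_y - theta_loo * r$beta_x)^2)
  res_star <- local_seed(seed, presso_sim_residuals(
    r$beta_x, r$beta_y, r$se_x, r$se_y, n_sim))
  rss_star <- colSums(res_star)
  list(rss_obs = rss_obs,
       global_pval = (1 + sum(rss_star >= rss_obs)) / (n_sim + 1))
}

#' MR-PRESSO per-SNP outlier test
#'
#' Compares each instrument's observed weighted squared leave-one-out
#' residual to the simulated distribution of the same quantity under the
#' null (see [presso_global()]); the empirical p uses the plus-one
#' estimator. A SNP is flagged as an outlier when its p-value falls below
#' `alpha / J` (Bonferroni across instruments).
#'
#' @inheritParams presso_global
#' @param alpha Family-wise outlier level before the Bonferroni division.
#'   Default 0.05.
#' @return List with `outlier_pvals` (named), `outliers` (flagged id set)
#'   and `threshold`.
#' @export
presso_outliers <- function(hset, n_sim = 1000, seed, alpha = 0.05) {
  r <- presso_check(hset)
  if (missing(seed)) stop("a simulation seed is required")
  J <- nrow(r)
  w <- 1 / r$se_y^2
  theta_loo <- loo_ivw_slopes(r$beta_x, r$beta_y, w)
  res_obs <- w * (r$beta_y - theta_loo * r$beta_x)^2
  res_star <- local_seed(seed, presso_sim_residuals(
    r$beta_x, r$beta_y, r$se_x, r$se_y, n_sim))
  pvals <- (1 + rowSums(res_star >= res_obs)) / (n_sim + 1)
  names(pvals) <- r$snp_id
  thr <- alpha / J
  list(outlier_pvals = pvals, outliers = r$snp_id[pvals < thr],
       threshold = thr)
}

#' MR-PRESSO distortion test
#'
#' Measures how much the flagged outliers distort the IVW estimate:
#' `d = (theta_raw - theta_corrected) / |theta_corrected|`, where
#' `theta_raw` is the IVW estimate on all instruments and
#' `theta_corrected` the IVW estimate with the outliers removed. Its null
#' reference is the same statistic under removal of equally many
#' instruments chosen at random; the two-sided empirical p-value uses the
#' plus-one estimator.
#'
#' @param hset A `harmonized_set`.
#' @param outliers Nonempty character vector of flagged ids, a strict
#'   subset of the instruments.
#' @param n_sim Random-removal draws; default 1000.
#' @param seed Integer seed.
#' @return List with `theta_raw`, `theta_corrected`, `distortion`,
#'   `distortion_pval`.
#' @export
presso_distortion <- function(hset, outliers, n_sim = 1000, seed) {
  stopifnot(inherits(hset, "harmonized_set"))
  if (missing(seed)) stop("a simulation seed is required")
  ids <- hset$rows$snp_id
  outliers <- intersect(outliers, ids)
  if (length(outliers) == 0L) stop("outlier set is empty")
  if (length(outliers) >= length(ids))
    stop("cannot remove every instrument")
  ivw_theta <- function(rows) {
    w <- 1 / rows$se_y^2
    sum(w * rows$beta_x * rows$beta_y) / sum(w * rows$beta_x^2)
  }
  theta_raw <- ivw_theta(hset$rows)
  keep <- !(ids %in% outliers)
  theta_corr <- ivw_theta(hset$rows[keep, , drop = FALSE])
  d_obs <- (theta_raw - theta_corr) / abs(theta_corr)
  k <- length(outliers)
  d_star <- local_seed(seed, vapply(seq_len(n_sim), function(b) {
    drop <- sample(length(ids), k)
    th <- ivw_theta(hset$rows[-drop, , drop = FALSE])
    (theta_raw - th) / abs(th)
  }, numeric(1)))
  list(theta_raw = theta_raw, theta_corrected = theta_corr,
       distortion = d_obs,
       distortion_pval = (1 + sum(abs(d_star) >= abs(d_obs))) / (n_sim + 1))
}

#' Run the full MR-PRESSO procedure
#'
#' Global residual-sum-of-squares test, per-SNP outlier test, and — when
#' outliers are flagged — the outlier-corrected random-effects IVW
#' estimate with the distortion test.
#'
#' @inheritParams presso_outliers
#' @return A `presso_result`: `rss_obs`, `global_pval`, `outlier_pvals`,
#'   `outliers`, `theta_raw`, and when outliers were flagged
#'   `theta_corrected` (an `mr_estimate`), `distortion`, `distortion_pval`;
#'   plus `n_sim` and `seed`.
#' @export
mr_presso <- function(hset, n_sim = 1000, seed, alpha = 0.05) {
  if (missing(seed)) stop("a simulation seed is required")
  glob <- presso_global(hset, n_sim, seed)
  outl <- presso_outliers(hset, n_sim, seed + 1L, alpha)
  raw <- mr_ivw(hset, "random")$estimate
  res <- list(rss_obs = glob$rss_obs, global_pval = glob$global_pval,
              outlier_pvals = outl$outlier_pvals, outliers = outl$outliers,
              theta_raw = raw, theta_corrected = NULL,
              distortion = NA_real_, distortion_pval = NA_real_,
              n_sim = n_sim, seed = seed)
  if (length(outl$outliers) > 0L &&
      length(outl$outliers) < nrow(hset$rows)) {
    keep <- !(hset$rows$snp_id %in% outl$outliers)
    sub <- harmonized_set(hset$exposure_name, hset$outcome_name,
                          hset$rows[keep, , drop = FALSE])
    res$theta_corrected <- mr_ivw(sub, "random")$estimate
    dist <- presso_distortion(hset, outl$outliers, n_sim, seed + 2L)
    res$distortion <- dist$distortion
    res$distortion_pval <- dist$distortion_pval
  }
  structure(res, class = "presso_result")
}

presso_check <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  if (nrow(hset$rows) < 4L)
    stop("too few instruments for PRESSO (need >= 4)")
  hset$rows
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS_obs %.4g, global p = %.3g, %d outlier(s)\n",
              x$rss_obs, x$global_pval, length(x$outliers)))
  if (!is.null(x$theta_corrected))
    cat(sprintf("  corrected theta %.4g (raw %.4g), distortion p = %.3g\n",
                x$theta_corrected$theta, x$theta_raw$theta,
                x$distortion_pval))
  invisible(x)
}
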