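#' Per-SNP Wald ratio estimates
#'
#' For each instrument j the causal effect is estimated as the ratio
#' `theta_j = beta_y / beta_x` with first-order delta-method standard error
#' `se_j = se_y / |beta_x|` (the SNP-exposure uncertainty is ignored, the
#' usual approximation when instruments are strong). The IVW weight is
#' `1 / se_j^2`. With `second_order = TRUE` the standard error additionally
#' carries the SNP-exposure term:
#' `sqrt(se_y^2/beta_x^2 + beta_y^2 se_x^2 / beta_x^4)`.
#'
#' @param hset A `harmonized_set`.
#' @param second_order Use the second-order delta-method SE? Default `FALSE`.
#' @return Data frame with columns `snp_id`, `theta`, `se`, `weight`.
#' @export
wald_ratios <- function(hset, second_order = FALSE) {
  stopifnot(inherits(hset, "harmonized_set"))
  r <- hset$rows
  if (any(r$beta_x == 0))
    stop("Wald ratio undefined for zero exposure effect: ",
         paste(r$snp_id[r$beta_x == 0], collapse = ", "))
  theta <- r$beta_y / r$beta_x
  se <- if (second_order)
    sqrt(r$se_y^2 / r$beta_x^2 + r$beta_y^2 * r$se_x^2 / r$beta_x^4)
  else r$se_y / abs(r$beta_x)
  data.frame(snp_id = r$snp_id, theta = theta, se = se, weight = 1 / se^2,
             stringsAsFactors = FALSE)
}

#' Single-SNP Wald ratio
#'
#' @param beta_x,beta_y Exposure and outcome effects for one SNP.
#' @param se_y Outcome standard error.
#' @return List with `theta` and `se` (first-order).
#' @export
wald_ratio <- function(beta_x, beta_y, se_y) {
  if (beta_x == 0) stop("Wald ratio undefined for zero exposure effect")
  list(theta = beta_y / beta_x, se = se_y / abs(beta_x))
}

mr_estimate <- function(method, theta, se, pval, n_snp, dispersion = 1,
                        level = 0.95) {
  ci <- or_ci(theta, se, level)
  structure(list(method = method, theta = theta, se = se,
                 or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 pval = pval, n_snp = n_snp, dispersion = dispersion),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: OR %.3f (95%% CI %.3f-%.3f), p = %.3g [%d SNPs]\n",
              x$method, x$or, x$ci_low, x$ci_high, x$pval, x$n_snp))
  invisible(x)
}

#' Inverse-variance-weighted estimator
#'
#' Pools the per-SNP Wald ratios by their inverse variances:
#' `theta_hat = sum(w_j theta_j) / sum(w_j)` with `w_j = 1/se_j^2`, equal
#' to the weighted regression of `beta_y` on `beta_x` through the origin
#' with weights `1/se_y^2`. The fixed-effect SE is `1/sqrt(sum(w_j))`.
#' Heterogeneity is summarized by Cochran's
#' `Q = sum(w_j (theta_j - theta_hat)^2)` on `J - 1` df; under the
#' multiplicative random-effects model the SE is inflated by
#' `phi = max(1, sqrt(Q/(J-1)))`. Inference uses the normal distribution;
#' the odds-ratio scale is obtained by exponentiation.
#'
#' A single instrument reduces to its Wald ratio (fixed-effect only).
#'
#' @param hset A `harmonized_set`.
#' @param model `"random"` (default; multiplicative overdispersion floored
#'   at 1) or `"fixed"`.
#' @return List with `estimate` (an `mr_estimate`) and `heterogeneity`
#'   (`q`, `df`, `pval`; `NULL` when J = 1).
#' @export
mr_ivw <- function(hset, model = c("random", "fixed")) {
  model <- match.arg(model)
  rat <- wald_ratios(hset)
  J <- nrow(rat)
  if (J == 0L) stop("no instruments")
  if (J == 1L) {
    if (model == "random") stop("random-effects IVW needs at least 2 instruments")
    est <- mr_estimate("IVW-fixed", rat$theta, rat$se,
                       2 * stats::pnorm(-abs(rat$theta / rat$se)), 1L)
    return(list(estimate = est, heterogeneity = NULL))
  }
  w <- rat$weight
  theta <- sum(w * rat$theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  het <- cochran_q(rat$theta, w, theta)
  phi <- if (model == "random") max(1, sqrt(het$q / (J - 1))) else 1
  se <- se_fixed * phi
  pval <- 2 * stats::pnorm(-abs(theta / se))
  est <- mr_estimate(if (model == "random") "IVW-random" else "IVW-fixed",
                     theta, se, pval, J, dispersion = phi)
  list(estimate = est, heterogeneity = het)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (theta_j - theta_ref)^2)`, compared to a chi-square with
#' `J - df_offset` degrees of freedom (`df_offset = 1` for IVW, 2 for the
#' Egger fit). A small p-value signals heterogeneity of the per-SNP
#' estimates beyond their sampling error.
#'
#' @param theta Per-SNP ratio estimates (length J >= 2).
#' @param weights Inverse-variance weights.
#' @param theta_ref Pooled reference estimate.
#' @param df_offset Degrees-of-freedom reduction. Default 1.
#' @return List with `q`, `df`, `pval`.
#' @export
cochran_q <- function(theta, weights, theta_ref, df_offset = 1) {
  J <- length(theta)
  if (J < 2L) stop("Cochran's Q requires at least 2 instruments")
  q <- sum(weights * (theta - theta_ref)^2)
  df <- J - df_offset
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept, weights `1/se_y^2`; rows are first oriented so
#' every exposure effect is non-negative (both betas flipped otherwise),
#' since the fit is not invariant to allele orientation. The slope
#' estimates the causal effect under the InSIDE assumption; the intercept
#' estimates average directional pleiotropy, and its test is the standard
#' pleiotropy diagnostic. Standard errors carry multiplicative
#' overdispersion `phi = max(1, sqrt(RSS_w/(J-2)))`; p-values use the t
#' distribution with `J - 2` df.
#'
#' @param hset A `harmonized_set` with at least 3 instruments.
#' @return An `egger_result`: `slope` (an `mr_estimate`), `intercept`,
#'   `intercept_se`, `intercept_pval`, `q` (heterogeneity about the Egger
#'   fit, df J-2), `dispersion`.
#' @export
mr_egger <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  r <- hset$rows
  J <- nrow(r)
  if (J < 3L) stop("MR-Egger requires at least 3 instruments")
  flip <- r$beta_x < 0
  bx <- ifelse(flip, -r$beta_x, r$beta_x)
  by <- ifelse(flip, -r$beta_y, r$beta_y)
  w <- 1 / r$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # summary.lm scales SEs by sigma = sqrt(weighted RSS / (J-2)); re-floor at 1
  sigma <- sm$sigma
  phi <- max(1, sigma)
  se_unscaled <- sm$coefficients[, "Std. Error"] / sigma
  se <- se_unscaled * phi
  coefs <- sm$coefficients[, "Estimate"]
  tval <- coefs / se
  pv <- 2 * stats::pt(-abs(tval), df = J - 2)
  rss <- sum(w * stats::residuals(fit)^2)
  slope <- mr_estimate("Egger", coefs[["bx"]], se[["bx"]], pv[["bx"]], J,
                       dispersion = phi)
  structure(list(slope = slope,
                 intercept = coefs[["(Intercept)"]],
                 intercept_se = se[["(Intercept)"]],
                 intercept_pval = pv[["(Intercept)"]],
                 q = list(q = rss, df = J - 2,
                          pval = stats::pchisq(rss, J - 2, lower.tail = FALSE)),
                 dispersion = phi),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4g (SE %.3g), p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

# Weighted-median point estimate from ratio estimates and weights.
weighted_median_point <- function(theta, weights) {
  ord <- order(theta)
  th <- theta[ord]; w <- weights[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1L] >= 0.5) return(th[1L])
  if (s[length(s)] <= 0.5) return(th[length(th)])
  stats::approx(s, th, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Consistent estimate of the causal effect when instruments carrying at
#' least half of the total weight are valid. Ratio estimates are sorted and
#' the estimate is the linear interpolation of the cumulative standardized
#' weight function `s_k = (sum_{i<=k} w_i - w_k/2) / sum(w)` at `s = 0.5`.
#' The standard error is the standard deviation of the estimate over
#' `n_boot` parametric bootstrap replicates (`theta_j* ~ N(theta_j, se_j)`)
#' under the given seed; p-value from the normal distribution.
#'
#' @param hset A `harmonized_set` with at least 3 instruments.
#' @param n_boot Bootstrap replicates; default 1000 (a warning is raised
#'   below 100).
#' @param seed Integer seed for the bootstrap (mandatory for
#'   reproducibility).
#' @return An `mr_estimate` with method `"WeightedMedian"`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed) {
  rat <- wald_ratios(hset)
  J <- nrow(rat)
  if (J < 3L) stop("weighted median requires at least 3 instruments")
  if (missing(seed)) stop("a bootstrap seed is required")
  if (n_boot < 100) warning("n_boot < 100 gives an unstable bootstrap SE")
  theta <- weighted_median_point(rat$theta, rat$weight)
  est_star <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      th_b <- stats::rnorm(J, rat$theta, rat$se)
      weighted_median_point(th_b, rat$weight)
    }, numeric(1))
  })
  se <- stats::sd(est_star)
  pval <- 2 * stats::pnorm(-abs(theta / se))
  mr_estimate("WeightedMedian", theta, se, pval, J)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the random-effects IVW estimate excluding each instrument in
#' turn, to reveal single SNPs that drive the pooled estimate. An exclusion
#' is flagged when its confidence interval loses the sign of (stops
#' overlapping) the full-set estimate's interval on the log-odds scale.
#'
#' @param hset A `harmonized_set` with at least 3 instruments.
#' @return Data frame with one row per excluded SNP: `excluded_snp`,
#'   `theta`, `se`, `or`, `ci_low`, `ci_high`, `pval`, `flagged`.
#' @export
mr_leave_one_out <- function(hset) {
  J <- nrow(hset$rows)
  if (J < 3L) stop("leave-one-out requires at least 3 instruments")
  full <- mr_ivw(hset, "random")$estimate
  full_sign <- sign(full$theta)
  res <- lapply(seq_len(J), function(j) {
    sub <- harmonized_set(hset$exposure_name, hset$outcome_name,
                          hset$rows[-j, , drop = FALSE])
    e <- mr_ivw(sub, "random")$estimate
    lo <- log(e$ci_low); hi <- log(e$ci_high)
    flagged <- if (full_sign > 0) lo <= 0 && log(full$ci_low) > 0
      else if (full_sign < 0) hi >= 0 && log(full$ci_high) < 0
      else FALSE
    data.frame(excluded_snp = hset$rows$snp_id[j], theta = e$theta,
               se = e$se, or = e$or, ci_low = e$ci_low, ci_high = e$ci_high,
               pval = e$pval, flagged = flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Odds ratio and confidence interval from a log-scale estimate
#'
#' `OR = exp(theta)`; bounds `exp(theta -+ z se)` with z the standard
#' normal quantile at `(1 + level)/2`.
#'
#' @param theta Log-odds estimate.
#' @param se Standard error (> 0).
#' @param level Confidence level in (0, 1). Default 0.95.
#' @return List with `or`, `ci_low`, `ci_high`.
#' @export
or_ci <- function(theta, se, level = 0.95) {
  if (level <= 0 || level >= 1) stop("confidence level must lie in (0, 1)")
  if (any(se <= 0)) stop("se must be positive")
  z <- stats::qnorm((1 + level) / 2)
  list(or = exp(theta), ci_low = exp(theta - z * se),
       ci_high = exp(theta + z * se))
}

#' Recover the Wald p-value implied by a published OR and CI
#'
#' Inverts the normal-theory confidence interval: the standard error is
#' `(log ci_high - log ci_low) / (2 z_{0.975})`, the z statistic is
#' `log(OR)/se` and the p-value the two-sided normal tail. Useful for
#' internal-consistency checks of published result tables; the OR is not
#' required to lie inside the interval.
#'
#' @param or_value Odds ratio (> 0).
#' @param ci_low,ci_high 95% bounds (> 0).
#' @return Two-sided p-value.
#' @export
wald_p_from_or_ci <- function(or_value, ci_low, ci_high) {
  if (any(c(or_value, ci_low, ci_high) <= 0))
    stop("OR and CI bounds must be positive")
  se <- (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975))
  if (se == 0) stop("degenerate CI (zero width)")
  z <- log(or_value) / se
  2 * stats::pnorm(-abs(z))
}

#' Funnel- and scatter-plot data
#'
#' Exports the plot-ready tables behind the standard MR diagnostics, with
#' no rendering decisions: a funnel table of per-SNP ratio estimates
#' against their precision `1/se_j`, and a scatter table of SNP-exposure
#' versus SNP-outcome effects with one fitted line per supplied method
#' (IVW lines pass through the origin; the Egger line carries its
#' intercept).
#'
#' @param hset A `harmonized_set`.
#' @param estimates List of `mr_estimate` and/or `egger_result` objects.
#' @return List of data frames `funnel` (`snp_id theta precision`),
#'   `scatter` (`snp_id beta_x se_x beta_y se_y`) and `lines`
#'   (`method intercept slope`).
#' @export
funnel_scatter_data <- function(hset, estimates = list()) {
  rat <- wald_ratios(hset)
  funnel <- data.frame(snp_id = rat$snp_id, theta = rat$theta,
                       precision = 1 / rat$se, stringsAsFactors = FALSE)
  scatter <- hset$rows[c("snp_id", "beta_x", "se_x", "beta_y", "se_y")]
  lines <- do.call(rbind, lapply(estimates, function(e) {
    if (inherits(e, "egger_result"))
      data.frame(method = "Egger", intercept = e$intercept,
                 slope = e$slope$theta, stringsAsFactors = FALSE)
    else data.frame(method = e$method, intercept = 0, slope = e$theta,
                    stringsAsFactors = FALSE)
  }))
  list(funnel = funnel, scatter = scatter, lines = lines)
}
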