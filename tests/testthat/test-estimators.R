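test_that("Wald ratios follow the first-order delta method", {
  h <- harmonized_set("e", "o", data.frame(
    snp_id = c("a", "b", "c"), beta_x = c(0.2, 0.2, -0.1), se_x = 0.01,
    beta_y = c(0.1, 0, 0.05), se_y = c(0.02, 0.02, 0.01)))
  r <- wald_ratios(h)
  expect_equal(r$theta, c(0.5, 0, -0.5))
  expect_equal(r$se, c(0.1, 0.1, 0.1))
  expect_equal(r$weight, 1 / r$se^2)
  expect_error(wald_ratio(0, 0.1, 0.01), "zero exposure effect")
  expect_equal(wald_ratio(0.2, 0.1, 0.02), list(theta = 0.5, se = 0.1))
})

test_that("single-instrument fixed IVW reduces to the Wald ratio", {
  h <- hset_from_ratios(0.42, 25)
  res <- mr_ivw(h, "fixed")
  expect_equal(res$estimate$theta, 0.42)
  expect_equal(res$estimate$se, 1 / sqrt(25))
  expect_null(res$heterogeneity)
  expect_error(mr_ivw(h, "random"), "at least 2")
})

test_that("identical ratios give zero heterogeneity; fixed equals random", {
  h <- hset_from_ratios(c(0.2, 0.2, 0.2), c(9, 100, 4))
  fx <- mr_ivw(h, "fixed"); rd <- mr_ivw(h, "random")
  expect_equal(fx$estimate$theta, 0.2)
  expect_equal(fx$heterogeneity$q, 0)
  expect_equal(rd$estimate$dispersion, 1)
  expect_equal(rd$estimate$se, fx$estimate$se)
})

test_that("IVW pooled estimate and Q match the weighted-mean oracle", {
  theta <- c(0.1, 0.3, 0.5); w <- c(100, 25, 4)
  h <- hset_from_ratios(theta, w)
  res <- mr_ivw(h, "fixed")
  want <- oracle_ivw(theta, w)
  expect_equal(res$estimate$theta, want$theta)
  expect_equal(res$estimate$se, want$se_fixed)
  expect_equal(res$heterogeneity$q, want$q)
  expect_equal(res$heterogeneity$df, 2)
  # random-effects SE carries the overdispersion floor
  rd <- mr_ivw(h, "random")
  expect_equal(rd$estimate$se,
               want$se_fixed * max(1, sqrt(want$q / 2)))
})

test_that("IVW is invariant to instrument order and weight rescaling", {
  set.seed(2)
  theta <- rnorm(8, 0.2, 0.1); w <- runif(8, 1, 50)
  base <- mr_ivw(hset_from_ratios(theta, w), "random")
  perm <- sample(8)
  reord <- mr_ivw(hset_from_ratios(theta[perm], w[perm]), "random")
  expect_equal(reord$estimate$theta, base$estimate$theta)
  expect_equal(reord$estimate$se, base$estimate$se)
  scaled <- mr_ivw(hset_from_ratios(theta, 7.3 * w), "fixed")
  expect_equal(scaled$estimate$theta, base$estimate$theta)
})

test_that("Cochran's Q matches direct arithmetic and its chi-square tail", {
  expect_equal(cochran_q(c(0.3, 0.3), c(5, 9), 0.3)$q, 0)
  expect_equal(cochran_q(c(0.3, 0.3), c(5, 9), 0.3)$pval, 1)
  res <- cochran_q(c(0, 1), c(1, 1), 0.5)
  expect_equal(res$q, 0.5)
  expect_equal(res$df, 1)
  expect_equal(res$pval, pchisq(0.5, 1, lower.tail = FALSE))
  expect_error(cochran_q(0.3, 1, 0.3), "at least 2")
})

test_that("Cochran's Q rejects at its nominal rate under homogeneity", {
  set.seed(404)
  reps <- 2000
  rej <- vapply(seq_len(reps), function(b) {
    se <- sqrt(1 / runif(10, 5, 50))
    theta <- rnorm(10, 0.3, se)
    o <- oracle_ivw(theta, 1 / se^2)
    cochran_q(theta, 1 / se^2, o$theta)$pval < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("Egger recovers exact linear and affine fits", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- harmonized_set("e", "o", data.frame(
    snp_id = letters[1:4], beta_x = bx, se_x = 0.01,
    beta_y = 0.3 * bx, se_y = c(0.01, 0.02, 0.01, 0.03)))
  res <- mr_egger(h)
  expect_equal(res$slope$theta, 0.3, tolerance = 1e-10)
  expect_equal(res$intercept, 0, tolerance = 1e-10)
  h2 <- harmonized_set("e", "o", data.frame(
    snp_id = letters[1:4], beta_x = bx, se_x = 0.01,
    beta_y = 0.1 + 0.3 * bx, se_y = c(0.01, 0.02, 0.01, 0.03)))
  res2 <- mr_egger(h2)
  expect_equal(res2$intercept, 0.1, tolerance = 1e-10)
  expect_equal(res2$slope$theta, 0.3, tolerance = 1e-10)
  expect_error(mr_egger(hset_from_ratios(c(0.1, 0.2), c(1, 1))),
               "at least 3")
})

test_that("Egger coefficients match the weighted normal-equations oracle", {
  set.seed(8)
  bx <- runif(4, 0.05, 0.3); by <- 0.05 + 0.4 * bx + rnorm(4, 0, 0.02)
  sey <- runif(4, 0.01, 0.05)
  h <- harmonized_set("e", "o", data.frame(
    snp_id = letters[1:4], beta_x = bx, se_x = 0.01, beta_y = by,
    se_y = sey))
  res <- mr_egger(h)
  want <- oracle_wls_line(bx, by, 1 / sey^2)
  expect_equal(res$slope$theta, want$slope)
  expect_equal(res$intercept, want$intercept)
})

test_that("Egger orients instruments to non-negative exposure effects", {
  set.seed(9)
  bx <- runif(6, 0.05, 0.3); by <- 0.02 + 0.4 * bx + rnorm(6, 0, 0.01)
  sey <- runif(6, 0.01, 0.05)
  mk <- function(bx, by) harmonized_set("e", "o", data.frame(
    snp_id = letters[1:6], beta_x = bx, se_x = 0.01, beta_y = by,
    se_y = sey))
  base <- mr_egger(mk(bx, by))
  flip <- c(1, -1, 1, -1, -1, 1)
  flipped <- mr_egger(mk(bx * flip, by * flip))
  expect_equal(flipped$slope$theta, base$slope$theta)
  expect_equal(flipped$intercept, base$intercept)
})

test_that("Egger with intercept constrained to zero equals fixed IVW", {
  set.seed(10)
  bx <- runif(5, 0.05, 0.3); by <- 0.3 * bx + rnorm(5, 0, 0.02)
  sey <- runif(5, 0.01, 0.05)
  h <- harmonized_set("e", "o", data.frame(
    snp_id = letters[1:5], beta_x = bx, se_x = 0.001, beta_y = by,
    se_y = sey))
  constrained <- lm(by ~ bx + 0, weights = 1 / sey^2)
  ivw <- mr_ivw(h, "fixed")
  expect_equal(ivw$estimate$theta, unname(coef(constrained)["bx"]))
})

test_that("weighted median interpolates the cumulative weight function", {
  # symmetric weights: middle order statistic
  h <- hset_from_ratios(c(0.1, 0.2, 0.9), c(4, 4, 4))
  expect_equal(mr_weighted_median(h, n_boot = 200, seed = 1)$theta, 0.2)
  # dominant instrument pulls the estimate to its ratio
  h2 <- hset_from_ratios(c(0.1, 0.2, 0.9, 0.91), c(1, 1, 1000, 1))
  expect_equal(mr_weighted_median(h2, n_boot = 200, seed = 1)$theta, 0.9,
               tolerance = 0.02)
  # 4 unequal weights against the hand-coded oracle
  theta <- c(0.05, 0.2, 0.35, 0.6); w <- c(10, 3, 25, 7)
  h3 <- hset_from_ratios(theta, w)
  expect_equal(mr_weighted_median(h3, n_boot = 200, seed = 1)$theta,
               oracle_weighted_median(theta, w))
  expect_error(mr_weighted_median(hset_from_ratios(c(1, 2), c(1, 1)),
                                  n_boot = 200, seed = 1), "at least 3")
  expect_warning(mr_weighted_median(h, n_boot = 50, seed = 1), "unstable")
})

test_that("equal-weight odd-J weighted median equals the sample median", {
  set.seed(3)
  for (J in c(3, 5, 9)) {
    theta <- rnorm(J)
    h <- hset_from_ratios(theta, rep(2.5, J))
    expect_equal(mr_weighted_median(h, n_boot = 100, seed = 4)$theta,
                 median(theta))
  }
})

test_that("weighted-median bootstrap SE is seed-reproducible", {
  h <- hset_from_ratios(c(0.1, 0.25, 0.4, 0.3), c(10, 20, 5, 8))
  a <- mr_weighted_median(h, n_boot = 300, seed = 99)
  b <- mr_weighted_median(h, n_boot = 300, seed = 99)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(h, n_boot = 300, seed = 100)
  expect_false(identical(a$se, c_$se))
})

test_that("leave-one-out recomputes IVW per exclusion and finds outliers", {
  h <- hset_from_ratios(rep(0.3, 3), c(5, 10, 20))
  loo <- mr_leave_one_out(h)
  expect_equal(nrow(loo), 3)
  expect_equal(loo$theta, rep(0.3, 3))
  # a gross outlier moves the estimate most when excluded
  h2 <- hset_from_ratios(c(0.3, 0.31, 0.29, 0.3, 5), rep(10, 5))
  full <- mr_ivw(h2, "random")$estimate$theta
  loo2 <- mr_leave_one_out(h2)
  shift <- abs(loo2$theta - full)
  expect_equal(which.max(shift), 5)
  expect_error(mr_leave_one_out(hset_from_ratios(c(1, 2), c(1, 1))),
               "at least 3")
})

test_that("OR/CI conversion exponentiates the normal interval", {
  res <- or_ci(0, 0.1)
  expect_equal(res$or, 1)
  expect_equal(res$ci_low * res$ci_high, 1)  # symmetric on log scale
  expect_equal(or_ci(log(1.58), 0.2)$or, 1.58)
  expect_error(or_ci(0.1, 0.1, level = 1.2), "\\(0, 1\\)")
  # inverse pair with the published-table consistency check
  p <- 2 * pnorm(-abs(0.3 / 0.12))
  ci <- or_ci(0.3, 0.12)
  expect_equal(wald_p_from_or_ci(ci$or, ci$ci_low, ci$ci_high), p)
})

test_that("wald_p_from_or_ci handles the null OR and bad input", {
  expect_equal(wald_p_from_or_ci(1, 0.8, 1.3), 1)
  expect_error(wald_p_from_or_ci(-1, 0.5, 2), "positive")
})

test_that("funnel and scatter exports are element-wise correct", {
  h <- harmonized_set("e", "o", data.frame(
    snp_id = letters[1:3], beta_x = c(0.1, 0.2, 0.3), se_x = 0.01,
    beta_y = c(0.01, 0.06, 0.15), se_y = c(0.01, 0.02, 0.05)))
  ivw <- mr_ivw(h, "fixed")$estimate
  egg <- mr_egger(h)
  fs <- funnel_scatter_data(h, list(ivw, egg))
  expect_equal(nrow(fs$funnel), 3)
  expect_equal(nrow(fs$scatter), 3)
  expect_equal(fs$funnel$precision, 1 / wald_ratios(h)$se)
  lines <- fs$lines
  expect_equal(lines$intercept[lines$method == "IVW-fixed"], 0)
  expect_equal(lines$intercept[lines$method == "Egger"], egg$intercept)
  expect_equal(lines$slope[lines$method == "Egger"], egg$slope$theta)
})
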