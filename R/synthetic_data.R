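#' Configuration for the synthetic GWAS generator
#'
#' Parameters of the generative model behind [simulate_pair()] /
#' [simulate_multi()]. Defaults are sized to echo a large biobank-scale
#' exposure GWAS feeding a two-sample MR with several hundred instruments
#' and mean instrument strength in the 100-200 range: with
#' `n_exposure_samples = 5e5`, `sigma_gamma = 0.0275` and minor-allele
#' frequencies uniform on \[0.05, 0.5\] the expected mean F statistic of
#' the generated SNPs is about 140 (see [expected_mean_f()]).
#'
#' @param n_snp Number of candidate instrument SNPs J (>= 4). Default 400.
#' @param n_exposure_samples,n_outcome_samples GWAS sample sizes. Defaults
#'   5e5 (biobank-scale exposure) and 58284 (a case-control outcome GWAS
#'   of 14361 cases + 43923 controls).
#' @param theta_true True causal effect of the exposure on the outcome
#'   (log-odds per SD of exposure). Default 0.3.
#' @param pi_invalid Fraction of SNPs violating the exclusion restriction
#'   (pleiotropic). Default 0.
#' @param mu_alpha,tau_alpha Mean and SD of the direct (pleiotropic)
#'   outcome effects of invalid SNPs. Defaults 0 and 0.05.
#' @param sigma_gamma SD of the true SNP-exposure effects. Default 0.0275.
#' @param maf_range Minor-allele-frequency range. Default `c(0.05, 0.5)`.
#' @param frac_palindromic Fraction of A/T or C/G SNPs. Default 0.15.
#' @param frac_strand_flip,frac_allele_swap Rates at which the outcome
#'   file reports a SNP on the opposite strand / with effect and other
#'   allele swapped (beta and frequency adjusted accordingly, so
#'   harmonization can undo the swap). Defaults 0.02 and 0.10.
#' @param ld_block_size,ld_r2 SNPs per LD block and the constant within-
#'   block r^2. Defaults 1 (independent SNPs) and 0.3.
#' @param inside_violated If `TRUE`, pleiotropic effects are correlated
#'   with instrument strength (violating the InSIDE assumption). Default
#'   `FALSE`.
#' @param seed Master seed; expanded into independent per-component
#'   streams (frequencies, true effects, pleiotropy, noise, alleles).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snp = 400, n_exposure_samples = 5e5,
                       n_outcome_samples = 58284, theta_true = 0.3,
                       pi_invalid = 0, mu_alpha = 0, tau_alpha = 0.05,
                       sigma_gamma = 0.0275, maf_range = c(0.05, 0.5),
                       frac_palindromic = 0.15, frac_strand_flip = 0.02,
                       frac_allele_swap = 0.10, ld_block_size = 1,
                       ld_r2 = 0.3, inside_violated = FALSE, seed = 1L) {
  stopifnot(n_snp >= 4, n_exposure_samples > 0, n_outcome_samples > 0,
            pi_invalid >= 0, pi_invalid <= 1, tau_alpha >= 0,
            sigma_gamma > 0, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            frac_palindromic >= 0, frac_palindromic <= 1,
            frac_strand_flip >= 0, frac_strand_flip <= 1,
            frac_allele_swap >= 0, frac_allele_swap <= 1,
            ld_block_size >= 1, ld_r2 >= 0, ld_r2 <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Derive a bounded per-component stream seed from the master seed.
stream_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + offset
}

#' Expected mean F statistic under a generator configuration
#'
#' For a SNP with minor-allele frequency p, the SNP-exposure z statistic
#' has noncentrality `gamma^2 * 2p(1-p) * n_X`; averaging over
#' `gamma ~ N(0, sigma_gamma^2)` and the frequency distribution gives the
#' expected per-SNP F of `1 + n_X * E[2p(1-p)] * sigma_gamma^2`.
#'
#' @param config A [sim_config()].
#' @return Expected mean F (numeric).
#' @export
expected_mean_f <- function(config) {
  f <- function(p) 2 * p * (1 - p)
  e2pq <- if (config$maf_range[1] == config$maf_range[2]) f(config$maf_range[1])
  else stats::integrate(f, config$maf_range[1], config$maf_range[2])$value /
    diff(config$maf_range)
  1 + config$n_exposure_samples * e2pq * config$sigma_gamma^2
}

draw_alleles <- function(n, frac_palindromic) {
  pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  nonpal <- expand.grid(BASES, BASES, stringsAsFactors = FALSE)
  nonpal <- nonpal[nonpal[, 1] != nonpal[, 2], ]
  nonpal <- as.matrix(nonpal[!(paste(nonpal[, 1], nonpal[, 2]) %in%
                                 paste(pal_pairs[, 1], pal_pairs[, 2])), ])
  is_pal <- stats::runif(n) < frac_palindromic
  ea <- oa <- character(n)
  i_pal <- sample(nrow(pal_pairs), n, replace = TRUE)
  i_non <- sample(nrow(nonpal), n, replace = TRUE)
  ea[is_pal] <- pal_pairs[i_pal[is_pal], 1]; oa[is_pal] <- pal_pairs[i_pal[is_pal], 2]
  ea[!is_pal] <- nonpal[i_non[!is_pal], 1]; oa[!is_pal] <- nonpal[i_non[!is_pal], 2]
  list(ea = ea, oa = oa)
}

# Genomic layout: SNPs in order, 100 per chromosome, 50 kb apart.
sim_positions <- function(J) {
  chrom <- as.character((seq_len(J) - 1) %/% 100 + 1)
  pos <- as.integer(((seq_len(J) - 1) %% 100) * 50000 + 1)
  list(chrom = chrom, pos = pos)
}

sim_ld <- function(snp_ids, block_size, r2) {
  J <- length(snp_ids)
  m <- diag(1, J)
  if (block_size > 1) {
    block <- (seq_len(J) - 1) %/% block_size
    same <- outer(block, block, "==")
    m[same] <- r2
    diag(m) <- 1
  }
  ld_matrix(snp_ids, m)
}

#' Simulate a paired exposure/outcome GWAS with known truth
#'
#' Generates summary statistics under the standard two-sample MR summary-
#' data model. Per SNP j: frequency `maf_j ~ U(maf_range)`; true exposure
#' effect `gamma_j ~ N(0, sigma_gamma^2)`; standard errors follow the
#' closed form `se = 1/sqrt(2 maf (1-maf) n)` exactly (no noise on SEs);
#' observed effects `beta_xj ~ N(gamma_j, se_xj^2)`. A Bernoulli
#' `pi_invalid` subset of SNPs receives a direct (pleiotropic) outcome
#' effect `alpha_j ~ N(mu_alpha, tau_alpha^2)` (correlated with instrument
#' strength `|gamma_j|` when `inside_violated`); valid SNPs have
#' `alpha_j = 0`. Pleiotropy is applied on the exposure-increasing allele
#' orientation — the convention under which a nonzero `mu_alpha` is
#' directional — so outcome effects are
#' `beta_yj ~ N(theta_true * gamma_j + sign(gamma_j) * alpha_j, se_yj^2)`;
#' p-values
#' are two-sided Wald. Alleles are drawn with the configured palindromic
#' fraction; the outcome file is then perturbed by the configured allele-
#' swap and strand-flip rates (with beta and frequency adjusted so the
#' discordance is recoverable by harmonization). The LD sidecar has
#' constant within-block r^2.
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` (`summary_stats`), `ld`
#'   (`ld_matrix`), and `truth` (`theta_true`, `gamma`, `alpha`,
#'   `invalid_ids`, `maf`, `expected_mean_f`).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_snp
  ids <- sprintf("rs%06d", seq_len(J))
  loc <- sim_positions(J)

  maf <- local_seed(stream_seed(config$seed, 1L),
                    stats::runif(J, config$maf_range[1], config$maf_range[2]))
  gamma <- local_seed(stream_seed(config$seed, 2L),
                      stats::rnorm(J, 0, config$sigma_gamma))
  inv <- local_seed(stream_seed(config$seed, 3L),
                    stats::runif(J) < config$pi_invalid)
  alpha <- numeric(J)
  if (any(inv)) {
    alpha[inv] <- local_seed(stream_seed(config$seed, 4L),
                             stats::rnorm(sum(inv), config$mu_alpha,
                                          config$tau_alpha))
    if (config$inside_violated)
      alpha[inv] <- alpha[inv] +
        (config$tau_alpha / config$sigma_gamma) * abs(gamma[inv])
  }
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure_samples)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome_samples)
  beta_x <- local_seed(stream_seed(config$seed, 5L),
                       stats::rnorm(J, gamma, se_x))
  # pleiotropy acts on the exposure-increasing orientation, so mu_alpha is
  # genuinely directional (a mean shift of the invalid SNPs' ratios)
  mu_y <- config$theta_true * gamma + sign(gamma) * alpha
  beta_y <- local_seed(stream_seed(config$seed, 6L),
                       stats::rnorm(J, mu_y, se_y))

  al <- local_seed(stream_seed(config$seed, 7L),
                   draw_alleles(J, config$frac_palindromic))
  wald_p <- function(b, s) 2 * stats::pnorm(-abs(b / s))
  mkrec <- function(ea, oa, eaf, beta, se, n)
    data.frame(snp_id = ids, chrom = loc$chrom, pos = loc$pos,
               effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
               se = se, pval = pmax(wald_p(beta, se), .Machine$double.xmin),
               n = n, stringsAsFactors = FALSE)
  exposure <- summary_stats("exposure",
                            mkrec(al$ea, al$oa, maf, beta_x, se_x,
                                  config$n_exposure_samples))

  # outcome-file discordance: allele swap and strand flip
  disc <- local_seed(stream_seed(config$seed, 8L), {
    list(swap = stats::runif(J) < config$frac_allele_swap,
         flip = stats::runif(J) < config$frac_strand_flip)
  })
  o_ea <- al$ea; o_oa <- al$oa
  o_beta <- beta_y; o_eaf <- maf
  sw <- disc$swap
  o_ea[sw] <- al$oa[sw]; o_oa[sw] <- al$ea[sw]
  o_beta[sw] <- -o_beta[sw]; o_eaf[sw] <- 1 - o_eaf[sw]
  fl <- disc$flip
  o_ea[fl] <- complement_alleles(o_ea[fl])
  o_oa[fl] <- complement_alleles(o_oa[fl])
  outcome <- summary_stats("outcome",
                           mkrec(o_ea, o_oa, o_eaf, o_beta, se_y,
                                 config$n_outcome_samples))
  truth <- list(theta_true = config$theta_true, gamma = stats::setNames(gamma, ids),
                alpha = stats::setNames(alpha, ids), invalid_ids = ids[inv],
                maf = stats::setNames(maf, ids),
                expected_mean_f = expected_mean_f(config))
  list(exposure = exposure, outcome = outcome,
       ld = sim_ld(ids, config$ld_block_size, config$ld_r2), truth = truth)
}

#' Simulate correlated multi-exposure GWAS with known direct effects
#'
#' Extends [simulate_pair()] to K exposures whose true SNP-effect columns
#' are correlated (Gaussian copula via the Cholesky factor of the given
#' correlation matrix): `gamma_jk = sigma_gamma * (Z L')_jk` with
#' `Z ~ N(0, I)`. The outcome is generated from the direct-effects vector
#' only: `beta_yj ~ N(sum_k d_k gamma_jk + alpha_j, se_yj^2)`, so an
#' exposure with direct effect 0 influences the outcome solely through
#' its correlation with causal exposures — the total-versus-direct
#' contrast multivariable MR is designed to separate.
#'
#' @param config A [sim_config()] (its `theta_true` is ignored in favour
#'   of `direct_effects`).
#' @param k_exposures K >= 2.
#' @param exposure_correlation K x K positive-definite correlation matrix.
#'   Default identity.
#' @param direct_effects Length-K vector of direct causal effects.
#' @return List with `exposures` (list of `summary_stats`), `outcome`,
#'   `ld`, `truth` (`direct_effects`, `gamma` matrix, `alpha`,
#'   `invalid_ids`, `maf`).
#' @export
simulate_multi <- function(config, k_exposures,
                           exposure_correlation = diag(k_exposures),
                           direct_effects) {
  stopifnot(inherits(config, "sim_config"), k_exposures >= 2,
            length(direct_effects) == k_exposures,
            all(dim(exposure_correlation) == c(k_exposures, k_exposures)))
  ev <- eigen(exposure_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-10)) stop("exposure correlation matrix is not positive definite")
  L <- chol(exposure_correlation)
  J <- config$n_snp
  ids <- sprintf("rs%06d", seq_len(J))
  loc <- sim_positions(J)
  K <- k_exposures

  maf <- local_seed(stream_seed(config$seed, 1L),
                    stats::runif(J, config$maf_range[1], config$maf_range[2]))
  Z <- local_seed(stream_seed(config$seed, 2L),
                  matrix(stats::rnorm(J * K), J, K))
  gamma <- config$sigma_gamma * (Z %*% L)
  inv <- local_seed(stream_seed(config$seed, 3L),
                    stats::runif(J) < config$pi_invalid)
  alpha <- numeric(J)
  if (any(inv))
    alpha[inv] <- local_seed(stream_seed(config$seed, 4L),
                             stats::rnorm(sum(inv), config$mu_alpha,
                                          config$tau_alpha))
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure_samples)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome_samples)
  beta_x <- local_seed(stream_seed(config$seed, 5L),
                       gamma + matrix(stats::rnorm(J * K), J, K) * se_x)
  mu_y <- as.numeric(gamma %*% direct_effects) + sign(gamma[, 1L]) * alpha
  beta_y <- local_seed(stream_seed(config$seed, 6L),
                       stats::rnorm(J, mu_y, se_y))
  al <- local_seed(stream_seed(config$seed, 7L),
                   draw_alleles(J, config$frac_palindromic))
  wald_p <- function(b, s) pmax(2 * stats::pnorm(-abs(b / s)),
                                .Machine$double.xmin)
  exposures <- lapply(seq_len(K), function(k) {
    summary_stats(paste0("exposure_", k), data.frame(
      snp_id = ids, chrom = loc$chrom, pos = loc$pos,
      effect_allele = al$ea, other_allele = al$oa, eaf = maf,
      beta = beta_x[, k], se = se_x, pval = wald_p(beta_x[, k], se_x),
      n = config$n_exposure_samples, stringsAsFactors = FALSE))
  })
  outcome <- summary_stats("outcome", data.frame(
    snp_id = ids, chrom = loc$chrom, pos = loc$pos,
    effect_allele = al$ea, other_allele = al$oa, eaf = maf,
    beta = beta_y, se = se_y, pval = wald_p(beta_y, se_y),
    n = config$n_outcome_samples, stringsAsFactors = FALSE))
  truth <- list(direct_effects = direct_effects,
                gamma = `dimnames<-`(gamma, list(ids, NULL)),
                alpha = stats::setNames(alpha, ids),
                invalid_ids = ids[inv], maf = stats::setNames(maf, ids))
  list(exposures = exposures, outcome = outcome,
       ld = sim_ld(ids, config$ld_block_size, config$ld_r2), truth = truth)
}

#' Write a simulated study to disk
#'
#' Writes `exposure.tsv` (or `exposure_<k>.tsv`), `outcome.tsv`, `ld.tsv`
#' (sparse triplets) and `truth.json` under a directory.
#'
#' @param sim Output of [simulate_pair()] or [simulate_multi()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim[["exposure"]]))
    write_summary_stats(sim[["exposure"]], file.path(dir, "exposure.tsv"))
  if (!is.null(sim[["exposures"]]))
    for (k in seq_along(sim[["exposures"]]))
      write_summary_stats(sim[["exposures"]][[k]],
                          file.path(dir, sprintf("exposure_%d.tsv", k)))
  write_summary_stats(sim$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(sim$ld, file.path(dir, "ld.tsv"))
  truth <- sim$truth
  if (is.matrix(truth$gamma)) truth$gamma <- as.data.frame(truth$gamma)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
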