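# Shared fixture builders and independent oracles.

# Minimal valid record data frame; fields overridable per column.
make_records <- function(n, ...) {
  if (n == 0) return(make_records_(1)[0, ])
  make_records_(n, ...)
}

make_records_ <- function(n, snp_id = sprintf("rs%03d", seq_len(n)),
                         chrom = "1", pos = seq_len(n) * 1000L,
                         effect_allele = "A", other_allele = "G",
                         eaf = 0.3, beta = 0.1, se = 0.01,
                         pval = 1e-10, n_samples = 1e5) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n_samples,
             stringsAsFactors = FALSE)
}

make_stats <- function(n, trait = "trait", ...) {
  summary_stats(trait, make_records(n, ...))
}

# Harmonized set whose Wald ratios and weights are exactly the given
# vectors: beta_x = 1, beta_y = theta, se_y = 1/sqrt(weight).
hset_from_ratios <- function(theta, weight, se_x = 1e-4) {
  n <- length(theta)
  harmonized_set("exposure", "outcome", data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)), beta_x = 1, se_x = se_x,
    beta_y = theta, se_y = 1 / sqrt(weight), stringsAsFactors = FALSE))
}

# Independent IVW oracle: plain weighted mean and Q, coded directly.
oracle_ivw <- function(theta, w) {
  tb <- sum(w * theta) / sum(w)
  list(theta = tb, se_fixed = sqrt(1 / sum(w)),
       q = sum(w * (theta - tb)^2))
}

# Independent Egger oracle: 2x2 weighted normal equations solved by hand.
oracle_wls_line <- function(x, y, w) {
  A <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2, 2)
  b <- c(sum(w * y), sum(w * x * y))
  ab <- solve(A, b)
  list(intercept = ab[1], slope = ab[2])
}

# Independent weighted-median oracle: cumulative standardized weights and
# manual linear interpolation at 0.5.
oracle_weighted_median <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]; ww <- w[o]
  s <- (cumsum(ww) - ww / 2) / sum(ww)
  if (s[1] >= 0.5) return(th[1])
  k <- max(which(s < 0.5))
  if (k == length(th)) return(th[length(th)])
  th[k] + (th[k + 1] - th[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# Independent greedy-clumping oracle: explicit loop over p-sorted SNPs.
oracle_clump_ids <- function(rec, r2mat, r2_threshold, window_bp) {
  ord <- order(rec$pval, rec$chrom, rec$pos, rec$snp_id)
  rec <- rec[ord, ]
  dropped <- character(); kept <- character()
  for (i in seq_len(nrow(rec))) {
    id <- rec$snp_id[i]
    if (id %in% dropped) next
    kept <- c(kept, id)
    for (j in seq_len(nrow(rec))) {
      idj <- rec$snp_id[j]
      if (idj == id || idj %in% dropped || idj %in% kept) next
      if (rec$chrom[j] == rec$chrom[i] &&
          abs(rec$pos[j] - rec$pos[i]) <= window_bp &&
          r2mat[id, idj] >= r2_threshold)
        dropped <- c(dropped, idj)
    }
  }
  kept
}

# Build a harmonized set straight from a simulated pair (alleles in the
# two files are aligned up to the generator's swap/flip perturbations,
# which harmonize() undoes).
sim_hset <- function(sim) harmonize(sim$exposure, sim$outcome)
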