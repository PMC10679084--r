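# wbcmr

Two-sample and multivariable Mendelian randomization (MR) from GWAS
summary statistics, built around the study design used to ask whether
blood leukocyte counts (eosinophils, neutrophils, lymphocytes,
monocytes, basophils, total white cells) causally affect rheumatoid
arthritis risk. It is aimed at analysts who have per-SNP association
files for an exposure and an outcome and want the full instrumental
variable workflow — selection, harmonization, estimation, sensitivity
analysis, and reporting — as reproducible, tested R functions, plus a
synthetic GWAS generator with known causal truth so every stage can be
validated without downloading real GWAS data.

## The method

For instrument *j*, the Wald ratio θ̂ⱼ = β̂ᵧⱼ/β̂ₓⱼ (per-SNP outcome effect
over exposure effect) estimates the causal effect θ on the log-odds
scale, with first-order SE σⱼ = σᵧⱼ/|β̂ₓⱼ|. The package provides:

- **Instrument selection** — genome-wide significance filter
  (p < 5×10⁻⁸), greedy LD clumping (r² < 0.01, 10,000 kb window),
  confounder-list exclusion, palindromic-SNP removal, per-SNP and mean
  F statistics (`select_instruments()`).
- **Harmonization** — alignment of both files to a common effect allele,
  resolving allele swaps and strand flips, with a full audit trail
  (`harmonize()`).
- **Estimators** — IVW (fixed and multiplicative random effects),
  MR-Egger with its pleiotropy intercept test, the bootstrap weighted
  median, Cochran's Q, leave-one-out, funnel/scatter plot data
  (`mr_ivw()`, `mr_egger()`, `mr_weighted_median()`,
  `mr_leave_one_out()`, `funnel_scatter_data()`).
- **MR-PRESSO** — simulation-calibrated global heterogeneity test,
  per-SNP outlier flags, distortion test and outlier-corrected estimate
  (`mr_presso()`).
- **Multivariable MR** — direct effects of several correlated exposures
  with Q_A heterogeneity and conditional F statistics
  (`build_mvmr_set()`, `mvmr_ivw()`, `conditional_f()`).
- **Reporting** — Bonferroni correction across exposures and a
  publication-style result table (`bonferroni_threshold()`,
  `assemble_table()`), plus a YAML-driven end-to-end pipeline
  (`run_pipeline()`).
- **Synthetic data** — paired and multi-exposure GWAS summary statistics
  with controllable causal effect, pleiotropy fraction, LD blocks,
  palindromes and cross-file allele discordance (`simulate_pair()`,
  `simulate_multi()`).

## Worked example

```r
library(wbcmr)

sim <- simulate_pair(sim_config(seed = 42))       # known truth: theta = 0.3
res <- mr_univariable(sim$exposure, sim$outcome, sim$ld, seed = 7)

cat("instruments:", res$selection$n_after_palindrome,
    "of", res$selection$n_input, " mean F:", round(res$selection$mean_f, 1), "\n")
print(res$ivw$estimate)
print(res$egger)
print(res$wmedian)
print(res$presso)
```

```
instruments: 204 of 400   mean F: 208.5
IVW-random: OR 1.310 (95% CI 1.273-1.348), p = 7.41e-75 [204 SNPs]
Egger: OR 1.262 (95% CI 1.184-1.345), p = 1.74e-11 [204 SNPs]
  intercept 0.001381 (SE 0.00108), p = 0.201
WeightedMedian: OR 1.324 (95% CI 1.266-1.384), p = 2.16e-35 [204 SNPs]
MR-PRESSO: RSS_obs 221.1, global p = 0.261, 0 outlier(s)
```

Reading the output: 204 of 400 simulated SNPs survive selection, with
mean F ≈ 209 (no weak-instrument concern). The true causal effect is
0.3, i.e. a true OR of e^0.3 ≈ 1.35; the IVW odds ratio of 1.31 reflects
the small first-order attenuation expected at finite instrument strength
(see the methods vignette). The Egger intercept is indistinguishable
from zero (p = 0.20) and MR-PRESSO flags no outliers — as it should,
since this simulation contains no pleiotropy. The weighted median agrees
with IVW, the pattern expected when instruments are predominantly valid.

A six-exposure study with multivariable MR and a Bonferroni-corrected
report runs through one config:

```r
sim <- simulate_multi(sim_config(seed = 1), 6, diag(6),
                      direct_effects = c(0.3, 0, 0, 0, 0, 0))
report <- run_pipeline(list(
  inputs = list(exposures = sim$exposures, outcome = sim$outcome, ld = sim$ld),
  seeds = list(master = 1)))
print(report)
```

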