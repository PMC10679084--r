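---
title: "Two-sample and multivariable Mendelian randomization with wbcmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample and multivariable Mendelian randomization with wbcmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbcmr)
```

## The problem and the model

Observational associations between blood leukocyte counts and autoimmune
disease are vulnerable to confounding and reverse causation. Mendelian
randomization (MR) sidesteps both by using genetic variants as
instrumental variables: because alleles are assorted randomly at meiosis,
a SNP that raises a leukocyte count is not confounded by lifestyle or
disease processes, and disease onset cannot alter germline genotype.

wbcmr implements the two-sample summary-statistics form of this design.
For instrument $j$ we observe the SNP–exposure association
$\hat\beta_{Xj}$ (SD units of the cell count) with standard error
$\sigma_{Xj}$ from one GWAS, and the SNP–outcome association
$\hat\beta_{Yj}$ (log-odds of disease) with $\sigma_{Yj}$ from another.
If the SNP is a valid instrument — associated with the exposure,
independent of confounders, and affecting the outcome only through the
exposure — the Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal
effect $\theta$, with first-order standard error
$\sigma_j = \sigma_{Yj}/|\hat\beta_{Xj}|$.

### Estimators

* **IVW** pools the ratios by inverse variance,
  $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$, $w_j = \sigma_j^{-2}$;
  equivalently, weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ through the origin with weights $\sigma_{Yj}^{-2}$.
  Heterogeneity is measured by Cochran's
  $Q = \sum w_j(\hat\theta_j - \hat\theta)^2$ on $J-1$ df. The
  random-effects variant inflates the fixed-effect standard error by the
  multiplicative overdispersion $\phi = \max\{1, \sqrt{Q/(J-1)}\}$. We
  chose the multiplicative model (rather than an additive $\tau^2$)
  because it is the convention of the summary-data MR software family
  this package follows; it never reports a smaller standard error than
  the fixed-effect model and leaves the point estimate untouched.
* **MR-Egger** adds a free intercept to the weighted regression. The
  intercept estimates average directional pleiotropy; the slope remains
  a consistent causal estimate under the InSIDE assumption (pleiotropic
  effects independent of instrument strength). Because the fit is not
  invariant to allele orientation, rows are first flipped so every
  $\hat\beta_{Xj} \ge 0$. Inference uses the $t$ distribution on $J-2$
  df with the same overdispersion floor; IVW uses the normal
  distribution — the common default pairing, stated here because it
  affects p-values at small $J$.
* **Weighted median**: the ratio estimates are sorted and the estimate is
  the interpolated 50% point of the cumulative standardized weights
  $s_k = (\sum_{i \le k} w_i - w_k/2)/\sum w_i$. It is consistent while
  instruments carrying at least half the total weight are valid. Its
  standard error comes from a parametric bootstrap
  ($\hat\theta_j^* \sim N(\hat\theta_j, \sigma_j)$, default 1,000
  replicates) under a mandatory seed.
* **MR-PRESSO** computes the leave-one-out residual sum of squares
  $\mathrm{RSS} = \sum_j w_j(\hat\beta_{Yj} -
  \hat\theta_{(-j)}\hat\beta_{Xj})^2$ and calibrates it by simulation,
  redrawing both effect columns from their sampling distributions.
  Per-SNP outlier p-values use the same simulated residuals with a
  Bonferroni flag at $0.05/J$; the distortion test compares the change
  in the IVW estimate after outlier removal to the change under removal
  of equally many random instruments. All empirical p-values use the
  $(r+1)/(n+1)$ estimator, so they are never exactly zero, and every
  result is bit-reproducible given the seed.
* **Multivariable MR** regresses $\hat\beta_{Yj}$ jointly on $K$ columns
  of exposure effects (no intercept, weights $\sigma_{Yj}^{-2}$), giving
  *direct* effects that hold the other exposures fixed. Heterogeneity
  uses $Q_A$ on $J-K$ df with the same multiplicative floor. Conditional
  instrument strength for exposure $k$ is the mean squared standardized
  residual of its effect column after weighted regression on the other
  columns; it collapses to zero for collinear exposures and approaches
  the univariable mean F for exposures with independent instruments.
  Cross-exposure covariances of the effect estimates are set to zero:
  the source GWAS overlap needed to estimate them is not available in
  the two-sample setting, and this is a documented limitation rather
  than an option.

### Instrument selection and harmonization

Selection applies, in order: the genome-wide significance filter
(strict $p < 5\times10^{-8}$), greedy LD clumping ($r^2 < 0.01$ within a
10,000 kb window, lowest p-value first, ties broken by chromosome,
position, then SNP id so results are order-insensitive), removal of a
user-supplied list of confounder-associated SNPs, and removal of
palindromic (A/T, C/G) SNPs. Instrument strength is summarized by the
mean of the per-SNP $F = (\hat\beta/\sigma)^2$, with 10 the conventional
weak-instrument bar. SNPs absent from the LD input are treated as
unlinked, because sparse LD files list only nonzero pairs; the LD matrix
is always an input, never estimated, since reference-panel access is out
of scope.

Harmonization matches on SNP id (both source GWAS families are
rsID-keyed; positions may disagree across genome builds), resolves
allele swaps by negating the outcome beta and reflecting its frequency,
resolves strand flips through the A↔T/C↔G complement, drops
irreconcilable pairs, and drops palindromes outright — allele
frequencies are never used to rescue them, the more conservative of the
two common conventions. Frequency discordance above 0.2 between studies
on non-palindromic SNPs raises a warning but no drop: it is a data
quality signal, not a harmonization failure. Every shared SNP lands in
exactly one audit category, so the audit counts always reconcile with
the input sizes.

## The synthetic-data generator

`simulate_pair()` generates the summary statistics the estimators
consume, with the truth retained so recovery is checkable. Per SNP:
minor-allele frequency $p_j \sim U(0.05, 0.5)$; true exposure effect
$\gamma_j \sim N(0, \sigma_\gamma^2)$; standard errors follow the
large-sample closed form $\sigma = 1/\sqrt{2p(1-p)n}$ exactly (no noise
on standard errors); observed effects are drawn around the truth. A
Bernoulli($\pi$) subset of SNPs violates the exclusion restriction with
direct outcome effects $\alpha_j \sim N(\mu_\alpha, \tau_\alpha^2)$.

One design choice deserves emphasis: **pleiotropy is applied on the
exposure-increasing allele orientation**,
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \mathrm{sign}(\gamma_j)\,
\alpha_j, \sigma_{Yj}^2)$. Allele orientation is arbitrary, and with
$\gamma_j$ symmetric around zero a mean shift $\mu_\alpha$ applied in a
random orientation cancels in ratio space
($E[\alpha_j\gamma_j] = 0$), leaving nothing "directional" about it.
Fixing the orientation to the exposure-increasing allele — the
convention of the MR-Egger and weighted-median simulation literature —
makes $\mu_\alpha$ a genuine mean shift of the invalid instruments'
ratios, which is the scenario pleiotropy-robust estimators are built
for. The `inside_violated` flag additionally correlates $\alpha_j$ with
instrument strength $|\gamma_j|$, breaking the InSIDE assumption that
MR-Egger relies on.

Defaults echo a biobank-scale study: 400 candidate SNPs (the source
study's per-trait instrument counts ranged from 159 to 425), exposure
GWAS of 500,000, an outcome GWAS of 58,284 (14,361 cases plus 43,923
controls), $\sigma_\gamma = 0.0275$ so the expected mean F is about 140
(the study's trait-wise means ranged from roughly 120 to 176;
`expected_mean_f()` gives the closed form
$1 + n_X E[2p(1-p)]\sigma_\gamma^2$), a true effect of 0.3 on the
log-odds scale, 15% palindromic SNPs, 10% allele-swapped and 2%
strand-flipped records in the outcome file (both recoverable by
harmonization), and no pleiotropy. One master seed expands into
independent per-component streams (frequencies, effects, pleiotropy,
noise, alleles), so a single component can be varied without disturbing
the rest. `simulate_multi()` extends this to $K$ correlated exposures
via the Cholesky factor of a supplied correlation matrix, with the
outcome generated from a vector of *direct* effects only — the
total-versus-direct contrast that motivates multivariable MR.

What the generator does **not** emulate: realistic genome-wide LD maps
(blocks have constant within-block $r^2$), case–control
liability-threshold sampling (outcome effects are Gaussian on the
log-odds scale, the standard summary-data approximation), sample
overlap between the exposure and outcome GWAS (the two-sample regime is
assumed), indels and multi-allelic variants, and population
stratification. Tests passing on these simulations therefore validate
the estimators and the pipeline plumbing, not robustness to those
real-data complications.

## Validation studies and their sizes

The package's study-level checks (in the test suite and
`scripts/acceptance.R`) use these designs, chosen to balance Monte-Carlo
resolution against a single-CPU run of a few minutes:

* **Null calibration** — $\theta = 0$, no pleiotropy, $J = 200$, 1,000
  replicates: IVW and Egger-intercept rejection rates at $\alpha = 0.05$
  should sit in [0.03, 0.07]. Selection is bypassed (all 200 SNPs are
  instruments) so $J$ is held exactly at its nominal value.
* **Recovery** — $\theta = 0.3$, $J = 100$, expected mean F of 60
  ($n_X = 10^5$, $\sigma_\gamma = 0.0402$), 500 replicates: mean
  estimate and 95% CI coverage.
* **Robustness** — as recovery but with 40% invalid instruments carrying
  directional pleiotropy ($\mu_\alpha = 0.05$, $\tau_\alpha = 0.02$):
  the weighted median should show smaller absolute bias than IVW on
  matched seeds.
* **Outlier detection** — $J = 20$ clean instruments with one outcome
  effect displaced by 10 outcome standard errors along its ratio
  direction, 200 seeded runs at 1,000 PRESSO simulations; plus 200 clean
  runs for the false-flag rate.
* **End-to-end power** — six exposures, only the first causal
  ($\theta = 0.3$), generator defaults, 100 replicates: the causal
  exposure alone should pass the Bonferroni bar ($0.05/6$) in at least
  90% of replicates, echoing a single-positive-trait study design.
* **Multivariable recovery** (test suite) — three exposures correlated
  at 0.6, only the first with a direct effect, 150 replicates at
  $J = 60$: direct effects centered on (0.3, 0, 0).

## Numerical choices and degenerate inputs

* Overdispersion is floored at 1 everywhere (IVW-random, Egger, MVMR):
  under-dispersed data never shrink a standard error below its
  fixed-effect value.
* A single instrument reduces IVW-fixed to the Wald ratio;
  random-effects IVW, Egger, the weighted median and leave-one-out
  refuse $J$ below their identifiable minimum (2, 3, 3, 3) rather than
  degrade silently; MR-PRESSO requires $J \ge 4$.
* A zero exposure effect makes the Wald ratio undefined and is a hard
  error, not an Inf.
* Clumping ties on p-value are broken deterministically (chromosome,
  position, SNP id); the selected set is invariant to input row order.
* Empirical p-values use the plus-one estimator and are bounded below by
  $1/(n_{\mathrm{sim}}+1)$.
* The Wald-ratio standard error ignores exposure-side noise by default
  (first-order delta method), the standard choice when mean F is large;
  `wald_ratios(second_order = TRUE)` exposes the two-term version.
* Rank-deficient multivariable designs are a hard error naming the
  collinear exposures; an all-zero exposure column is rank-deficient,
  not silently dropped.

## Known limitations

* **Weak-instrument attenuation.** First-order ratio IVW is attenuated
  by roughly the factor $1 - 1/\bar F$, because
  $E[\hat\beta_{Xj}^2] = \gamma_j^2 + \sigma_{Xj}^2$. At the recovery
  study's mean F of 60 this is a relative bias near 1.7% (mean estimate
  about 0.295 for a truth of 0.3) — small in practice at the
  instrument strengths of the motivating study (mean F above 100), but
  systematic: at 500 replicates the Monte-Carlo standard error of the
  mean (about 0.0008) resolves it clearly, so the recovery study's mean
  lands several MC-SEs below the truth even though coverage is nominal.
  This is a property of the estimator, not of the implementation (which
  matches the closed-form oracle exactly); no correction (e.g.
  Steiger-style filtering or debiased IVW) is applied because none was
  part of the analysis design this package reproduces.
* MVMR assumes zero covariance between a SNP's effect estimates across
  exposures; with heavily overlapping source GWAS the direct-effect
  standard errors are optimistic.
* Palindromic SNPs are always dropped, never frequency-inferred; with
  high palindrome fractions this costs instruments.
* The confounder screen removes exactly the ids supplied; proxies (LD
  friends) of confounder SNPs are not chased.
* Instruments missing from the outcome GWAS are dropped, not proxied.
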