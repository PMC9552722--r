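---
title: "Two-sample Mendelian randomization with mrpipe: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The causal model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure (here, blood pyroglutamine level) on an outcome (COVID-19
susceptibility) using genetic variants as instrumental variables, with the
exposure and outcome associations measured in two separate GWAS. For
instrument $j$ the exposure GWAS supplies $(\hat\beta_{Xj}, se_{Xj})$ and
the outcome GWAS $(\hat\beta_{Yj}, se_{Yj})$. Under the instrumental-variable
assumptions (relevance, independence from confounders, and effect on the
outcome only through the exposure), each variant yields a Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimating the same causal
effect $\theta$, on the log-odds scale when the outcome is binary.

The estimators combine these ratios:

* **IVW** — $\hat\theta = \sum_j w_j \hat\theta_j / \sum_j w_j$ with
  $w_j = se(\hat\theta_j)^{-2}$; equivalent to a weighted zero-intercept
  regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$. Efficient when every
  instrument is valid; biased if pleiotropy is directional.
* **Weighted median** — the 50th percentile of the weight-standardized
  ratio distribution, by linear interpolation of the standardized
  cumulative weights $s_j = \sum_{k \le j} p_k - p_j/2$ at $s = 0.5$.
  Consistent while valid instruments carry more than half the weight.
* **MR-Egger** — weighted regression of outcome on exposure betas with a
  free intercept after orienting all exposure effects non-negative. The
  slope is robust to directional pleiotropy under the InSIDE assumption;
  the intercept estimates the average direct effect and its test is the
  pleiotropy diagnostic.

Diagnostics: Cochran's $Q$ (about the fixed-effect IVW estimate, $J-1$ df,
and about the Egger fit, $J-2$ df) measures heterogeneity among ratios;
MR-PRESSO simulates the residual-sum-of-squares distribution under the
no-pleiotropy model to give a global test, per-variant outlier calls and an
outlier-corrected estimate; leave-one-out and single-SNP tables expose
estimates driven by individual variants.

## Parameters that matter

| parameter | default | units / scale | why |
|---|---|---|---|
| `pval_threshold` | 5e-8 | p-value | genome-wide significance for instrument relevance |
| `ld_r2_max` | 0.001 | LD r² | near-independence between instruments; greedy clumping by ascending p |
| `eaf_ambiguity_band` | 0.08 | allele frequency | palindromic SNPs with either frequency inside 0.5 ± band are ambiguous |
| `se_method` | `first_order` | — | ratio SE `se_out/|beta_exp|`; adequate for strong instruments |
| `ivw_model` | `multiplicative_random_effects` | — | SE scaled by `max(1, sqrt(Q/(J-1)))`; never narrower than fixed-effect |
| `n_boot` | 1000 | iterations | weighted-median parametric bootstrap SE |
| `n_sim` | 1000 | replicates | MR-PRESSO simulated RSS distribution |
| `outlier_alpha` | 0.05 | level | PRESSO global gate and Bonferroni-adjusted outlier calls |
| weak-instrument flag | F < 10 | F-statistic | conventional relevance threshold |

The multiplicative random-effects IVW is the default because, on the
packaged four-instrument dataset, it reproduces the published standard
error (0.213 from unrounded inputs; 0.219 from the printed 3-decimal
inputs) where the fixed-effect form gives about 0.204. IVW p-values use
the normal distribution; Egger p-values use $t_{J-2}$, which with four
instruments (2 df) is the only choice consistent with the published
intercept p of 0.224. Confidence intervals use 1.96 exactly, matching the
published interval arithmetic.

## The packaged dataset and what "reproducing" it means

The package ships the four pyroglutamine instruments (blood-metabolite
GWAS, per-SNP n = 7,354 as printed) and their effects in the COVID-19 Host
Genetics Initiative release-4 susceptibility GWAS (14,134 cases, 1,284,876
controls), transcribed at the 3-decimal precision of the published tables.
Three consequences are worth stating plainly:

* The source prints outcome betas already oriented to the
  pyroglutamine-raising allele and omits outcome alleles and frequencies.
  The outcome fixture therefore carries the exposure alleles (an
  orientation assumption) and missing EAF. One instrument (rs1600760,
  A/T) is palindromic; because its outcome EAF is missing, the
  `keep_if_eaf_informative` policy cannot apply its frequency check and
  keeps the variant — the degradation is deliberate and logged, and it is
  what makes the four-variant analysis reproducible.
* The shipped LD table records r² = 0 for all six instrument pairs. It
  encodes the published statement that all pairs have r² < 0.001, not a
  measured LD matrix.
* Because the printed inputs are rounded, recomputed statistics differ
  from the published ones in the second or third decimal (e.g. IVW beta
  −0.630 vs −0.644; Q 3.47 vs 3.29). The test suite asserts agreement
  within bands wide enough to absorb 3-decimal input rounding but narrow
  enough to catch any methodological deviation.

The published per-SNP variance-explained column is not exactly
reproducible from the printed summary statistics: the z-based formula
$r^2 = z^2/(z^2+n-2)$ gives 1.09% for rs715 against the printed 0.91%,
and the allele-frequency formula $2f(1-f)\beta^2$ gives 0.05%. Both
estimators are exposed; [f_statistic()] accepts an externally supplied
$r^2$, so the published F column is reproducible from the published
$R^2$ column (within 0.5%), which is how the strength table is checked.

## The synthetic generator

`simulate_mr()` draws, per SNP, a frequency, a true exposure effect
$\gamma_j$, and a direct effect $\alpha_j$ (zero, balanced, or
directional), sets the true outcome effect to $\theta\gamma_j + \alpha_j$,
and observes both betas with analytic unit-variance-phenotype standard
errors $(2f(1-f)n)^{-1/2}$. It emulates: arbitrary instrument counts,
configurable pleiotropy, planted outliers, palindromic allele pairs, and
exact determinism by seed. It does **not** emulate LD between instruments,
winner's curse, sample overlap, non-normal summary noise, or violations of
InSIDE ($\alpha_j$ is always independent of $\gamma_j$). Calibration
results on synthetic data therefore speak to estimator correctness under
the standard two-sample MR model, not to robustness against those
real-data complications.

The battery defaults (chosen once as realistic study conditions): 20
instruments, $\gamma \sim N(0.12, 0.03)$, frequencies uniform on
(0.1, 0.9), both sample sizes 5×10⁵ (strong instruments), causal effect
−0.3 for causal scenarios, balanced pleiotropy SD 0.01, directional mean
0.02, single outlier shifted 10 outcome SEs. The `paper_like` scenario
mirrors the fixture's dimensions (4 SNPs, θ = −0.6, exposure-effect
magnitudes 0.022–0.059, n = 7,354 / 1,299,010); note that with the
unit-variance SE model n = 7,354 yields exposure SEs of 0.015–0.03,
larger than the printed 0.004–0.006 — the metabolite GWAS betas are
evidently not on a unit-variance scale — so `paper_like` reproduces the
published dimensions, not the published instrument strength.

Calibration sizes used by the test suite (chosen to give Monte-Carlo
error well inside each tolerance): 1000 null datasets with 300 PRESSO
replicates each for the global-test type-I error; 200 replicates for IVW
coverage and for the planted-outlier study; 100 random instances for the
weighted-median oracle comparison; 60 replicates for the pleiotropy-mode
checks of the Egger intercept.

## Numerical and design choices

* **Ties and determinism.** Clumping sorts by ascending p-value with
  lexicographic SNP-ID tie-breaks; harmonized output is ordered by SNP ID;
  every stochastic routine takes an explicit seed, runs under a restored
  RNG state, and records the seed in its output.
* **Weighted-median interpolation.** The quantile curve is piecewise
  linear in the standardized cumulative weights; values of $s = 0.5$
  outside $[s_1, s_J]$ return the extreme ratio. With two or more
  positively weighted instruments $s_1 = p_1/2 < 0.5 < 1 - p_J/2 = s_J$
  always holds, so the clamp is a defensive boundary rather than a
  reachable code path; a single dominant weight instead pulls the
  interpolated estimate arbitrarily close to its ratio.
* **Egger standard errors.** Coefficient SEs use the inverse-variance
  weight covariance inflated by `max(1, sigma)` with
  `sigma² = RSS_w/(J-2)`, so under-dispersion never shrinks them below
  the fixed-weight SE.
* **MR-PRESSO p-values.** The global p uses the add-one estimator
  `(1 + #[RSS* ≥ RSS])/(n_sim + 1)`, which can never be zero. Per-SNP
  outlier p-values use the plain empirical proportion before Bonferroni
  adjustment: with the add-one form the smallest achievable adjusted p
  is `J/(n_sim + 1)`, which at 20 SNPs and 1000 replicates (0.02) leaves
  little room, and at 300 replicates (0.066) can never clear 0.05.
* **Degenerate inputs.** Zero exposure betas make the Wald ratio
  undefined (an error, not NA); perfect fits give `sigma = 0` and fall
  back to the fixed-weight SE; simulated p-values are floored at 1e-300
  to stay in (0, 1].
* **Known limitation.** For a single outlier shifted by $k$ SEs among
  $J$ equally weighted instruments, the probability that removing it
  leaves the corrected IVW estimate *strictly* closer to the truth is
  approximately $\Phi(k\sqrt{J-1}/(2J))$ — about 0.86 at $k = 10$,
  $J = 20$, independent of instrument strength — because the outlier's
  pull on the full estimate is comparable to the corrected estimate's
  own sampling noise. Outlier *detection* at that shift is essentially
  certain; guaranteed improvement requires a grosser outlier or fewer
  instruments.
* **Diagnostics are advisory.** Significant pleiotropy or heterogeneity
  flags the run but does not abort it (strict mode is available),
  mirroring how applied MR studies report diagnostics alongside
  estimates.

## Worked run

```{r, eval = FALSE}
report <- run_mr_pipeline(run_config())
report
```

The default configuration analyses the packaged dataset: four instruments
selected and harmonized, no pleiotropy or heterogeneity flags, IVW log-OR
about −0.63 (OR ≈ 0.53, 95% CI ≈ 0.35–0.82) and weighted-median log-OR
about −0.60 — a genetically predicted increase in blood pyroglutamine
associated with reduced odds of COVID-19, matching the published analysis
within input-rounding tolerance.
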