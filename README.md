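# mrpipe

Two-sample Mendelian randomization (MR) from GWAS summary statistics, built
for analysts who want a tested, reproducible pipeline rather than a chain of
ad-hoc scripts: instrument selection, allele harmonization, causal-effect
estimation and the standard pleiotropy/heterogeneity/outlier diagnostics,
with a synthetic-data generator whose known ground truth lets every stage be
calibration-tested offline.

The package ships, as a worked fixture, the published summary statistics
linking blood pyroglutamine to COVID-19 susceptibility: four genetic
instruments from a blood-metabolite GWAS (per-SNP n = 7,354) and their
effects in the COVID-19 Host Genetics Initiative release-4 GWAS (14,134
cases, 1,284,876 controls).

## The statistics

For instrument $j$ with exposure association $(\hat\beta_{Xj}, se_{Xj})$ and
outcome association $(\hat\beta_{Yj}, se_{Yj})$, each variant's Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal log odds
ratio $\theta$. The estimators and diagnostics:

- **IVW**: $\hat\theta = \sum w_j\hat\theta_j/\sum w_j$,
  $w_j = se(\hat\theta_j)^{-2}$; multiplicative random-effects SE
  $(\sum w_j)^{-1/2}\max(1, \sqrt{Q/(J-1)})$.
- **Weighted median**: interpolated 50th percentile of the
  weight-standardized ratio distribution; parametric-bootstrap SE.
- **MR-Egger**: weighted regression with free intercept; the intercept
  (t-test, $J-2$ df) is the directional-pleiotropy diagnostic.
- **Cochran's Q** about the IVW and Egger fits; **MR-PRESSO**
  simulation-based global, outlier and distortion tests; **leave-one-out**
  and per-SNP forest tables.
- Instrument strength: $R^2$ (z-based or allele-frequency form) and
  $F = R^2(N-2)/(1-R^2)$, flagged below the conventional $F < 10$.

## Worked example

```r
library(mrpipe)
report <- run_mr_pipeline(run_config())
report
```

```
Two-sample MR run: blood pyroglutamine -> COVID-19 susceptibility
  instruments: 4 selected, 4 harmonized, 0 dropped
  variance explained: 3.95%

Estimates:
# A tibble: 3 × 8
  method          nsnp   beta    se    pval    or or_lci95 or_uci95
  <chr>          <int>  <dbl> <dbl>   <dbl> <dbl>    <dbl>    <dbl>
1 IVW                4 -0.630 0.219 0.00400 0.533   0.347     0.818
2 WeightedMedian     4 -0.603 0.257 0.0189  0.547   0.331     0.905
3 Egger_slope        4 -1.81  0.689 0.119   0.164   0.0424    0.631

Diagnostics:
# A tibble: 2 × 4
  method       q  q_df q_pval
  <chr>    <dbl> <int>  <dbl>
1 IVW      3.47      3  0.324
2 MR_Egger 0.260     2  0.878
  Egger intercept  0.044 (se 0.025, p = 0.215): no significant pleiotropy
  MR-PRESSO global p = 0.416, 0 outlier(s)
```

Reading the output: none of the diagnostics fires (Egger intercept p and
both heterogeneity p-values above 0.05, no PRESSO outliers), so the four
variants behave as valid instruments. The IVW log odds ratio of −0.630
(OR 0.53, 95% CI 0.35–0.82, p = 0.004) and the concordant weighted median
(−0.603) indicate that genetically higher blood pyroglutamine predicts
lower odds of COVID-19. The published analysis reports IVW −0.644
(OR 0.525, 95% CI 0.346–0.798); the small differences come from the
3-decimal rounding of the printed inputs the fixture transcribes.

Other entry points: `load_fixture()`, `read_summary_stats()` /
`write_summary_stats()`, `select_instruments()`, `harmonize()`,
`mr_ivw()` / `mr_weighted_median()` / `mr_egger()`, `cochran_q()`,
`mr_presso()`, `leave_one_out()`, `simulate_mr()` / `scenario_battery()`.
A thin shell wrapper lives at `inst/cli/mr-pipeline.R`
(`run`, `simulate`, `fixtures` subcommands).

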