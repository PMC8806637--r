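# irgpsurv

Rank-based immune-related gene-pair (IRGP) prognostic modelling for
censored survival outcomes, with the published 11-pair clear-cell renal
cell carcinoma (ccRCC) signature and a united clinical-stage + risk-score
nomogram.

## The problem

Gene-expression prognostic signatures built from absolute expression
levels travel poorly between platforms: RNA-seq FPKM and microarray
intensities live on different scales, and cross-platform normalisation is
fragile. A gene-*pair* signature sidesteps this: for a pair of genes
(a, b) measured in the same sample, the feature is the binary indicator

```
IRGP(a, b) = 1  if expr(a) > expr(b),   0 otherwise
```

which depends only on the within-sample ranking and is therefore invariant
to any strictly increasing rescaling of that sample's values — no
normalisation needed. The package implements the full workflow around this
primitive, for statisticians and computational biologists building or
validating pair-based survival signatures:

1. **Gene filter** — immune genes with median absolute deviation
   (MAD) > 0.5 across samples, per platform.
2. **Pair construction** — all gene pairs, indicator per sample; pairs kept
   only when neither indicator class reaches 80% of samples, and only when
   they survive this filter on *every* platform.
3. **Signature selection** — per-pair univariate Cox screen (Wald
   p < 0.001), then LASSO-penalised Cox regression (10,000 iteration cap,
   10-fold cross-validated penalty) on the training half of a seeded 7:3
   split.
4. **Risk score** — `score = Σ_k IRGP_k × coef_k`, dichotomised at each
   cohort's median (high iff strictly above).
5. **Evaluation** — Kaplan–Meier curves and log-rank tests, IPCW
   cumulative/dynamic AUC at 1/3/5 years, Harrell's C-index, and
   uni/multivariable Cox models over age, gender, grade, stage and score.
6. **United model** — a two-covariate Cox fit (ordinal stage + risk score)
   expressed as a nomogram (0–100 point scales, Breslow baseline survival
   lookup) with quantile-binned calibration tables.

A synthetic-cohort generator (`simulate_cohorts()`) produces
multi-platform expression with known true pairs driving an exponential
hazard, so every stage can be tested against a recoverable ground truth.

## Worked example

Score a patient under the packaged published signature:

```r
library(irgpsurv)
sig <- kirc_signature()
print(sig)
#> irgp_signature: 11 pairs (provenance: published ccRCC 11-pair signature)
#>     gene_a gene_b coefficient
#> 1   PSMD11  NFKB1  0.01149287
#> 2   PSMD11  F2RL1  0.15069916
#> ...
#> 11   PLAUR    TEK  0.15416274
```

A patient whose only positive indicator is PSMD11 > F2RL1 scores exactly
that pair's coefficient, 0.150699162881823; a patient with every indicator
positive scores the coefficient sum 0.2870367.

Run the whole pipeline on a simulated two-platform cohort:

```r
cfg <- pipeline_config(
  simulation = simulation_config(n_samples = c(200, 100), n_genes = 60,
                                 n_immune_genes = 30, n_true_pairs = 4,
                                 true_log_hazard_ratios = rep(0.8, 4),
                                 censoring_rate = 0.35,
                                 baseline_hazard = 0.08, seed = 17L),
  horizons = c(1, 3))
mf <- run_pipeline(cfg)
#> stage simulate: 2 platform(s)
#> stage mad_filter: 30 immune genes retained on all platforms
#> stage pairs: 435 built, 198 candidates after prevalence+intersection
#> stage screen: 4 of 198 pairs at p < 0.001
#> stage lasso: signature of 4 pairs
print(mf$evaluations$training)
#> evaluation_report
#>   log-rank: chi2 = 39.406, p = 3.44e-10
#>   AUC: auc_1 = 0.762, auc_3 = 0.803
#>   C-index: 0.7071
round(unlist(mf$united_cindex), 4)
#>    training validation1 validation2
#>      0.7524      0.7177      0.6758
```

The funnel reads: 30 immune genes pass the MAD filter on both platforms,
giving 30·29/2 = 435 pairs, of which 198 are prevalence-balanced on both
platforms; 4 pass the univariate screen and all 4 carry non-zero LASSO
coefficients. The high/low split separates survival strongly (log-rank
p ≈ 3×10⁻¹⁰), and adding clinical stage lifts the training C-index from
0.71 to 0.75 — the united model outperforms the score alone.

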