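---
title: "Gene-pair prognostic signatures: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair prognostic signatures: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irgpsurv)
```

## The model

The unit of information is the within-sample comparison of two genes:
`IRGP(a, b) = 1` iff gene *a*'s expression strictly exceeds gene *b*'s in
that sample, else 0 (ties score 0 — equality falls in the "otherwise"
branch of the rule, and with continuous expression ties are measure-zero
anyway). Because the indicator depends only on the ranking of two values
measured in the *same* sample, it is invariant to any strictly increasing
per-sample transform: linear rescaling, log transforms, rank
normalisation, platform offsets. That invariance is the reason a pair
signature fitted on RNA-seq FPKM can be applied unchanged to log-scale
microarray intensities, and it is asserted bit-for-bit in the test suite
over random monotone warps.

A prognostic signature is an ordered set of oriented pairs with
coefficients; the risk score of a sample is the linear functional

$$\mathrm{score} = \sum_k \mathrm{IRGP}_k \times \beta_k,$$

with the coefficients taken from an L1-penalised Cox fit. Scores are
dichotomised at a median cutoff (high iff strictly above; ties go low).
Each cohort is split at its own median by default — the alternative, a
fixed training-cohort cutoff, is available by passing `cutoff=` to
`median_stratify()`; we default to per-cohort medians because validation
cohorts on other platforms have no comparable absolute score scale, and
the per-cohort rule is self-calibrating.

## Thresholds and defaults

| parameter | default | where |
|---|---|---|
| MAD gene filter | > 0.5, strict | `filter_config()` |
| MAD scaling constant | 1 (bare median of absolute deviations) | `filter_config(mad_constant=)` |
| pair prevalence bound | majority class < 80%, strict | `filter_config()` |
| univariate screen | Wald p < 0.001 | `univariate_cox_screen()` |
| LASSO | 10,000 iteration cap, 10-fold CV, `lambda.min` | `lasso_cox_select()` |
| training split | u ≤ 0.7 → training (ties at the threshold included) | `split_cohort()` |
| multivariate entry | univariate p ≤ 0.001 | `multivariate_cox()` |
| nomogram covariate significance | p < 0.05 | `pipeline_config()` |
| evaluation horizons | 1, 3, 5 years | `evaluate_risk_model()` |

Notes on the less obvious ones:

* **MAD without the 1.4826 consistency constant.** The filter is a plain
  variability screen against a fixed bound of 0.5, not a robust scale
  estimate, so the bare median of absolute deviations is the natural
  reading; the normal-consistency constant is exposed via `mad_constant`
  for anyone who wants `stats::mad()` semantics.
* **MAD scale.** By default the MAD is computed on the log2 scale
  (linear-scale cohorts are log2(x+1)-transformed internally for the
  filter only). A threshold of 0.5 is only meaningful on a log-like
  scale; on raw FPKM nearly every gene passes. `mad_scale = "native"`
  disables this. Pair indicators are identical either way.
* **log2(x+1), not log2(x).** The pseudocount keeps zero FPKM finite and
  is strictly increasing, so indicators are unaffected.
* **Prevalence bound strict at 0.8.** A pair where 80% or more of samples
  share one indicator value is excluded ("less than 80%" read as a strict
  bound on the majority class); the filter is idempotent.
* **Gene filter across platforms.** A gene must pass the MAD filter on
  *every* platform used for the intersection; candidate pairs must
  survive the prevalence filter on every platform.
* **LASSO cross-validation.** The selection rule is the CV-minimum
  partial-likelihood deviance with seeded fold assignment. The iteration
  cap (10,000) bounds the coordinate-descent optimiser. A single
  screened pair cannot be cross-validated over a penalty path, so it
  falls back to the unpenalised Cox coefficient.
* **Ties in event times** use Efron's approximation throughout; screen
  p-values are Wald (matching standard forest-plot output).

## The synthetic generator

`simulate_cohorts()` emulates the data regime the workflow targets: a
shared gene universe measured on several platforms, an immune-gene
subset, survival driven by known pair indicators. Per platform it draws
log2 expression as per-gene lognormal base signal plus Gaussian noise,
then applies a platform-specific affine map on the log scale (positive
scale, arbitrary offset — strictly increasing, so the ground-truth
indicators are untouched; this is asserted in tests). Platform 1 is
emitted on log2 scale, later platforms on linear scale so the ingestion
path's log2 step is exercised. True pairs are disjoint immune-gene pairs
whose base means are equalised, making each indicator close to
Bernoulli(1/2) — informative, and safely inside the prevalence bounds.

Survival is exponential with rate
`baseline_hazard × exp(Σ β_k IRGP_k + stage_effect × (stage − 1))`;
exponential rather than Weibull because the closed-form survivor function
gives exact analytic checks (the null-cohort KM is compared against
`exp(−λt)` in the suite). Censoring is independent uniform on [0, c] with
c solved by bisection from the exact expectation
`E[(1 − e^{−λc})/(λc)]` so the realised censored fraction matches the
target; the empirical event fraction is verified within ±5 percentage
points over seed batches. Stage is ordinal 1–4 with marginals
0.50/0.10/0.22/0.18 (training-cohort composition of the motivating
study); age, gender and grade are simulated as nuisance covariates with
no hazard effect by default. Defaults (~540 + ~100 samples, ~67%
censoring) mirror a two-platform renal-cancer regime.

What the generator does **not** emulate: gene–gene correlation structure,
library-size or GC artefacts, non-proportional hazards, informative
censoring, or annotation mismatches between platforms. Passing tests
therefore demonstrate correctness of the algorithms and their invariances
— not that the workflow's operating characteristics (AUC, C-index) on
real tumour cohorts will match the simulated ones.

## Numerical and statistical choices

* **Time-dependent AUC** is the cumulative-case / dynamic-control
  estimator with inverse-probability-of-censoring weights from the KM
  estimate of the censoring distribution (cases weighted by 1/G(T−),
  controls by 1/G(horizon); score ties count ½). When censoring is absent
  it reduces *exactly* to the case/control pairwise count, which is how
  it is tested. Published pair-signature studies often use a
  nearest-neighbour smoothed KM variant of the time-dependent ROC; the
  two estimators agree to a few hundredths but not bit-for-bit, and no
  smoothing span is needed here.
* **Harrell's C** is computed from the concordance pair counts of the
  `survival` package, with comparable pairs defined by censoring order
  and score ties counted ½; an exhaustive O(n²) double-loop oracle in the
  test suite checks exact equality on random censored data, including
  tied times and tied scores.
* **The united model** is a two-covariate Cox fit of ordinal stage (1–4)
  plus risk score — the pipeline always fits this pair and records the
  multivariate entry p-values in the manifest rather than choosing
  covariates dynamically. Stage and grade enter Cox models as ordinal
  numerics (one hazard ratio per factor); categorical coding would need a
  different forest-plot layout.
* **Nomogram points** rescale each covariate's contribution
  β·(x − x_ref) so the widest-range covariate (over the training data)
  spans exactly [0, 100]; x_ref is the training value minimising β·x, so
  points are non-negative on the training range while validation samples
  may exceed 100. Predicted survival is S0(t)^exp(βᵀx) with the Breslow
  baseline; the lookup is tested against `survival::survfit()` on new
  data.
* **Calibration** bins subjects into predicted-survival quantiles
  (tertiles by default — small validation cohorts do not support more
  granular bins) and compares each bin's mean prediction with its KM
  estimate at the horizon; bins whose KM cannot reach the horizon are
  flagged, never dropped silently.

## Problem sizes in the test suite

The suite exercises: rank invariance on 50 random cohorts × 10 monotone
transforms; metric/oracle equality on 100+ random censored datasets
(n ≤ 30 for C, n ≤ 50 for AUC); screen calibration on 10 runs × 1,000
null pairs at n = 400; LASSO recovery on 20 runs of 5 true + 95 null
pairs at n = 400; calibration self-consistency at n = 2,000. These sizes
give stable Monte-Carlo margins at the asserted bounds while keeping the
full suite under a minute.

## Known limitations

* **Marginal screening attenuates joint effects.** With several true
  pairs active, the univariate Cox screen estimates each pair's
  *marginal* hazard ratio, which is attenuated relative to the joint
  coefficient (non-collapsibility of the Cox model): five active pairs
  with joint log-HR 0.7 present marginally at roughly 0.56. Screening
  power calculations must be made against the marginal, not the
  generating, effect size.
* Orientation-reversed scoring through `risk_score()` complements the
  stored indicator (1 − v), which assumes tie-free expression;
  `signature_pairs()` evaluates the signature's own orientation directly
  and is exact under ties.
* The LASSO path is deterministic given the fold seed, but signature
  membership near the CV optimum can be sensitive to fold assignment on
  small cohorts; the seed is part of the pipeline configuration and
  recorded in the manifest.
* Proportional hazards is assumed, not tested; no competing risks; no
  time-varying effects; calibration beyond the observed follow-up is
  undefined (and flagged).
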