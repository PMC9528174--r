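# bioagestack

Biological age (BA) estimation from routine physical-examination
biomarkers, built for one methodological question: **how much of a BA
model's apparent signal survives once you control its overfitting?**

A BA model regresses chronological age (CA, 45–90 y here) on a biomarker
panel; the value of the prediction lies in its residuals — people whose
markers run "older" than their calendar age. Boosted-tree BAs can be tuned
so that two models look identical on a held-out test set while one of them
fits the training set almost perfectly. Since full-sample BA is usually
predicted by the model trained on the training set, that hidden
overfitting contaminates every downstream association analysis. This
package provides the full pipeline to study the effect on synthetic
cohorts:

- a seeded **synthetic examination-cohort generator** (13 continuous
  biochemical markers, 4 urine dipsticks, anthropometry with derived BMI,
  7 disease flags) with a hidden per-person aging offset `delta` planted
  into markers and disease risk — the recoverable ground truth;
- **missingness injection** (MCAR at exact global counts; MNAR at exact
  per-variable counts with upper-tail value bias) and a masked-entry
  benchmark of five imputers: column mean, k-nearest neighbours,
  chained-equation multiple imputation, round-robin linear regression
  (RRLR), and a dense symmetric autoencoder;
- a **two-step feature screen**: cross-validated lasso, then a two-tailed
  Pearson correlation-with-age filter;
- a **stacked BA (STK-BA)**: five tree-ensemble base models fused through
  out-of-fold level-2 features and a spline (GAM) meta-model, with an
  auditable no-leakage contract, next to deliberately **moderate and
  overfit boosted-tree contrasts**;
- **association batteries** linking each BA variant to A Body Shape Index
  (ABSI = WC / (BMI^(2/3)·Height^(1/2))), waist-to-height ratio (WHtR),
  three-category disease counts (linear + Poisson) and per-disease
  logistic odds ratios, crude (Model 1) and covariate-adjusted (Model 2).

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on result types.

## Worked example

```r
library(bioagestack)
library(dplyr)

coh <- generate_cohort(cohort_spec(n_participants = 5000, seed = 1))
an  <- drop_oracle(coh)   # the hidden aging offset never enters estimation

# feature screen: lasso + Pearson-vs-age
sel  <- select_features(an, config = selection_config(seed = 1))
kept <- sel$feature[sel$kept]

# stacked BA vs an overfit boosted contrast
parts <- split_cohort(an, train_fraction = 0.8, seed = 1)
stk <- stack_predict(parts$train, parts$test, kept, folds = 10, seed = 1)
ov  <- fit_boost_contrast(parts$train, parts$test, kept, "overfit", seed = 1)

glance(stk)[c("train_rmse", "test_rmse", "rmse_gap", "test_r")]
#> # A tibble: 1 × 4
#>   train_rmse test_rmse rmse_gap test_r
#>        <dbl>     <dbl>    <dbl>  <dbl>
#> 1       7.10      7.26    0.160  0.640
glance(ov)[c("train_rmse", "test_rmse", "rmse_gap", "train_r")]
#> # A tibble: 1 × 4
#>   train_rmse test_rmse rmse_gap train_r
#>        <dbl>     <dbl>    <dbl>   <dbl>
#> 1       2.51      7.52     5.01   0.971

# Model-2-adjusted association of each BA with ABSI (t statistic):
risk_indicator_battery(stk, an, "absi", "model2") |>
  filter(term == "absi") |> pull(statistic)
#> [1] 33.07
risk_indicator_battery(ov, an, "absi", "model2") |>
  filter(term == "absi") |> pull(statistic)
#> [1] 22.31
```

Read: the stacked BA is train/test-consistent (gap 0.16 y) while the
overfit booster shows a 5 y gap despite near-identical test error — and
the overfit BA's adjusted association with ABSI is visibly attenuated
(t = 22.3 vs 33.1). The same pattern holds for WHtR, disease counts and
most individual diseases.

The imputation benchmark is one call:

```r
bench <- run_benchmark(
  an,
  lapply(c(.05, .1, .2, .3), \(r) missingness_profile("MCAR", global_rate = r)),
  c("mean", "knn", "round_robin_regression", "chained_multiple", "autoencoder"),
  folds = 10, seed = 1
)
summarize_benchmark(bench)   # fold mean ± SD of masked-cell MSE / R² per condition
autoplot(bench)              # benchmark curves by mechanism and metric
```

On the default cohort RRLR wins at every MCAR rate while the autoencoder
degrades most slowly as the missing rate grows — the qualitative ranking
that motivates using regression-based imputation at low missing rates and
representation-learning imputers at high ones.

`run_pipeline(default_run_config())` chains
generate → benchmark → screen → train/stack → associate, writes every
stage artifact as CSV plus a digest manifest, and `render_report()`
assembles a Markdown report.

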