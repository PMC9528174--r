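---
title: "Biological age from examination biomarkers: models, imputation and overfitting diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biological age from examination biomarkers: models, imputation and overfitting diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bioagestack)
```

## The problem

Biological age (BA) is a biomarker-derived summary of physiological aging
intended to carry information beyond chronological age (CA). A BA model is
usually a regression of CA on a panel of routine biomarkers; the interesting
part of the prediction is its residual structure — people whose markers look
"older" than their calendar age. Three practical problems dominate applied
work with examination data, and this package addresses all three on fully
synthetic cohorts:

1. **Missing values.** Examination tables are incomplete; the choice of
   imputer changes downstream model quality. We benchmark five imputers
   under controlled missing-completely-at-random (MCAR) and
   missing-not-at-random (MNAR) removal with exact-count contracts, scoring
   only the cells that were removed.
2. **Estimator construction.** We fuse five tree-ensemble regressors
   through a stacked ensemble whose second level is trained exclusively on
   out-of-fold predictions, with a deliberately simple spline meta-model.
3. **Overfitting and association stability.** Boosted-tree BAs can be
   tuned to look identical on a held-out test set while fitting the
   training set almost perfectly. Because full-sample BA is usually
   predicted by the model *trained on the training set*, that hidden
   overfitting leaks into every downstream association analysis. The
   package builds moderate and overfit boosted contrasts and measures how
   covariate-adjusted associations with health-risk indices and disease
   attenuate as overfitting grows.

## The synthetic cohort generator

No suitable public examination cohort exists at this scale, so the
generator is a first-class, tested module, and everything downstream runs
on its output.

Each participant has CA drawn from a normal distribution centred mid-range
(SD 10 y) truncated to 45–90 y, a gender (the female fraction rises mildly
with age, logit slope 0.02/y, emulating differential survival), and a
hidden per-person aging offset `delta ~ N(0, 4 y)` with a small negative
shift (−0.5 y) for women. `delta` is the planted truth: a marker with age
slope `b` responds to *effective age* CA + delta, so two people of equal CA
differ systematically when their `delta` differs. Waist circumference and
urine protein carry additional per-year-of-delta loadings so that the
aging rate reaches body-shape indices beyond CA.

Continuous markers follow
`mean + slope·(EA−65) + quad·(EA−65)² + shift·female + loading·F_block + noise`,
with block latent factors giving realistic inter-marker correlation
(SBP–DBP ≈ 0.5, TC–LDL ≈ 0.7, SGPT–SGOT ≈ 0.7, weight–waist ≈ 0.6);
binary dipstick markers are Bernoulli-logistic in the same linear
predictor. Three dipsticks (sugar, ketone, occult blood) are generated
with *no* signal at all: they are the candidates the feature screen is
expected to discard. Seven disease flags are Bernoulli with logit
`intercept + beta_age·(CA−65) + beta_delta·delta + beta_family·family`;
`beta_delta` (0.045–0.08 per year) is what a good BA should recover.
Intercepts were set so disease prevalences fall in the 5–15% range typical
of examination reports for this age band.

What the generator does *not* emulate: measurement rounding, skewed marker
distributions (triglycerides are log-normal in real data), informative
examination scheduling, and longitudinal correlation. Passing tests
therefore demonstrate correctness of the machinery and qualitative
orderings, not quantitative transfer to any real cohort.

One deliberate consequence of the design: BMI is *exactly* `weight/height²`
(the table invariant), so within the 22-candidate screen BMI is locally an
exact linear combination of height and weight. A lasso is entitled to zero
such a redundant column, and at the default scale it usually does — the
synthetic cohort therefore keeps 18–19 of 22 candidates depending on seed,
whereas a non-degenerate design keeps exactly 19. The candidate
bookkeeping (22 − 3 null markers) is accordingly measured on a
non-collinear screen fixture; the default-cohort count is reported
separately. Real data avoid the degeneracy through measurement noise.

## Missingness injection

`inject_missing()` guarantees exact removal counts: `round_half_up(rate·n)`
per column under MNAR and `round_half_up(rate·cells)` over the whole
19-column maskable block under MCAR (the 17 biochemical/urine markers plus
height and weight; age, gender, waist, derived BMI, disease flags and
family history are never masked). Under MNAR, cells are drawn without
replacement with weight `exp(strength · z_rank)` on the standardized
within-column value rank — a genuinely not-at-random mechanism whose
strength is tunable, implemented by weighted sampling so the printed target
counts are hit exactly rather than in expectation. The default MNAR profile
averages about 5% of the block, concentrated in the lipid panel and
transaminases.

## The five imputers

All imputers work on the standardized scale (training-row means and
variances only), are fitted on training rows only, never touch observed
cells, and threshold binary predictions at 0.5 (a prediction of exactly 0.5
maps to 0). Always-observed age and gender join the predictor block of
every conditional method; they are never imputation targets.

- **mean** — training-column mean; the information-free baseline.
- **knn** — NA-aware Euclidean distance (squared differences averaged over
  jointly observed coordinates); neighbour count tuned over {3, 5, 10, 20}
  on training-row masked cells.
- **round-robin linear regression** — columns cycled in ascending
  missing-rate order, each incomplete column regressed on all others and
  overwritten, until the largest standardized change falls below 1e-3 or
  10 cycles; non-convergence is a warning, not an error.
- **chained-equation multiple imputation** — the same cycle with Gaussian
  residual-SD noise added to predictions; m = 5 completed tables are
  averaged (continuous) or majority-voted (binary, tie → 0).
- **autoencoder** — a dense symmetric network (19→12→6→12→19 by default,
  tanh, linear output) trained with Adam (200 epochs, batch 64, learning
  rate 1e-3) on a reconstruction loss restricted to observed entries;
  missing inputs enter as the training mean and are replaced by the decoder
  output. Implemented directly in R matrix algebra — the model is small
  enough that no framework is needed.

Scoring is masked-cell MSE and the coefficient of determination
(1 − SS_res/SS_tot about the masked-cell truth mean) — the determination
form rather than squared correlation, because it penalizes biased
imputations and pairs coherently with MSE. The benchmark's "tenfold
cross-validation" is implemented as ten seeded replicate removal draws on
the fixed 80/20 split: the split defines which masked cells are scored
(test rows), and the fold-to-fold variation comes from the removal draw.
Within a fold, the removal seed is shared across the whole rate grid, so
an MCAR mask at a lower rate is an exact prefix — a nested subset — of the
mask at a higher rate. Comparisons along the rate axis are therefore
paired: how an imputer *degrades* with the missing rate is measured on
growing supersets of the same cells rather than independent draws, which
at these sample sizes would bury the degradation signal in masking noise.

## Feature screen

Lasso of CA on the 22 standardized candidates with the minimum-CV-error
lambda (10 folds), then a two-tailed Pearson test of every candidate
against CA; a feature is kept iff its lasso coefficient is nonzero *and*
P ≤ 0.05. Binary candidates use the same formula (point-biserial).
Constant columns abort the screen rather than disappearing silently.

## Stacked BA and the overfit contrasts

The training partition (80%) is split into 10 folds. Each of the five base
models — four gradient-boosted-tree flavours and extremely randomized
trees — is fitted 10 times; the out-of-fold predictions form its level-2
training feature and the mean of the 10 fold-models' test-set predictions
forms its level-2 test feature. The meta-model (default: spline additive
model, `s()` per base model) sees only level-2 features. Full-sample BA
keeps the no-leakage convention — training rows are always scored through
out-of-fold features — because the whole point of the construction is that
no participant's BA is produced by a model that saw that participant. The
fold bookkeeping is retained in the fitted object and `audit_no_leakage()`
re-verifies the contract after the fact. A random-forest meta-model is
available but warned about: it reintroduces the train/test gap.

The boosted-tree defaults (for example the deep flavour: eta 0.05, depth 6,
300 rounds, min_child_weight 10, 80% row/column subsampling) were chosen so
each base generalizes competitively at the default 5,000-row scale on a
single thread; the shallow flavour (depth 2) plays the role of a classic
gradient-boosting machine.

`fit_boost_contrast()` builds the diagnostic pair: **moderate** reuses the
stack's deep-booster configuration; **overfit** grid-searches ten
higher-capacity configurations (continued boosting of the moderate
configuration, and deeper trees with leaf-weight shrinkage `lambda` 10–20)
and returns the one with the highest training-set Pearson r among those
whose test MAE stays within 1% (relative) of the moderate model's. If no
configuration satisfies the constraint the search warns and reports the
closest, flagged `constraint_met = FALSE` — the failure is surfaced, never
silently accepted. Both contrasts predict the full sample from the
training-set model, reproducing on purpose the leakage being studied.

## Association batteries

- ABSI = WC / (BMI^(2/3)·Height^(1/2)) and WHtR = waist/height, computed in
  coherent units (metres), as continuous exposures and as full-sample
  quintiles (Q1 reference; ties broken by stable participant order so the
  partition is deterministic and group sizes differ by at most one).
- Disease counts: linear BA increments for 1 and 2+ diseases versus
  disease-free, and Poisson regression of the raw 0–7 count on BA. CA
  enters as a covariate, not an offset, matching "adjusted for CA".
- Per-disease logistic fits, reporting the OR per BA year with Wald 95%
  intervals on the log-odds scale; separation is flagged in the output.

Model 1 is crude; Model 2 adjusts for CA, BMI and family disease (risk
indicators) or CA and family disease (disease batteries). P-values are
two-tailed; no multiplicity correction is applied, which matches the
analysis design this package mirrors but should be kept in mind when many
diseases are scanned.

## Numerical and design choices

- Exact-count rounding is round-half-up, so removal counts are testable
  integers.
- Quintile ties: stable participant order (deterministic partitions).
- Pearson intervals are Fisher-z; published-style correlation *ranges* are
  reported as 95% CIs.
- Rank-deficient linear fits inside the imputers zero the unidentifiable
  coefficients instead of propagating NA.
- GLM fits in the batteries run with a tightened convergence epsilon
  (1e-12) so estimates agree with an independent IRLS reference to 1e-8.
- The benchmark records wall-clock per imputation but no test or
  acceptance quantity depends on it (hardware-bound).
- Poisson "truth" for the planted disease-count slope: the count is a sum
  of seven Bernoullis, not an exact log-linear model, so coverage checks
  target the pseudo-true slope computed by a large Monte-Carlo fit rather
  than the planted logistic coefficient (the per-disease log-OR check uses
  the planted value, which is exact).

## Problem sizes

The package's reference conditions are 5,000-participant cohorts, the MCAR
grid 5/10/20/30% with ten replicate removal draws, tenfold stacking, and
ten seeded cohorts for the consistency and attenuation checks; coverage
checks use 200 cohorts of n = 2,000. These sizes were chosen as the point
where the planted orderings are stable without requiring the original
scale (tens of thousands of rows), and the same sizes are what the test
suite and the acceptance script run.

## Limitations

- Orderings (which imputer wins, how strongly associations attenuate) are
  functions of the generator's correlation structure; magnitudes are not
  transferable to real cohorts.
- The overfit search is a small grid, not an adversarial optimum; on very
  small cohorts the test-stability constraint may be unsatisfiable, and
  the object says so.
- No survival outcomes are modelled; mortality-linked validation of BA is
  out of scope by design.
- Feed-forward and convolutional base learners are not implemented; the
  model zoo covers linear, spline, kernel, boosting and randomized-tree
  families.
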