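Package: bioagestack
Title: Stacked-Ensemble Biological Age with Imputation Benchmarking and
    Overfitting-Stability Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating biological age (BA) from routine physical
    examination biomarkers in middle-aged and elderly cohorts. Provides a
    seeded synthetic-cohort generator with planted age, gender and latent
    aging-rate structure; injectors for missing-completely-at-random and
    missing-not-at-random gaps with an exact-count contract; five missing
    value imputers (column mean, k-nearest-neighbour, chained-equation
    multiple imputation, round-robin linear regression and an autoencoder)
    with a masked-entry cross-validated benchmark; a lasso plus Pearson
    correlation feature screen; a stacked ensemble BA built from
    out-of-fold base-model predictions with a spline meta-model, together
    with deliberately overfit boosted-tree contrasts; and association
    batteries linking BA to A Body Shape Index, waist-to-height ratio,
    disease counts and specific diseases under crude and covariate-adjusted
    models. All user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    glmnet,
    mgcv,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
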