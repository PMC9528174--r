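test_that("fit metrics agree with a brute-force reference", {
  withr::with_seed(1, {
    pred <- rnorm(20, 70, 5); truth <- rnorm(20, 70, 5)
  })
  fm <- fit_metrics(pred, truth)
  # independent element-by-element accumulation
  se <- 0; ae <- 0
  for (i in 1:20) { se <- se + (pred[i] - truth[i])^2
                    ae <- ae + abs(pred[i] - truth[i]) }
  expect_equal(fm$rmse, sqrt(se / 20), tolerance = 1e-9)
  expect_equal(fm$mae, ae / 20, tolerance = 1e-9)
  sst <- sum((truth - sum(truth) / 20)^2)
  expect_equal(fm$r2, 1 - se / sst, tolerance = 1e-9)
  expect_equal(fm$pearson_r,
               sum(scale(pred) * scale(truth)) / 19, tolerance = 1e-9)
  expect_true(fm$r_low <= fm$pearson_r && fm$pearson_r <= fm$r_high)
  expect_gte(fm$rmse, fm$mae)
})

test_that("the Pearson interval shrinks roughly as 1/sqrt(n)", {
  withr::with_seed(2, {
    x <- rnorm(4000); y <- 0.5 * x + rnorm(4000)
  })
  small <- fit_metrics(y[1:400], x[1:400])
  large <- fit_metrics(y, x)
  expect_lt(large$r_high - large$r_low,
            0.45 * (small$r_high - small$r_low))
})

test_that("a constant response degenerates gracefully", {
  fm <- fit_metrics(rep(3, 10), rep(3, 10))
  expect_equal(fm$rmse, 0)
  expect_true(is.na(fm$pearson_r))
})

test_that("a linear base model recovers the planted fraction of variance", {
  withr::with_seed(3, {
    n <- 3000
    z <- rnorm(n)
    ca <- 67 + 6 * z + rnorm(n, 0, 4)   # planted R^2 = 36/52
  })
  d <- tibble::tibble(participant_id = 1:n, chronological_age = ca, sbp = z)
  tr <- d[1:2400, ]; te <- d[2401:n, ]
  zoo <- fit_base_models(tr, te, list(base_model_spec("mlr")), "sbp", seed = 1)
  r2_te <- zoo$metrics$r2[zoo$metrics$partition == "test"]
  expect_equal(r2_te, 36 / 52, tolerance = 0.08)
})

test_that("unconstrained extremely-randomized trees show the overfit signature", {
  an <- drop_oracle(small_cohort(800, 13))
  parts <- split_cohort(an, seed = 13)
  zoo <- fit_base_models(parts$train, parts$test,
                         list(base_model_spec("extra_trees",
                                              params = list(min.node.size = 1))),
                         ba_feature_names(), seed = 13)
  m <- zoo$metrics
  expect_gt(m$pearson_r[m$partition == "train"], 0.95)
  expect_gt(m$pearson_r[m$partition == "train"],
            m$pearson_r[m$partition == "test"])
})

test_that("every zoo family fits and ranks by test correlation", {
  an <- drop_oracle(small_cohort(400, 14))
  parts <- split_cohort(an, seed = 14)
  specs <- list(base_model_spec("mlr"), base_model_spec("gam"),
                base_model_spec("svr"),
                base_model_spec("adaboost", params = list(n_rounds = 10)),
                base_model_spec("gbt_shallow", params = list(nrounds = 40)))
  zoo <- fit_base_models(parts$train, parts$test, specs,
                         ba_feature_names(), seed = 14)
  expect_equal(nrow(zoo$metrics), 10)
  expect_true(all(is.finite(zoo$metrics$rmse)))
  te <- dplyr::filter(tidy(zoo), partition == "test")
  expect_equal(zoo$ranking, te$model_tag[order(-te$pearson_r)])
})

test_that("aggregate importance is normalized, idempotent and order-invariant", {
  an <- drop_oracle(small_cohort(500, 15))
  parts <- split_cohort(an, seed = 15)
  feats <- ba_feature_names()
  specs <- list(base_model_spec("gbt_shallow", params = list(nrounds = 40),
                                tag = "a"),
                base_model_spec("gbt_shallow", params = list(nrounds = 40),
                                tag = "b"))
  zoo <- fit_base_models(parts$train, parts$test, specs, feats, seed = 15)
  imp <- aggregate_importance(zoo, parts$train)
  expect_equal(sum(imp$a), 1, tolerance = 1e-9)
  expect_equal(sum(imp$b), 1, tolerance = 1e-9)
  # identical specs and seed give identical models: aggregate equals either
  expect_equal(imp$aggregate, (imp$a + imp$b) / 2, tolerance = 1e-12)
})

test_that("a single-signal feature dominates the importance ranking", {
  withr::with_seed(16, {
    n <- 1000
    d <- tibble::tibble(participant_id = 1:n,
                        chronological_age = rnorm(n, 67, 9))
    d$sbp <- d$chronological_age * 2 + rnorm(n, 0, 2)
    d$tc <- rnorm(n); d$hdl <- rnorm(n)
  })
  parts <- split_cohort(d, seed = 16)
  zoo <- fit_base_models(parts$train, parts$test,
                         list(base_model_spec("gbt_shallow",
                                              params = list(nrounds = 50)),
                              base_model_spec("mlr")),
                         c("sbp", "tc", "hdl"), seed = 16)
  imp <- aggregate_importance(zoo, parts$train)
  expect_equal(imp$feature[1], "sbp")
  expect_gt(imp$aggregate[1], 0.8)
})
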