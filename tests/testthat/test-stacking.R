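test_that("a perfect base model yields BA equal to chronological age", {
  n <- 300
  d <- withr::with_seed(21, tibble::tibble(
    participant_id = 1:n,
    chronological_age = runif(n, 45, 90)
  ))
  d$sbp <- d$chronological_age            # an identity oracle feature
  d$tc <- d$chronological_age
  parts <- split_cohort(d, seed = 21)
  stk <- stack_predict(parts$train, parts$test, c("sbp", "tc"),
                       base_specs = list(base_model_spec("mlr", tag = "m1"),
                                         base_model_spec("mlr", tag = "m2")),
                       folds = 5, meta_family = "mlr", seed = 21,
                       with_zoo = FALSE)
  expect_lt(stk$metrics$rmse[stk$metrics$partition == "train"], 1e-6)
  expect_lt(stk$metrics$rmse[stk$metrics$partition == "test"], 1e-6)
  expect_equal(stk$predictions$ba, stk$predictions$ca, tolerance = 1e-6)
})

test_that("a constant base model propagates a constant level-2 feature", {
  n <- 200
  d <- withr::with_seed(22, tibble::tibble(
    participant_id = 1:n,
    chronological_age = rep(65, n),       # constant response
    sbp = rnorm(n)
  ))
  parts <- split_cohort(d, seed = 22)
  suppressWarnings(
    stk <- stack_predict(parts$train, parts$test, "sbp",
                         base_specs = list(base_model_spec("mlr", tag = "m1"),
                                           base_model_spec("gbt_shallow",
                                                           params = list(nrounds = 10),
                                                           tag = "m2")),
                         folds = 4, meta_family = "mlr", seed = 22,
                         with_zoo = FALSE)
  )
  # every fold model can only learn the constant: the level-2 columns carry
  # it into both partitions
  expect_equal(stk$level2_train$m1, rep(65, nrow(parts$train)), tolerance = 1e-8)
  expect_equal(stk$level2_test$m1, rep(65, nrow(parts$test)), tolerance = 1e-8)
  expect_equal(stk$predictions$ba, rep(65, n), tolerance = 1e-6)
})

test_that("the no-leakage audit passes for a genuine fit and catches tampering", {
  an <- drop_oracle(small_cohort(300, 23))
  parts <- split_cohort(an, seed = 23)
  stk <- stack_predict(parts$train, parts$test, ba_feature_names(),
                       base_specs = list(base_model_spec("mlr"),
                                         base_model_spec("gbt_shallow",
                                                         params = list(nrounds = 20))),
                       folds = 4, meta_family = "mlr", seed = 23,
                       with_zoo = FALSE)
  aud <- audit_no_leakage(stk)
  expect_true(aud$ok)
  expect_false(any(aud$audit$leaked))
  # fold training sets partition correctly: each excludes exactly its fold
  n_tr <- length(stk$train_ids)
  for (f in seq_along(stk$fold_train_ids)) {
    expect_equal(length(stk$fold_train_ids[[f]]), sum(stk$fold_of_row != f))
  }
  tampered <- stk
  tampered$fold_train_ids[[1]] <- stk$train_ids  # pretend fold 1 saw everything
  expect_false(audit_no_leakage(tampered)$ok)
})

test_that("stacking is deterministic in the seed", {
  an <- drop_oracle(small_cohort(250, 24))
  parts <- split_cohort(an, seed = 24)
  run <- function() stack_predict(parts$train, parts$test, ba_feature_names(),
                                  base_specs = list(base_model_spec("gbt_shallow",
                                                                    params = list(nrounds = 20)),
                                                    base_model_spec("mlr")),
                                  folds = 3, seed = 24, with_zoo = FALSE)
  expect_equal(run()$predictions, run()$predictions)
})

test_that("a random-forest meta-model is allowed but warned about", {
  an <- drop_oracle(small_cohort(200, 25))
  parts <- split_cohort(an, seed = 25)
  expect_warning(
    stack_predict(parts$train, parts$test, ba_feature_names(),
                  base_specs = list(base_model_spec("mlr"),
                                    base_model_spec("gbt_shallow",
                                                    params = list(nrounds = 10))),
                  folds = 3, meta_family = "rf", seed = 25, with_zoo = FALSE),
    "overfitting"
  )
})

test_that("BA range expansion matches direct arithmetic", {
  stk <- c(43.59, 88.57)
  other <- c(35.37, 99.66)
  expect_equal(ba_range_expansion(stk, other),
               100 * ((99.66 - 35.37) / (88.57 - 43.59) - 1))
  expect_equal(ba_range_expansion(stk, stk), 0)
  expect_equal(ba_range_expansion(c(0, 1), c(0, 2)), 100)
  expect_error(ba_range_expansion(c(2, 2), c(0, 1)), "zero")
})

test_that("the overfit contrast raises training fit while test MAE holds", {
  an <- drop_oracle(small_cohort(1500, 26))
  parts <- split_cohort(an, seed = 26)
  feats <- ba_feature_names()
  mod <- fit_boost_contrast(parts$train, parts$test, feats, "moderate",
                            seed = 26)
  suppressWarnings(
    ov <- fit_boost_contrast(parts$train, parts$test, feats, "overfit",
                             seed = 26)
  )
  gm <- glance(mod); go <- glance(ov)
  expect_gt(go$train_r, gm$train_r)
  if (go$constraint_met) {
    expect_lt(abs(go$test_mae - gm$test_mae) / gm$test_mae, 0.01)
  }
  expect_equal(sort(unique(ov$predictions$partition)), c("test", "train"))
  expect_equal(nrow(ov$predictions), 1500)
})
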