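test_that("a fixed seed reproduces the cohort exactly", {
  spec <- cohort_spec(n_participants = 300, seed = 42)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  other <- generate_cohort(cohort_spec(n_participants = 300, seed = 43))
  expect_false(identical(generate_cohort(spec), other))
})

test_that("cohort structure honours the spec", {
  coh <- small_cohort(n = 400, seed = 5)
  expect_equal(nrow(coh), 400)
  expect_true(all(coh$chronological_age >= 45 & coh$chronological_age <= 90))
  expect_equal(coh$bmi, coh$weight / coh$height^2, tolerance = 1e-12)
  expect_true(all(unlist(coh[disease_names()]) %in% 0:1))
  expect_setequal(levels(coh$gender), c("male", "female"))
  expect_equal(length(ba_feature_names()), 22)
})

test_that("planted age slopes and gender shifts are recovered by regression", {
  coh <- small_cohort(n = 6000, seed = 11)
  defs <- default_biomarker_defs()
  for (nm in c("sbp", "hemoglobin", "tc")) {
    d <- defs[defs$name == nm, ]
    fit <- lm(coh[[nm]] ~ chronological_age + gender, data = coh)
    est <- summary(fit)$coefficients
    # delta is independent of CA, so the CA coefficient is the planted slope
    expect_lt(abs(est["chronological_age", 1] - d$age_slope),
              3 * est["chronological_age", 2])
  }
})

test_that("with no planted signal marker-age slopes are null", {
  coh <- null_cohort(n = 4000, seed = 2)
  fit <- summary(lm(sbp ~ chronological_age, data = coh))$coefficients
  expect_lt(abs(fit["chronological_age", 1]), 3 * fit["chronological_age", 2])
  expect_gt(cor(small_cohort(5000, 3)$sbp,
                small_cohort(5000, 3)$chronological_age), 0)
})

test_that("the latent aging offset reaches markers beyond chronological age", {
  coh <- small_cohort(n = 6000, seed = 9)
  fit <- summary(lm(waist ~ chronological_age + gender + latent_delta,
                    data = coh))$coefficients
  expect_gt(fit["latent_delta", 1], 0)
  expect_lt(fit["latent_delta", 4], 1e-6)
})

test_that("oracle-column guard blocks estimation stages", {
  coh <- small_cohort(n = 50, seed = 1)
  expect_error(check_no_oracle(coh), "latent_delta")
  expect_silent(check_no_oracle(drop_oracle(coh)))
  expect_false("latent_delta" %in% names(drop_oracle(coh)))
})

test_that("exclusion accounting reproduces the cascade and audits each step", {
  expect_equal(as.numeric(exclusion_accounting(418161, 30935, 309416, 0)), 77810)
  res <- exclusion_accounting(418161, 30935, 309416, 666)
  expect_equal(as.numeric(res), 77144)
  audit <- attr(res, "audit")
  expect_equal(audit$remaining, c(418161, 387226, 77810, 77144))
  expect_equal(as.numeric(exclusion_accounting(100, 0, 0, 0)), 100)
  expect_error(exclusion_accounting(100, 150, 0, 0), "exceed")
  expect_error(exclusion_accounting(-1, 0, 0, 0), "nonnegative")
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_participants = 0), "positive")
  expect_error(cohort_spec(age_range = c(90, 45)), "increasing")
  expect_error(cohort_spec(prop_female = 1.2))
  expect_error(cohort_spec(biomarker_defs = default_biomarker_defs()[0, ]),
               "nonempty")
})
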