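test_that("ABSI and WHtR closed forms match direct arithmetic", {
  expect_equal(absi(1, 1, 1), 1, tolerance = 1e-12)
  bmi <- 70 / 1.7^2
  expect_equal(absi(0.85, bmi, 1.7),
               0.85 / (bmi^(2 / 3) * sqrt(1.7)), tolerance = 1e-12)
  expect_equal(absi(2 * 0.85, bmi, 1.7), 2 * absi(0.85, bmi, 1.7),
               tolerance = 1e-12)
  expect_equal(whtr(0.85, 1.70), 0.5, tolerance = 1e-12)
  expect_equal(whtr(1.7, 1.7), 1)
  expect_equal(whtr(85, 170), whtr(0.85, 1.70))  # unit invariance of a ratio
  expect_error(absi(-1, 20, 1.7), "positive")
  expect_error(whtr(0.85, 0), "positive")
})

test_that("quantile groups partition evenly and monotonically", {
  withr::with_seed(31, x <- rnorm(1003))
  q <- quantile_groups(x, 5)
  expect_lte(diff(range(table(q))), 1)
  # assignment is monotone in the indicator
  expect_true(all(diff(as.integer(q[order(x)])) >= 0))
  # stable tie handling: repeated values keep first-come ordering
  q2 <- quantile_groups(rep(1, 10), 5)
  expect_equal(as.integer(q2), rep(1:5, each = 2))
})

test_that("disease counts and categories are consistent", {
  coh <- drop_oracle(small_cohort(300, 32))
  d <- add_disease_count(coh)
  expect_true(all(d$disease_count == rowSums(d[disease_names()])))
  expect_true(all((d$disease_count >= 2) == (d$disease_cat == "2+")))
  expect_true(all((d$disease_count == 0) == (d$disease_cat == "0")))
})

test_that("battery estimates match an independent IRLS reference", {
  d <- make_assoc_fixture()
  preds <- tibble::tibble(participant_id = d$participant_id,
                          model_tag = "STK", ba = d$ba)
  coh <- dplyr::select(d, -"ba")

  # linear: BA on ABSI, crude
  res <- risk_indicator_battery(preds, coh, "absi", "model1")
  a <- absi(d$waist, d$bmi, d$height)
  ref <- ols_ref(cbind(1, a), d$ba)
  row <- res[res$term == "absi", ]
  expect_equal(row$estimate, ref$coef[2], tolerance = 1e-8)
  expect_equal(row$std_error, ref$se[2], tolerance = 1e-8)

  # Poisson: disease count on BA, adjusted
  res_p <- disease_count_battery(preds, coh, "model2",
                                 diseases = c("disease_kidney", "disease_heart"))
  cnt <- d$disease_kidney + d$disease_heart
  Xp <- cbind(1, d$ba, d$chronological_age, d$family_disease)
  refp <- irls_ref(Xp, cnt, poisson())
  rp <- res_p[res_p$model_kind == "poisson", ]
  expect_equal(rp$estimate, refp$coef[2], tolerance = 1e-8)
  expect_equal(rp$std_error, refp$se[2], tolerance = 1e-8)

  # logistic: kidney disease on BA, crude, with Wald interval
  res_l <- per_disease_battery(preds, coh, "model1",
                               diseases = "disease_kidney")
  refl <- irls_ref(cbind(1, d$ba), d$disease_kidney, binomial())
  expect_equal(res_l$estimate, refl$coef[2], tolerance = 1e-8)
  expect_equal(res_l$std_error, refl$se[2], tolerance = 1e-6)
  expect_equal(res_l$odds_ratio, exp(refl$coef[2]), tolerance = 1e-8)
  expect_true(res_l$or_low <= res_l$odds_ratio &
                res_l$odds_ratio <= res_l$or_high)
})

test_that("an indicator with no planted path shows a null adjusted association", {
  ad <- default_anthro_defs()
  ad$age_slope <- 0; ad$delta_extra <- 0; ad$loading <- 0
  coh <- generate_cohort(cohort_spec(n_participants = 2000, seed = 34,
                                     anthro_defs = ad))
  preds <- tibble::tibble(participant_id = coh$participant_id,
                          model_tag = "oracle",
                          ba = coh$chronological_age + coh$latent_delta)
  res <- risk_indicator_battery(preds, drop_oracle(coh), "whtr", "model2")
  expect_lt(abs(res$statistic[res$term == "whtr"]), 4)
})

test_that("the planted aging path reaches the risk indicators through BA", {
  coh <- small_cohort(4000, 35)
  preds <- tibble::tibble(participant_id = coh$participant_id,
                          model_tag = "oracle",
                          ba = coh$chronological_age + coh$latent_delta)
  an <- drop_oracle(coh)
  res <- risk_indicator_battery(preds, an, "whtr", "model2")
  q <- res[res$outcome == "whtr_quintile", ]
  expect_equal(q$term, paste0("quintileQ", 2:5))
  expect_true(all(diff(q$estimate) > 0))           # increments rise Q2..Q5
  expect_gt(res$statistic[res$term == "whtr"], 10)
  # diseases: strong planted delta effect gives OR > 1 per BA year
  pd <- per_disease_battery(preds, an, "model2", diseases = "disease_kidney")
  expect_gt(pd$odds_ratio, 1)
  expect_lt(pd$p_value, 0.05)
})

test_that("perfect separation is reported as a diagnostic", {
  withr::with_seed(36, {
    n <- 60
    d <- tibble::tibble(
      participant_id = 1:n,
      chronological_age = runif(n, 45, 90),
      family_disease = rbinom(n, 1, 0.3),
      ba = seq(45, 90, length.out = n)
    )
    d$disease_heart <- as.integer(d$ba > 67)
  })
  preds <- tibble::tibble(participant_id = d$participant_id,
                          model_tag = "STK", ba = d$ba)
  res <- per_disease_battery(preds, dplyr::select(d, -"ba"), "model1",
                             diseases = "disease_heart")
  expect_true(res$separation)
})

test_that("batteries refuse the oracle column", {
  coh <- small_cohort(100, 37)
  preds <- tibble::tibble(participant_id = coh$participant_id,
                          model_tag = "STK", ba = coh$chronological_age)
  expect_error(risk_indicator_battery(preds, coh, "absi"), "latent_delta")
})
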