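tiny_block <- function(n = 40, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    x = rnorm(n, 10, 2),
    y = rnorm(n, 5, 1),
    b = rbinom(n, 1, 0.5)
  ))
}

test_that("an all-false mask returns the input unchanged for every method", {
  truth <- tiny_block()
  st <- standardization_stats(truth, seq_len(40), c("x", "y", "b"))
  mask <- matrix(FALSE, 40, 3, dimnames = list(NULL, c("x", "y", "b")))
  for (m in c("mean", "knn", "round_robin_regression", "chained_multiple",
              "autoencoder")) {
    out <- impute(truth, mask, imputer_config(m, epochs = 5), st)
    expect_identical(out, truth, label = m)
  }
})

test_that("observed cells are bit-identical after imputation", {
  an <- drop_oracle(small_cohort(250, 3))
  inj <- inject_missing(an, missingness_profile("MCAR", 0.15), 2)
  st <- standardization_stats(an, 1:200)
  for (m in c("mean", "knn", "round_robin_regression", "chained_multiple",
              "autoencoder")) {
    out <- impute(inj$data, inj$mask, imputer_config(m, epochs = 10), st, 1:200)
    blk_in <- as.matrix(inj$data[colnames(inj$mask)])
    blk_out <- as.matrix(out[colnames(inj$mask)])
    expect_identical(blk_out[!inj$mask], blk_in[!inj$mask], label = m)
    expect_false(anyNA(blk_out), label = m)
  }
})

test_that("binary predictions are thresholded: above 0.5 is 1, otherwise 0", {
  truth <- tibble::tibble(x = rnorm(8), b = c(1, 1, 0, 0, 1, 1, 0, 0))
  st <- standardization_stats(truth, 1:8, c("x", "b"))
  mask <- matrix(FALSE, 8, 2, dimnames = list(NULL, c("x", "b")))
  mask[1, "b"] <- TRUE
  gap <- truth; gap$b[1] <- NA
  # training mean of b is exactly 0.5: the rule maps 0.5 to 0
  out <- impute(gap, mask, imputer_config("mean"), st)
  expect_identical(out$b[1], 0)
  truth2 <- tibble::tibble(x = rnorm(8), b = c(1, 1, 1, 0, 1, 1, 1, 0))
  st2 <- standardization_stats(truth2, 1:8, c("x", "b"))
  gap2 <- truth2; gap2$b[1] <- NA
  out2 <- impute(gap2, mask, imputer_config("mean"), st2)
  expect_identical(out2$b[1], 1)
})

test_that("round-robin regression recovers exactly collinear columns", {
  withr::with_seed(5, {
    x <- rnorm(200, 0, 3)
    truth <- tibble::tibble(x = x, y = 2 * x)
    mask <- matrix(FALSE, 200, 2, dimnames = list(NULL, c("x", "y")))
    mask[sample.int(200, 20), "y"] <- TRUE
  })
  gap <- truth; gap$y[mask[, "y"]] <- NA
  st <- standardization_stats(truth, which(!mask[, "y"]), c("x", "y"))
  out <- impute(gap, mask, imputer_config("round_robin_regression"), st,
                which(!mask[, "y"]))
  expect_equal(out$y, truth$y, tolerance = 1e-6)
})

test_that("imputation scores match hand arithmetic", {
  st <- tibble::tibble(variable = "v", mean = 0, var = 1, binary = FALSE)
  truth <- tibble::tibble(v = c(1, 0, -1, 5))
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 4, 1,
                 dimnames = list(NULL, "v"))
  perfect <- score_imputation(truth, truth, mask, st)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$r2, 1)
  filled <- tibble::tibble(v = c(0, 0, 0, 5))
  sc <- score_imputation(filled, truth, mask, st)
  expect_equal(sc$mse, 2 / 3)            # ((1-0)^2 + 0 + (0-(-1))^2) / 3
  expect_equal(sc$r2, 0)                 # prediction = masked truth mean
  expect_error(score_imputation(truth, truth,
                                matrix(FALSE, 4, 1, dimnames = list(NULL, "v")),
                                st), "empty mask")
})

test_that("chained multiple imputation stabilises as m grows", {
  an <- drop_oracle(small_cohort(150, 8))
  inj <- inject_missing(an, missingness_profile("MCAR", 0.1), 3)
  st <- standardization_stats(an, 1:150)
  cell <- which(inj$mask[, "sbp"])[1]
  draw <- function(m, s) {
    out <- impute(inj$data, inj$mask, imputer_config("chained_multiple",
                                                     m = m, seed = s), st)
    out$sbp[cell]
  }
  v2 <- var(vapply(1:15, function(s) draw(2, s), numeric(1)))
  v10 <- var(vapply(1:15, function(s) draw(10, s), numeric(1)))
  expect_lt(v10, v2)
})

test_that("degenerate inputs are signalled", {
  truth <- tiny_block()
  st <- standardization_stats(truth, 1:40, c("x", "y", "b"))
  mask <- matrix(FALSE, 40, 3, dimnames = list(NULL, c("x", "y", "b")))
  mask[, "x"] <- TRUE
  gap <- truth; gap$x <- NA_real_
  expect_error(impute(gap, mask, imputer_config("mean"), st),
               "entirely missing")
  coh <- small_cohort(50, 1)
  expect_error(impute(coh, mask[1:50, ], imputer_config("mean"), st),
               "latent_delta")
})
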