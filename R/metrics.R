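#' Regression fit metrics with a Fisher-z Pearson interval
#'
#' RMSE, coefficient of determination, MAE, and Pearson's correlation with
#' its 95% Fisher-z confidence interval — the standard panel for comparing
#' biological-age models against chronological age.
#'
#' @param pred predicted values (years).
#' @param truth observed chronological age (years).
#' @return a one-row tibble `rmse`, `r2`, `mae`, `pearson_r`, `r_low`,
#'   `r_high`, `n`. Degenerate inputs (constant `pred` or `truth`) give
#'   `NA` correlations.
#' @export
fit_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  err <- pred - truth
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(err^2) / ss_tot
  r <- if (sd(pred) == 0 || sd(truth) == 0) NA_real_ else cor(pred, truth)
  n <- length(pred)
  if (is.na(r) || n < 4 || abs(r) >= 1) {
    lo <- hi <- r
  } else {
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    lo <- tanh(z - qnorm(0.975) * se)
    hi <- tanh(z + qnorm(0.975) * se)
  }
  tibble::tibble(rmse = rmse, r2 = r2, mae = mae, pearson_r = r,
                 r_low = lo, r_high = hi, n = n)
}
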