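#' Benchmark imputers under simulated missingness
#'
#' Runs the full masked-entry evaluation cycle: split the complete cohort
#' 80/20, compute training-set standardization statistics, then for each
#' missingness profile and each of `folds` replicate removal draws, inject
#' gaps, impute with every requested method (fitted on training rows only)
#' and score MSE / R-squared on the masked cells of the test portion.
#' The KNN neighbour count is tuned per condition by grid search on
#' training-row masked cells of the first fold.
#'
#' @param cohort complete cohort table (no oracle column).
#' @param profiles a list of [missingness_profile()]s.
#' @param methods character vector of method names or a list of
#'   [imputer_config()]s.
#' @param train_fraction training fraction of the split.
#' @param folds number of replicate removal draws per condition.
#' @param seed master seed; fold-level seeds are derived from it.
#' @param knn_grid candidate neighbour counts for KNN tuning.
#' @return a tibble of class `ba_benchmark`: one row per
#'   (method, mechanism, rate, fold) with `mse`, `r2`, `seconds`.
#' @export
run_benchmark <- function(cohort, profiles, methods,
                          train_fraction = 0.8, folds = 10, seed = 1L,
                          knn_grid = c(3L, 5L, 10L, 20L)) {
  check_no_oracle(cohort, "the imputation benchmark")
  if (inherits(profiles, "missingness_profile")) profiles <- list(profiles)
  if (is.character(methods)) {
    methods <- lapply(methods, function(m) imputer_config(method = m))
  }
  n <- nrow(cohort)
  train_idx <- with_seed(seed, sample.int(n, round_half_up(train_fraction * n)))
  test_rows <- setdiff(seq_len(n), train_idx)
  cols <- profiles[[1]]$columns
  stats <- standardization_stats(cohort, train_idx, cols)

  out <- list()
  for (pi in seq_along(profiles)) {
    prof <- profiles[[pi]]
    rate <- if (prof$mechanism == "MCAR") prof$global_rate else
      sum(prof$per_variable_rate) / length(prof$columns)
    tuned_k <- NULL
    for (fold in seq_len(folds)) {
      # the removal seed depends on the fold only, so MCAR masks are nested
      # across the rate grid (a lower rate masks a prefix of the cells a
      # higher rate masks) and across-rate comparisons are paired
      fs <- seed + 104729L * fold
      inj <- inject_missing(cohort, prof, seed = fs)
      mask_test <- inj$mask
      mask_test[train_idx, ] <- FALSE
      if (!any(mask_test)) abort("fold with zero masked test cells.")
      mask_train <- inj$mask
      mask_train[test_rows, ] <- FALSE
      for (cfg in methods) {
        cfg$seed <- fs + 17L
        if (cfg$method == "knn") {
          if (is.null(tuned_k)) {
            tune <- vapply(knn_grid, function(kk) {
              ck <- cfg; ck$k <- as.integer(kk)
              comp <- impute(inj$data, inj$mask, ck, stats, train_idx)
              score_imputation(comp, cohort, mask_train, stats)$mse
            }, numeric(1))
            tuned_k <- knn_grid[which.min(tune)]
          }
          cfg$k <- as.integer(tuned_k)
        }
        t0 <- proc.time()[["elapsed"]]
        completed <- impute(inj$data, inj$mask, cfg, stats, train_idx)
        elapsed <- proc.time()[["elapsed"]] - t0
        sc <- score_imputation(completed, cohort, mask_test, stats)
        out[[length(out) + 1L]] <- tibble::tibble(
          method = cfg$method, mechanism = prof$mechanism, rate = rate,
          fold = fold, mse = sc$mse, r2 = sc$r2, seconds = elapsed,
          param = if (cfg$method == "knn") paste0("k=", cfg$k) else NA_character_
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("ba_benchmark", class(res))
  res
}

#' Summarise a benchmark across folds
#'
#' @param scores output of [run_benchmark()].
#' @return a tibble with fold mean and SD of MSE and R-squared and mean
#'   elapsed seconds per (method, mechanism, rate).
#' @export
summarize_benchmark <- function(scores) {
  dplyr::summarise(
    dplyr::group_by(scores, .data$method, .data$mechanism, .data$rate),
    mse_mean = mean(.data$mse), mse_sd = sd(.data$mse),
    r2_mean = mean(.data$r2), r2_sd = sd(.data$r2),
    seconds_mean = mean(.data$seconds), .groups = "drop"
  )
}

#' Plot benchmark curves
#'
#' MSE and R-squared against the missing rate, one line per imputer,
#' faceted by mechanism and metric — the standard way to read an
#' imputation benchmark.
#'
#' @param object a `ba_benchmark` tibble from [run_benchmark()].
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot ba_benchmark
#' @export
autoplot.ba_benchmark <- function(object, ...) {
  summ <- summarize_benchmark(object)
  long <- tidyr::pivot_longer(
    summ, c("mse_mean", "r2_mean"), names_to = "metric", values_to = "value"
  )
  long$metric <- ifelse(long$metric == "mse_mean", "MSE", "R²")
  ggplot2::ggplot(long, ggplot2::aes(.data$rate, .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(metric ~ mechanism, scales = "free_y") +
    ggplot2::labs(x = "missing rate", y = NULL, colour = "imputer") +
    ggplot2::theme_minimal()
}
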