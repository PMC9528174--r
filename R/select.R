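#' Configure the two-step feature screen
#'
#' @param lambda_grid optional decreasing positive lambda sequence for the
#'   lasso path; `NULL` lets the fitting routine choose its own.
#' @param cv_folds folds for cross-validated lambda selection.
#' @param alpha_threshold two-tailed significance level of the Pearson
#'   correlation-with-age filter.
#' @param seed seed for the CV fold assignment.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(lambda_grid = NULL, cv_folds = 10,
                             alpha_threshold = 0.05, seed = 1L) {
  if (!is.null(lambda_grid) && (length(lambda_grid) == 0 || any(lambda_grid <= 0))) {
    abort("`lambda_grid` must be nonempty and positive.")
  }
  if (alpha_threshold <= 0 || alpha_threshold >= 1) {
    abort("`alpha_threshold` must be in (0, 1).")
  }
  structure(list(lambda_grid = lambda_grid, cv_folds = as.integer(cv_folds),
                 alpha_threshold = alpha_threshold, seed = as.integer(seed)),
            class = "selection_config")
}

feature_matrix <- function(data, features) {
  X <- data[features]
  if ("gender" %in% features) X$gender <- as.numeric(data$gender == "female")
  as.matrix(X)
}

#' Lasso shrinkage screen against chronological age
#'
#' Standardizes the candidate features, fits a cross-validated lasso of
#' chronological age on them, selects the minimum-CV-error lambda and
#' marks features with an exactly-zero coefficient as dropped.
#'
#' @param data imputed (complete) cohort table.
#' @param features candidate feature names; defaults to the 22 candidates
#'   of [ba_feature_names()].
#' @param config a [selection_config()].
#' @return a tibble `feature`, `lasso_coef`, `kept_lasso`, with the chosen
#'   lambda in attribute `"lambda"`.
#' @export
lasso_screen <- function(data, features = ba_feature_names(),
                         config = selection_config()) {
  check_no_oracle(data, "feature selection")
  X <- feature_matrix(data, features)
  constant <- apply(X, 2, function(x) var(x) == 0)
  if (any(constant)) {
    abort(paste0("constant feature columns (cannot be screened): ",
                 paste(features[constant], collapse = ", ")))
  }
  # canonical column order inside the fit, so the report is exactly
  # invariant under permutation of the candidate list
  ord <- order(features)
  Xs <- scale(X[, ord, drop = FALSE])
  y <- data$chronological_age
  cvfit <- with_seed(config$seed, {
    glmnet::cv.glmnet(Xs, y, alpha = 1, lambda = config$lambda_grid,
                      nfolds = config$cv_folds, standardize = FALSE)
  })
  b <- numeric(length(features))
  b[ord] <- as.numeric(coef(cvfit, s = "lambda.min"))[-1]
  out <- tibble::tibble(feature = features, lasso_coef = b,
                        kept_lasso = b != 0)
  attr(out, "lambda") <- cvfit$lambda.min
  out
}

#' Pearson correlation-with-age screen
#'
#' Two-tailed Pearson test of each lasso-surviving feature against
#' chronological age; features with `P > alpha` are dropped. Binary
#' features use the same formula (point-biserial correlation). The final
#' keep rule is: nonzero lasso coefficient AND significant correlation.
#'
#' @param data imputed cohort table.
#' @param lasso_report output of [lasso_screen()].
#' @param alpha significance threshold.
#' @return the full selection report: `feature`, `lasso_coef`,
#'   `kept_lasso`, `pearson_r`, `p_value`, `kept`.
#' @export
correlation_screen <- function(data, lasso_report, alpha = 0.05) {
  check_no_oracle(data, "feature selection")
  X <- feature_matrix(data, lasso_report$feature)
  y <- data$chronological_age
  if (nrow(X) < 3) abort("need at least 3 complete pairs per feature.")
  tests <- apply(X, 2, function(x) {
    ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  out <- lasso_report
  out$pearson_r <- unname(tests["r", ])
  out$p_value <- unname(tests["p", ])
  out$kept <- out$kept_lasso & out$p_value <= alpha
  attr(out, "lambda") <- attr(lasso_report, "lambda")
  out
}

#' Run the full two-step feature screen
#'
#' Convenience wrapper: [lasso_screen()] followed by
#' [correlation_screen()].
#'
#' @inheritParams lasso_screen
#' @return the final selection report tibble (see [correlation_screen()]).
#' @export
select_features <- function(data, features = ba_feature_names(),
                            config = selection_config()) {
  rep1 <- lasso_screen(data, features, config)
  correlation_screen(data, rep1, alpha = config$alpha_threshold)
}
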