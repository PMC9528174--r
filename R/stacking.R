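#' Stacked biological-age estimator with out-of-fold level-2 features
#'
#' Implements the two-layer stacking flow: each base model is run through
#' k-fold cross-validation on the training partition; the out-of-fold
#' predictions (each training row predicted by the fold model that never
#' saw it) form that model's level-2 training feature, and the mean of the
#' k fold-models' predictions on the held-out test partition forms its
#' level-2 test feature. The meta-model is then fitted on the level-2
#' training features with chronological age as the response. Full-sample
#' BA keeps the no-leakage convention: training rows are scored through
#' their out-of-fold level-2 features, test rows through the fold-mean
#' features.
#'
#' @param train,test disjoint cohort partitions (imputed, oracle column
#'   dropped).
#' @param features screened feature names.
#' @param base_specs list of [base_model_spec()]s; default the five fused
#'   tree families.
#' @param folds number of cross-validation folds in the training set.
#' @param meta_family `"gam"` (spline meta-model, the default), `"mlr"`,
#'   `"svr"`, or `"rf"`. A random-forest meta-model is accepted with a
#'   warning: it reintroduces the train/test gap stacking is meant to
#'   remove.
#' @param seed seed controlling fold assignment and stochastic engines.
#' @param with_zoo also refit each base model on the full training
#'   partition (needed for base-model metrics and feature importance);
#'   disable to save time when only the stacked predictions matter.
#' @return an object of class `ba_stack` with elements `predictions`
#'   (tibble: `participant_id`, `ca`, `model_tag = "STK"`, `partition`,
#'   `ba`), `metrics`, the fitted `meta` model, level-2 feature tables,
#'   fold bookkeeping for the leakage audit, and `zoo` (the base models
#'   refitted on the full training partition, with their own metrics).
#' @export
stack_predict <- function(train, test, features,
                          base_specs = default_base_specs(),
                          folds = 10, meta_family = c("gam", "mlr", "svr", "rf"),
                          seed = 1L, with_zoo = TRUE) {
  meta_family <- match.arg(meta_family)
  if (length(base_specs) < 2) abort("need at least 2 base models.")
  if (folds < 2) abort("`folds` must be >= 2.")
  if (meta_family == "rf") {
    warn("a random-forest meta-model tends to reintroduce overfitting; prefer 'gam' or 'mlr'.")
  }
  check_no_oracle(train, "stacking"); check_no_oracle(test, "stacking")
  df_tr <- as.data.frame(feature_matrix(train, features))
  df_te <- as.data.frame(feature_matrix(test, features))
  if (anyNA(df_tr) || anyNA(df_te)) abort("NAs in the design matrix: impute first.")
  y_tr <- train$chronological_age
  y_te <- test$chronological_age
  n_tr <- nrow(df_tr)
  if (n_tr < folds * 2) abort("folds too small for the training partition.")

  fold_of_row <- with_seed(seed, sample(rep(seq_len(folds), length.out = n_tr)))
  fold_train_ids <- lapply(seq_len(folds), function(f)
    train$participant_id[fold_of_row != f])

  tags <- vapply(base_specs, function(s) s$tag, character(1))
  L2_tr <- matrix(NA_real_, n_tr, length(tags), dimnames = list(NULL, tags))
  L2_te <- matrix(0, nrow(df_te), length(tags), dimnames = list(NULL, tags))
  for (m in seq_along(base_specs)) {
    te_acc <- matrix(NA_real_, nrow(df_te), folds)
    for (f in seq_len(folds)) {
      in_f <- fold_of_row == f
      mod <- fit_engine(base_specs[[m]], df_tr[!in_f, , drop = FALSE],
                        y_tr[!in_f], seed = seed + 1000L * m + f)
      L2_tr[in_f, m] <- predict_engine(mod, df_tr[in_f, , drop = FALSE])
      te_acc[, f] <- predict_engine(mod, df_te)
    }
    L2_te[, m] <- rowMeans(te_acc)
  }

  meta_df_tr <- as.data.frame(L2_tr)
  meta_df_te <- as.data.frame(L2_te)
  meta <- with_seed(seed + 7L, switch(
    meta_family,
    gam = {
      fml <- gam_formula(meta_df_tr, 5)
      structure(list(fit = mgcv::gam(fml, data = cbind(meta_df_tr, .y = y_tr))),
                class = "engine_gam")
    },
    mlr = structure(list(fit = lm(.y ~ ., data = cbind(meta_df_tr, .y = y_tr)),
                         sds = vapply(meta_df_tr, sd, numeric(1))),
                    class = "engine_lm"),
    svr = structure(list(fit = e1071::svm(x = as.matrix(meta_df_tr), y = y_tr,
                                          scale = TRUE)),
                    class = "engine_svm"),
    rf = structure(list(fit = ranger::ranger(x = meta_df_tr, y = y_tr,
                                             num.trees = 300, num.threads = 1,
                                             seed = seed + 7L)),
                   class = "engine_ranger")
  ))

  ba_tr <- predict_engine(meta, meta_df_tr)
  ba_te <- predict_engine(meta, meta_df_te)
  predictions <- dplyr::bind_rows(
    tibble::tibble(participant_id = train$participant_id, ca = y_tr,
                   model_tag = "STK", partition = "train", ba = ba_tr),
    tibble::tibble(participant_id = test$participant_id, ca = y_te,
                   model_tag = "STK", partition = "test", ba = ba_te)
  )
  metrics <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(model_tag = "STK", partition = "train"),
                     fit_metrics(ba_tr, y_tr)),
    dplyr::bind_cols(tibble::tibble(model_tag = "STK", partition = "test"),
                     fit_metrics(ba_te, y_te))
  )
  zoo <- if (with_zoo) {
    fit_base_models(train, test, base_specs, features, seed = seed)
  }
  structure(
    list(predictions = predictions, metrics = metrics, meta = meta,
         meta_family = meta_family, level2_train = meta_df_tr,
         level2_test = meta_df_te, fold_of_row = fold_of_row,
         fold_train_ids = fold_train_ids,
         train_ids = train$participant_id, base_specs = base_specs,
         features = features, zoo = zoo, seed = seed),
    class = "ba_stack"
  )
}

#' Audit the stacked estimator's no-leakage contract
#'
#' Verifies, from the fold bookkeeping recorded at fit time, that every
#' level-2 training feature value was produced by a fold model whose
#' training rows exclude the row being predicted.
#'
#' @param stack a `ba_stack` from [stack_predict()].
#' @return a list with `ok` (logical) and `audit`, a tibble with one row
#'   per training participant (`participant_id`, `fold`, `leaked`).
#' @export
audit_no_leakage <- function(stack) {
  stopifnot(inherits(stack, "ba_stack"))
  leaked <- vapply(seq_along(stack$train_ids), function(i) {
    stack$train_ids[i] %in% stack$fold_train_ids[[stack$fold_of_row[i]]]
  }, logical(1))
  audit <- tibble::tibble(participant_id = stack$train_ids,
                          fold = stack$fold_of_row, leaked = leaked)
  list(ok = !any(leaked), audit = audit)
}

#' Deliberately moderate or overfit boosted-tree BA contrasts
#'
#' Fits the boosted-tree contrast models used to study how overfitting
#' degrades downstream association analyses. `"moderate"` uses the same
#' gradient-boosted-tree configuration as the stacked ensemble's deep
#' booster. `"overfit"` grid-searches deeper / longer-trained
#' configurations and picks the one with the highest training-set Pearson
#' correlation among those whose test MAE stays within
#' `test_mae_tolerance` (relative) of the moderate model's — i.e. it
#' amplifies the training fit while leaving test performance approximately
#' unchanged. Both are trained on the training partition only and applied
#' to the full sample, reproducing on purpose the leakage being critiqued.
#'
#' @param train,test disjoint cohort partitions.
#' @param features screened feature names.
#' @param mode `"moderate"` or `"overfit"`.
#' @param moderate_params boosted-tree parameters of the moderate model.
#' @param test_mae_tolerance allowed relative change in test MAE for the
#'   overfit search.
#' @param search_grid data frame of candidate overfit configurations
#'   (columns `eta`, `max_depth`, `nrounds`, `min_child_weight`,
#'   `subsample`); at most 50 are evaluated.
#' @param seed engine seed.
#' @return an object of class `ba_contrast` with `predictions` (full
#'   sample, tagged `boost_moderate` / `boost_overfit`), `metrics`,
#'   `params`, and for the overfit mode `constraint_met` and the search
#'   `log`.
#' @export
fit_boost_contrast <- function(train, test, features,
                               mode = c("moderate", "overfit"),
                               moderate_params = base_model_spec("gbt_xgb")$params,
                               test_mae_tolerance = 0.01,
                               search_grid = default_overfit_grid(),
                               seed = 1L) {
  mode <- match.arg(mode)
  check_no_oracle(train, "boosted-tree contrast")
  check_no_oracle(test, "boosted-tree contrast")
  df_tr <- as.data.frame(feature_matrix(train, features))
  df_te <- as.data.frame(feature_matrix(test, features))
  y_tr <- train$chronological_age
  y_te <- test$chronological_age

  fit_with <- function(params) {
    fit_engine(base_model_spec("gbt_xgb", params = params), df_tr, y_tr,
               seed = seed)
  }
  mod_moderate <- fit_with(moderate_params)
  mae_ref <- fit_metrics(predict_engine(mod_moderate, df_te), y_te)$mae

  constraint_met <- TRUE
  search_log <- NULL
  if (mode == "moderate") {
    model <- mod_moderate
    params <- moderate_params
  } else {
    grid <- utils::head(search_grid, 50)
    logs <- list()
    best <- NULL; best_r <- -Inf
    for (g in seq_len(nrow(grid))) {
      params_g <- as.list(grid[g, ])
      params_g$colsample_bytree <- 0.8
      m_g <- fit_with(params_g)
      tr_r <- fit_metrics(predict_engine(m_g, df_tr), y_tr)$pearson_r
      te_mae <- fit_metrics(predict_engine(m_g, df_te), y_te)$mae
      feasible <- abs(te_mae - mae_ref) / mae_ref < test_mae_tolerance
      logs[[g]] <- tibble::tibble(!!!grid[g, ], train_r = tr_r,
                                  test_mae = te_mae, feasible = feasible)
      if (feasible && tr_r > best_r) { best <- m_g; best_r <- tr_r; params <- params_g }
    }
    search_log <- dplyr::bind_rows(logs)
    if (is.null(best)) {
      warn("overfit search found no configuration keeping test MAE within tolerance; returning the closest one.")
      constraint_met <- FALSE
      g <- which.min(abs(search_log$test_mae - mae_ref))
      params <- as.list(search_grid[g, ]); params$colsample_bytree <- 0.8
      best <- fit_with(params)
    }
    model <- best
  }

  tag <- if (mode == "moderate") "boost_moderate" else "boost_overfit"
  ba_tr <- predict_engine(model, df_tr)
  ba_te <- predict_engine(model, df_te)
  predictions <- dplyr::bind_rows(
    tibble::tibble(participant_id = train$participant_id, ca = y_tr,
                   model_tag = tag, partition = "train", ba = ba_tr),
    tibble::tibble(participant_id = test$participant_id, ca = y_te,
                   model_tag = tag, partition = "test", ba = ba_te)
  )
  metrics <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(model_tag = tag, partition = "train"),
                     fit_metrics(ba_tr, y_tr)),
    dplyr::bind_cols(tibble::tibble(model_tag = tag, partition = "test"),
                     fit_metrics(ba_te, y_te))
  )
  structure(list(predictions = predictions, metrics = metrics, params = params,
                 mode = mode, constraint_met = constraint_met,
                 log = search_log, model = model, features = features),
            class = "ba_contrast")
}

#' Default search grid for the overfit contrast
#' @return a data frame of boosted-tree configurations ordered by
#'   increasing capacity.
#' @export
default_overfit_grid <- function() {
  base <- data.frame(eta = 0.05, max_depth = 6, min_child_weight = 10,
                     subsample = 0.8, lambda = 1)
  rbind(
    # continued boosting of the moderate configuration
    merge(base, data.frame(nrounds = c(400, 450, 500, 600, 800))),
    # deeper trees with leaf-weight shrinkage to hold the test error
    merge(data.frame(eta = 0.05, max_depth = 8, min_child_weight = 10,
                     subsample = 0.8, lambda = 10),
          data.frame(nrounds = c(400, 600, 800))),
    merge(data.frame(eta = 0.05, max_depth = 8, min_child_weight = 5,
                     subsample = 0.8, lambda = 20),
          data.frame(nrounds = 600)),
    # aggressive capacity (rarely test-stable at the default scale)
    merge(data.frame(eta = 0.1, max_depth = 10, min_child_weight = 1,
                     subsample = 1, lambda = 1),
          data.frame(nrounds = 300))
  )
}

#' Relative expansion of one BA range over another
#'
#' `100 * ((max - min)_other / (max - min)_reference - 1)`: how much wider
#' the comparison model's biological-age range is than the reference's,
#' in percent.
#'
#' @param reference,other vectors of BA predictions (or `ba_stack` /
#'   `ba_contrast` objects, whose full-sample predictions are used) over
#'   the same participants.
#' @return a percentage.
#' @export
ba_range_expansion <- function(reference, other) {
  get_ba <- function(x) if (is.numeric(x)) x else x$predictions$ba
  ref <- get_ba(reference); oth <- get_ba(other)
  ref_range <- max(ref) - min(ref)
  if (ref_range == 0) abort("reference BA range is zero.")
  100 * ((max(oth) - min(oth)) / ref_range - 1)
}

#' @method tidy ba_stack
#' @export
tidy.ba_stack <- function(x, ...) x$metrics

#' @method glance ba_stack
#' @export
glance.ba_stack <- function(x, ...) {
  m <- x$metrics
  tr <- m[m$partition == "train", ]; te <- m[m$partition == "test", ]
  tibble::tibble(meta_family = x$meta_family, n_base = length(x$base_specs),
                 folds = length(x$fold_train_ids),
                 train_rmse = tr$rmse, test_rmse = te$rmse,
                 rmse_gap = abs(tr$rmse - te$rmse),
                 test_r = te$pearson_r, test_mae = te$mae)
}

#' @method tidy ba_contrast
#' @export
tidy.ba_contrast <- function(x, ...) x$metrics

#' @method glance ba_contrast
#' @export
glance.ba_contrast <- function(x, ...) {
  m <- x$metrics
  tr <- m[m$partition == "train", ]; te <- m[m$partition == "test", ]
  tibble::tibble(mode = x$mode, constraint_met = x$constraint_met,
                 train_rmse = tr$rmse, test_rmse = te$rmse,
                 rmse_gap = abs(tr$rmse - te$rmse),
                 train_r = tr$pearson_r, test_r = te$pearson_r,
                 test_mae = te$mae)
}

#' Plot biological age against chronological age
#'
#' @param object a `ba_stack` or `ba_contrast`.
#' @param ... ignored.
#' @return a ggplot object, faceted by partition.
#' @method autoplot ba_stack
#' @export
autoplot.ba_stack <- function(object, ...) {
  ggplot2::ggplot(object$predictions, ggplot2::aes(.data$ca, .data$ba)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~partition) +
    ggplot2::labs(x = "chronological age (y)", y = "biological age (y)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ba_stack
#' @method autoplot ba_contrast
#' @export
autoplot.ba_contrast <- autoplot.ba_stack

#' Distribution summary of BA predictions by gender
#'
#' Min, max, median, mean (SD) and correlation with chronological age (with
#' its 95% interval), per gender and overall.
#'
#' @param predictions a BA prediction tibble (from a `ba_stack` or
#'   `ba_contrast`), or such an object itself.
#' @param cohort the cohort table supplying `gender` per participant.
#' @return a tibble with one row per (model_tag, group).
#' @export
ba_distribution <- function(predictions, cohort) {
  if (!is.data.frame(predictions)) predictions <- predictions$predictions
  joined <- dplyr::left_join(
    predictions,
    dplyr::select(cohort, "participant_id", "gender"),
    by = "participant_id"
  )
  one <- function(d, label) {
    fm <- fit_metrics(d$ba, d$ca)
    tibble::tibble(model_tag = d$model_tag[1], group = label,
                   min = min(d$ba), max = max(d$ba), median = median(d$ba),
                   mean = mean(d$ba), sd = sd(d$ba),
                   r = fm$pearson_r, r_low = fm$r_low, r_high = fm$r_high)
  }
  dplyr::bind_rows(
    one(dplyr::filter(joined, .data$gender == "male"), "male"),
    one(dplyr::filter(joined, .data$gender == "female"), "female"),
    one(joined, "total")
  )
}
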