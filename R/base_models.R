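#' Specify a base biological-age model
#'
#' @param family one of `"mlr"` (multiple linear regression), `"gam"`
#'   (spline additive model), `"svr"` (support-vector regression),
#'   `"adaboost"` (AdaBoost.R2 over shallow trees), `"extra_trees"`
#'   (extremely randomized trees), or one of four gradient-boosted-tree
#'   flavours `"gbt_xgb"`, `"gbt_lgbm"`, `"gbt_cat"`, `"gbt_shallow"`.
#' @param params named list of hyperparameter overrides for the family.
#' @param tag label used in outputs; defaults to the family name.
#' @return an object of class `base_model_spec`.
#' @export
base_model_spec <- function(family, params = list(), tag = family) {
  families <- c("mlr", "gam", "svr", "adaboost", "extra_trees",
                "gbt_xgb", "gbt_lgbm", "gbt_cat", "gbt_shallow")
  if (!family %in% families) {
    abort(paste0("unknown family `", family, "`."))
  }
  defaults <- switch(
    family,
    mlr = list(),
    gam = list(spline_k = 5),
    svr = list(cost = 1, gamma_scale = 1),
    adaboost = list(n_rounds = 50, maxdepth = 3),
    extra_trees = list(num.trees = 300, min.node.size = 5),
    gbt_xgb = list(eta = 0.05, max_depth = 6, nrounds = 300,
                   subsample = 0.8, colsample_bytree = 0.8,
                   min_child_weight = 10, lambda = 1),
    gbt_lgbm = list(eta = 0.07, max_depth = 7, nrounds = 250,
                    subsample = 0.8, colsample_bytree = 0.8,
                    min_child_weight = 10, lambda = 1),
    gbt_cat = list(eta = 0.04, max_depth = 7, nrounds = 300,
                   subsample = 0.9, colsample_bytree = 1,
                   min_child_weight = 5, lambda = 1),
    gbt_shallow = list(eta = 0.10, max_depth = 2, nrounds = 200,
                       subsample = 0.8, colsample_bytree = 1,
                       min_child_weight = 5, lambda = 1)
  )
  defaults[names(params)] <- params
  structure(list(family = family, params = defaults, tag = tag),
            class = "base_model_spec")
}

#' The five base families fused by the default stacked ensemble
#'
#' Four gradient-boosted-tree flavours (deep, light, slow-deep, shallow)
#' plus extremely randomized trees.
#'
#' @return a list of [base_model_spec()]s.
#' @export
default_base_specs <- function() {
  list(base_model_spec("gbt_xgb"), base_model_spec("gbt_lgbm"),
       base_model_spec("gbt_cat"), base_model_spec("gbt_shallow"),
       base_model_spec("extra_trees"))
}

#' The full model-zoo specification
#'
#' The stacking families plus multiple linear regression, a spline additive
#' model, support-vector regression, and AdaBoost.R2.
#'
#' @return a list of [base_model_spec()]s.
#' @export
zoo_base_specs <- function() {
  c(default_base_specs(),
    list(base_model_spec("mlr"), base_model_spec("gam"),
         base_model_spec("svr"), base_model_spec("adaboost")))
}

# ---- engines ---------------------------------------------------------------

adaboost_r2_fit <- function(df, y, n_rounds, maxdepth) {
  n <- nrow(df)
  w <- rep(1 / n, n)
  learners <- list(); betas <- numeric(0)
  for (t in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = y), weights = w,
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       cp = 0, xval = 0))
    err <- abs(predict(fit, df) - y)
    emax <- max(err)
    if (emax == 0) { learners <- c(learners, list(fit)); betas <- c(betas, 1e-10); break }
    L <- err / emax
    Lbar <- sum(w * L)
    if (Lbar >= 0.5) break
    beta <- Lbar / (1 - Lbar)
    learners <- c(learners, list(fit))
    betas <- c(betas, beta)
    w <- w * beta^(1 - L)
    w <- w / sum(w)
  }
  if (length(learners) == 0) { learners <- list(fit); betas <- 0.5 }
  structure(list(learners = learners, betas = betas), class = "adaboost_r2")
}

adaboost_r2_predict <- function(model, df) {
  P <- vapply(model$learners, function(f) predict(f, df), numeric(nrow(df)))
  if (is.null(dim(P))) P <- matrix(P, nrow = nrow(df))
  wts <- log(1 / pmax(model$betas, 1e-12))
  # weighted median across learners, row-wise
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(wts[o]) / sum(wts)
    p[o][which(cw >= 0.5)[1]]
  })
}

gam_formula <- function(df, k) {
  terms <- vapply(names(df), function(nm) {
    x <- df[[nm]]
    if (length(unique(x)) > 10) sprintf("s(%s, k = %d)", nm, k) else nm
  }, character(1))
  as.formula(paste(".y ~", paste(terms, collapse = " + ")))
}

fit_engine <- function(spec, df, y, seed = 1L) {
  fam <- spec$family; p <- spec$params
  with_seed(seed, {
    if (fam %in% c("gbt_xgb", "gbt_lgbm", "gbt_cat", "gbt_shallow")) {
      dm <- xgboost::xgb.DMatrix(as.matrix(df), label = y, nthread = 1)
      booster <- xgboost::xgb.train(
        params = list(eta = p$eta, max_depth = p$max_depth,
                      subsample = p$subsample,
                      colsample_bytree = p$colsample_bytree,
                      min_child_weight = p$min_child_weight,
                      lambda = if (is.null(p$lambda)) 1 else p$lambda,
                      objective = "reg:squarederror", nthread = 1),
        data = dm, nrounds = p$nrounds, verbose = 0
      )
      structure(list(fit = booster), class = "engine_xgb")
    } else if (fam == "extra_trees") {
      fit <- ranger::ranger(
        x = df, y = y, num.trees = p$num.trees, splitrule = "extratrees",
        min.node.size = p$min.node.size, replace = FALSE,
        sample.fraction = 1, num.random.splits = 1,
        importance = "impurity", num.threads = 1, seed = seed
      )
      structure(list(fit = fit), class = "engine_ranger")
    } else if (fam == "mlr") {
      structure(list(fit = lm(.y ~ ., data = cbind(df, .y = y)),
                     sds = vapply(df, sd, numeric(1))),
                class = "engine_lm")
    } else if (fam == "gam") {
      fml <- gam_formula(df, p$spline_k)
      structure(list(fit = mgcv::gam(fml, data = cbind(df, .y = y))),
                class = "engine_gam")
    } else if (fam == "svr") {
      structure(list(fit = e1071::svm(x = as.matrix(df), y = y,
                                      cost = p$cost, scale = TRUE)),
                class = "engine_svm")
    } else if (fam == "adaboost") {
      structure(list(fit = adaboost_r2_fit(df, y, p$n_rounds, p$maxdepth)),
                class = "engine_adaboost")
    }
  })
}

predict_engine <- function(model, df) {
  switch(class(model),
         engine_xgb = predict(model$fit, as.matrix(df)),
         engine_ranger = predict(model$fit, data = df,
                                 num.threads = 1)$predictions,
         engine_lm = unname(predict(model$fit, newdata = df)),
         engine_gam = unname(as.numeric(predict(model$fit, newdata = df))),
         engine_svm = unname(predict(model$fit, as.matrix(df))),
         engine_adaboost = adaboost_r2_predict(model$fit, df))
}

engine_importance <- function(model, df, y, seed = 1L) {
  # nonnegative per-feature importance; tree gain, |standardized
  # coefficient| for the linear family, permutation importance otherwise
  if (inherits(model, "engine_xgb")) {
    imp <- xgboost::xgb.importance(model = model$fit)
    out <- setNames(rep(0, ncol(df)), names(df))
    out[imp$Feature] <- imp$Gain
    out
  } else if (inherits(model, "engine_ranger")) {
    imp <- model$fit$variable.importance
    pmax(imp[names(df)], 0)
  } else if (inherits(model, "engine_lm")) {
    b <- coef(model$fit)[-1]
    abs(b * model$sds[names(df)])
  } else {
    base_mse <- mean((predict_engine(model, df) - y)^2)
    with_seed(seed, {
      vapply(names(df), function(nm) {
        dfp <- df
        dfp[[nm]] <- sample(dfp[[nm]])
        max(mean((predict_engine(model, dfp) - y)^2) - base_mse, 0)
      }, numeric(1))
    })
  }
}

# ---- model zoo -------------------------------------------------------------

#' Fit the biological-age model zoo
#'
#' Fits every requested base family on the training partition, evaluates
#' RMSE / R-squared / MAE / Pearson's r on both partitions, and ranks the
#' models by test-set correlation with chronological age.
#'
#' @param train,test disjoint cohort partitions (imputed, no oracle
#'   column).
#' @param specs list of [base_model_spec()]s.
#' @param features feature names (the screened set).
#' @param seed seed passed to stochastic engines.
#' @return an object of class `ba_zoo`: list with `models`, `metrics`
#'   (tibble, one row per model and partition), `specs`, `features`.
#' @export
fit_base_models <- function(train, test, specs = zoo_base_specs(),
                            features, seed = 1L) {
  check_no_oracle(train, "model fitting"); check_no_oracle(test, "model fitting")
  df_tr <- as.data.frame(feature_matrix(train, features))
  df_te <- as.data.frame(feature_matrix(test, features))
  if (anyNA(df_tr) || anyNA(df_te)) abort("NAs in the design matrix: impute first.")
  y_tr <- train$chronological_age
  y_te <- test$chronological_age
  models <- list(); rows <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    m <- fit_engine(sp, df_tr, y_tr, seed = seed + i)
    models[[sp$tag]] <- m
    for (part in c("train", "test")) {
      df <- if (part == "train") df_tr else df_te
      y <- if (part == "train") y_tr else y_te
      fm <- fit_metrics(predict_engine(m, df), y)
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(model_tag = sp$tag, partition = part), fm)
    }
  }
  metrics <- dplyr::bind_rows(rows)
  rank_tbl <- dplyr::arrange(
    dplyr::filter(metrics, .data$partition == "test"),
    dplyr::desc(.data$pearson_r)
  )
  structure(list(models = models, metrics = metrics, specs = specs,
                 features = features, ranking = rank_tbl$model_tag,
                 seed = seed),
            class = "ba_zoo")
}

#' @method tidy ba_zoo
#' @export
tidy.ba_zoo <- function(x, ...) x$metrics

#' Aggregate feature importance across base models
#'
#' Each model's nonnegative importances are normalized to weights summing
#' to one; the aggregate importance of a feature is the mean of its
#' normalized weights across models, and features are ranked by it.
#'
#' @param zoo a `ba_zoo` from [fit_base_models()] (or the `$zoo` of a
#'   stacked fit).
#' @param train the training table used to fit the zoo (needed for
#'   permutation importances).
#' @return a tibble: `feature`, one weight column per model, `aggregate`,
#'   sorted decreasing.
#' @export
aggregate_importance <- function(zoo, train) {
  df <- as.data.frame(feature_matrix(train, zoo$features))
  y <- train$chronological_age
  cols <- list(feature = zoo$features)
  for (tag in names(zoo$models)) {
    imp <- engine_importance(zoo$models[[tag]], df, y, seed = zoo$seed)
    tot <- sum(imp)
    if (tot == 0) abort(paste0("model `", tag, "` has all-zero importance."))
    cols[[tag]] <- unname(imp[zoo$features] / tot)
  }
  out <- tibble::as_tibble(cols)
  out$aggregate <- rowMeans(as.matrix(out[names(zoo$models)]))
  dplyr::arrange(out, dplyr::desc(.data$aggregate))
}
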