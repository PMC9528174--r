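#' Training-set standardization statistics
#'
#' Per-variable mean and variance computed on training rows only, used both
#' inside the imputers (all work on the standardized scale) and to put
#' masked-entry errors of variables with different units on a common scale.
#'
#' @param data complete cohort table (pre-injection).
#' @param train_idx integer indices of training rows.
#' @param columns variables to cover; defaults to [maskable_columns()].
#' @return a tibble `variable`, `mean`, `var`, `binary`.
#' @export
standardization_stats <- function(data, train_idx, columns = maskable_columns()) {
  block <- as.matrix(data[train_idx, columns, drop = FALSE])
  mu <- colMeans(block)
  v <- apply(block, 2, var)
  if (any(v <= 0)) {
    abort(paste0("zero training variance in: ",
                 paste(columns[v <= 0], collapse = ", ")))
  }
  binary <- apply(block, 2, function(x) all(x %in% c(0, 1)))
  tibble::tibble(variable = columns, mean = unname(mu), var = unname(v),
                 binary = unname(binary))
}

#' Configure an imputer
#'
#' @param method one of `"mean"`, `"knn"`, `"chained_multiple"` (multiple
#'   imputation by chained equations), `"round_robin_regression"`, or
#'   `"autoencoder"`.
#' @param k neighbour count (knn).
#' @param m number of completed tables (chained_multiple).
#' @param iterations chained-equation cycles per completed table.
#' @param max_iter,tol round-robin regression: maximum cycles and the
#'   convergence threshold on the maximum absolute change of any imputed
#'   value (standardized scale).
#' @param layers autoencoder hidden-layer widths (symmetric decoder is
#'   implied); input/output width is the number of maskable variables.
#' @param epochs,batch_size,learning_rate autoencoder training schedule.
#' @param activation `"tanh"` or `"relu"`.
#' @param seed seed for the method's own stochasticity.
#' @return an object of class `imputer_config`.
#' @export
imputer_config <- function(method = c("mean", "knn", "chained_multiple",
                                      "round_robin_regression", "autoencoder"),
                           k = 5L, m = 5L, iterations = 5L,
                           max_iter = 10L, tol = 1e-3,
                           layers = c(12L, 6L), epochs = 200L,
                           batch_size = 64L, learning_rate = 1e-3,
                           activation = c("tanh", "relu"), seed = 1L) {
  method <- match.arg(method)
  activation <- match.arg(activation)
  if (k < 1) abort("`k` must be >= 1.")
  if (m < 2) abort("`m` must be >= 2.")
  if (max_iter < 1) abort("`max_iter` must be >= 1.")
  if (tol <= 0) abort("`tol` must be > 0.")
  structure(
    list(method = method, k = as.integer(k), m = as.integer(m),
         iterations = as.integer(iterations), max_iter = as.integer(max_iter),
         tol = tol, layers = as.integer(layers), epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), learning_rate = learning_rate,
         activation = activation, seed = as.integer(seed)),
    class = "imputer_config"
  )
}

# least-squares fit tolerant of rank deficiency; returns coefficient vector
# (intercept first) with unidentifiable terms set to 0
ls_coef <- function(X, y) {
  fit <- stats::lm.fit(cbind(1, X), y)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  b
}

rr_cycle <- function(Xs, obs, train, order_j, noise_sd = NULL) {
  # one round-robin pass; returns list(Xs, max_change)
  max_change <- 0
  for (j in order_j) {
    miss_j <- which(!obs[, j])
    if (length(miss_j) == 0) next
    fit_rows <- which(train & obs[, j])
    b <- ls_coef(Xs[fit_rows, -j, drop = FALSE], Xs[fit_rows, j])
    pred <- drop(cbind(1, Xs[miss_j, -j, drop = FALSE]) %*% b)
    if (!is.null(noise_sd)) {
      res <- Xs[fit_rows, j] -
        drop(cbind(1, Xs[fit_rows, -j, drop = FALSE]) %*% b)
      s <- sqrt(sum(res^2) / max(1, length(fit_rows) - ncol(Xs)))
      pred <- pred + rnorm(length(pred), 0, s)
    }
    max_change <- max(max_change, max(abs(pred - Xs[miss_j, j])))
    Xs[miss_j, j] <- pred
  }
  list(Xs = Xs, max_change = max_change)
}

impute_round_robin <- function(Xs, obs, train, max_iter, tol, warn_converge = TRUE) {
  Xs[!obs] <- 0  # training mean on the standardized scale
  miss_rate <- colMeans(!obs)
  order_j <- order(miss_rate)
  order_j <- order_j[miss_rate[order_j] > 0]
  if (length(order_j) == 0) return(Xs)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- rr_cycle(Xs, obs, train, order_j)
    Xs <- step$Xs
    if (step$max_change < tol) { converged <- TRUE; break }
  }
  if (!converged && warn_converge) {
    warn("round-robin regression did not converge within `max_iter` cycles.")
  }
  Xs
}

# returns the list of m completed standardized tables; combination rules
# (mean for continuous, majority vote for binary) live in impute()
impute_chained <- function(Xs0, obs, train, cfg) {
  miss_rate <- colMeans(!obs)
  order_j <- order(miss_rate)
  order_j <- order_j[miss_rate[order_j] > 0]
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$m), function(r) {
      Xs <- Xs0
      Xs[!obs] <- 0
      for (it in seq_len(cfg$iterations)) {
        Xs <- rr_cycle(Xs, obs, train, order_j, noise_sd = TRUE)$Xs
      }
      Xs
    })
  })
}

impute_knn <- function(Xs, obs, train, k, chunk = 512L) {
  filled <- Xs
  filled[!obs] <- 0
  A_tr <- filled[train, , drop = FALSE]
  A_tr[!obs[train, , drop = FALSE]] <- 0
  O_tr <- obs[train, , drop = FALSE] * 1
  A2_tr <- t(A_tr^2)
  rows_missing <- which(rowSums(!obs) > 0)
  for (start in seq(1, length(rows_missing), by = chunk)) {
    idx <- rows_missing[start:min(start + chunk - 1L, length(rows_missing))]
    A_q <- Xs[idx, , drop = FALSE]
    O_q <- obs[idx, , drop = FALSE] * 1
    A_q[O_q == 0] <- 0
    d2 <- (A_q^2) %*% t(O_tr) + O_q %*% A2_tr - 2 * A_q %*% t(A_tr)
    share <- O_q %*% t(O_tr)
    d2 <- d2 / pmax(share, 1)        # mean squared diff over shared coords
    d2[share == 0] <- Inf
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      for (j in which(!obs[i, ])) {
        cand <- which(obs[train, j, drop = TRUE])
        if (length(cand) == 0) next
        dd <- d2[ii, cand]
        nb <- cand[order(dd)[seq_len(min(k, length(cand)))]]
        filled[i, j] <- mean(A_tr[nb, j])
      }
    }
  }
  filled
}

#' Fill missing values
#'
#' Completes a table with gaps using one of five imputers: training-column
#' mean; k-nearest-neighbour averaging under an NA-aware Euclidean distance
#' (squared differences averaged over jointly observed coordinates);
#' round-robin linear regression (columns cycled in ascending missing-rate
#' order, each incomplete column regressed on all others and its missing
#' entries overwritten, until the largest change falls below `tol`);
#' chained-equation multiple imputation (the same cycle with Gaussian
#' residual noise, `m` completed tables combined); or a symmetric
#' autoencoder trained with reconstruction loss on observed entries only.
#' All methods are fitted on training rows only and work on the
#' standardized scale. Observed cells are never altered. Binary variables
#' are thresholded: a prediction greater than 0.5 becomes 1, otherwise 0.
#'
#' @param data table with `NA`s in the maskable block.
#' @param mask logical matrix from [inject_missing()] (`TRUE` = absent).
#' @param config an [imputer_config()].
#' @param stats a [standardization_stats()] table from training rows.
#' @param train_idx integer indices of training rows; defaults to all rows.
#' @return the completed table as a tibble.
#' @export
impute <- function(data, mask, config, stats, train_idx = seq_len(nrow(data))) {
  stopifnot(inherits(config, "imputer_config"))
  check_no_oracle(data, "imputation")
  cols <- stats$variable
  X <- as.matrix(data[cols])
  if (!identical(dim(mask), dim(X))) abort("`mask` shape must match the maskable block.")
  obs <- !mask
  if (any(is.na(X) & obs)) abort("`mask` must mark every absent cell.")
  all_missing <- colSums(obs[train_idx, , drop = FALSE]) == 0
  if (any(all_missing)) {
    abort(paste0("no training signal (entirely missing): ",
                 paste(cols[all_missing], collapse = ", ")))
  }
  if (!any(mask)) return(tibble::as_tibble(data))

  mu <- stats$mean; s <- sqrt(stats$var)
  Xs <- sweep(sweep(X, 2, mu), 2, s, "/")
  train <- rep(FALSE, nrow(X)); train[train_idx] <- TRUE
  p <- length(cols)

  # always-observed covariates (age, gender) join the predictor block for
  # every conditional method; they are never imputation targets
  aux <- NULL
  std_by_train <- function(x) {
    s0 <- sd(x[train_idx])
    if (is.na(s0) || s0 == 0) return(NULL)
    (x - mean(x[train_idx])) / s0
  }
  if ("chronological_age" %in% names(data)) {
    aux <- cbind(aux, age = std_by_train(data$chronological_age))
  }
  if ("gender" %in% names(data)) {
    g <- std_by_train(as.numeric(data$gender == "female"))
    if (!is.null(g)) aux <- cbind(aux, female = g)
  }
  A <- cbind(Xs, aux)
  obsA <- cbind(obs, matrix(TRUE, nrow(X), ncol(A) - p))

  if (config$method == "chained_multiple") {
    reps <- impute_chained(A, obsA, train, config)
    rep_blocks <- lapply(reps, function(Z)
      sweep(sweep(Z[, seq_len(p), drop = FALSE], 2, s, "*"), 2, mu, "+"))
    out_block <- Reduce(`+`, rep_blocks) / length(rep_blocks)
    # binary: majority vote over the m thresholded completions (tie -> 0)
    for (j in which(stats$binary)) {
      votes <- vapply(rep_blocks, function(B) as.numeric(B[, j] > 0.5),
                      numeric(nrow(X)))
      out_block[mask[, j], j] <-
        as.numeric(rowMeans(votes)[mask[, j]] > 0.5)
    }
  } else {
    Xs_hat <- switch(
      config$method,
      mean = { Z <- Xs; Z[!obs] <- 0; Z },
      knn = impute_knn(A, obsA, train, config$k)[, seq_len(p), drop = FALSE],
      round_robin_regression =
        impute_round_robin(A, obsA, train, config$max_iter,
                           config$tol)[, seq_len(p), drop = FALSE],
      autoencoder =
        impute_autoencoder(A, obsA, train, config)[, seq_len(p), drop = FALSE]
    )
    out_block <- sweep(sweep(Xs_hat, 2, s, "*"), 2, mu, "+")
    # binary rule: predicted value > 0.5 -> 1, otherwise 0 (0.5 itself -> 0)
    for (j in which(stats$binary)) {
      out_block[mask[, j], j] <- as.numeric(out_block[mask[, j], j] > 0.5)
    }
  }
  out_block[obs] <- X[obs]  # observed cells bit-identical
  out <- data
  for (j in seq_along(cols)) out[[cols[j]]] <- out_block[, j]
  tibble::as_tibble(out)
}

#' Score an imputation against the truth on masked cells
#'
#' Both tables are standardized by the training-set statistics; MSE and the
#' coefficient of determination are computed over masked cells only, with
#' the total sum of squares taken about the masked-cell truth mean.
#'
#' @param completed imputed table.
#' @param truth the original complete table.
#' @param mask logical removal matrix (`TRUE` = was absent).
#' @param stats a [standardization_stats()] table.
#' @return a one-row tibble `mse`, `r2`, `n_cells`.
#' @export
score_imputation <- function(completed, truth, mask, stats) {
  cols <- stats$variable
  if (!any(mask)) abort("empty mask: imputation score undefined.")
  s <- sqrt(stats$var)
  Zc <- sweep(sweep(as.matrix(completed[cols]), 2, stats$mean), 2, s, "/")
  Zt <- sweep(sweep(as.matrix(truth[cols]), 2, stats$mean), 2, s, "/")
  err <- (Zc - Zt)[mask]
  tru <- Zt[mask]
  mse <- mean(err^2)
  ss_tot <- sum((tru - mean(tru))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(err^2) / ss_tot
  tibble::tibble(mse = mse, r2 = r2, n_cells = sum(mask))
}
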