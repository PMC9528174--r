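# Dense symmetric autoencoder for tabular imputation.
#
# Encoder widths come from `config$layers`; the decoder mirrors them, so the
# default [12, 6] on a 19-column block gives 19 -> 12 -> 6 -> 12 -> 19.
# Hidden activations are tanh (or ReLU), the output layer is linear, and the
# reconstruction loss is squared error restricted to observed entries, so
# missing cells (zero-filled at the input, i.e. the training mean on the
# standardized scale) never contribute gradient. Optimized with Adam on
# minibatches of training rows; imputation is one forward pass over all rows.

ae_init <- function(widths) {
  L <- length(widths) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (widths[l] + widths[l + 1]))
    W[[l]] <- matrix(runif(widths[l] * widths[l + 1], -lim, lim),
                     widths[l], widths[l + 1])
    b[[l]] <- rep(0, widths[l + 1])
  }
  list(W = W, b = b)
}

ae_forward <- function(par, X, act) {
  L <- length(par$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    A[[l + 1]] <- if (l < L) act(Z) else Z
  }
  A
}

impute_autoencoder <- function(Xs, obs, train, config) {
  p <- ncol(Xs)
  widths <- c(p, config$layers, rev(config$layers[-length(config$layers)]), p)
  act <- switch(config$activation,
                tanh = tanh,
                relu = function(z) pmax(z, 0))
  dact <- switch(config$activation,
                 tanh = function(a) 1 - a^2,        # in terms of activation
                 relu = function(a) (a > 0) * 1)

  X0 <- Xs; X0[!obs] <- 0
  Xtr <- X0[train, , drop = FALSE]
  Otr <- obs[train, , drop = FALSE] * 1
  ntr <- nrow(Xtr)
  L <- length(widths) - 1

  with_seed(config$seed, {
    par <- ae_init(widths)
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
    lr <- config$learning_rate
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(ntr)
      starts <- seq(1, ntr, by = config$batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + config$batch_size - 1L, ntr)]
        Xb <- Xtr[idx, , drop = FALSE]
        Ob <- Otr[idx, , drop = FALSE]
        A <- ae_forward(par, Xb, act)
        # d loss / d output; loss = sum_obs (yhat - x)^2 / n_obs
        n_obs <- max(1, sum(Ob))
        delta <- 2 * (A[[L + 1]] - Xb) * Ob / n_obs
        t <- t + 1
        for (l in L:1) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(par$W[[l]])) * dact(A[[l]])
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          par$W[[l]] <- par$W[[l]] -
            lr * (mW[[l]] / (1 - beta1^t)) / (sqrt(vW[[l]] / (1 - beta2^t)) + eps)
          par$b[[l]] <- par$b[[l]] -
            lr * (mb[[l]] / (1 - beta1^t)) / (sqrt(vb[[l]] / (1 - beta2^t)) + eps)
        }
      }
    }
    out <- ae_forward(par, X0, act)[[L + 1]]
    Xs[!obs] <- out[!obs]
    Xs
  })
}
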