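# Small cohort builders and an independent IRLS reference used across files.

small_cohort <- function(n = 500, seed = 1, ...) {
  generate_cohort(cohort_spec(n_participants = n, seed = seed, ...))
}

# A cohort with no planted signal at all: flat markers, no aging-rate
# heterogeneity, no marker correlation.
null_cohort <- function(n = 500, seed = 1) {
  bd <- default_biomarker_defs()
  bd$age_slope <- 0; bd$quad <- 0; bd$gender_shift <- 0
  bd$loading[!is.na(bd$loading)] <- 0; bd$delta_extra <- 0
  ad <- default_anthro_defs()
  ad$age_slope <- 0; ad$gender_shift <- 0
  ad$loading <- 0; ad$delta_extra <- 0
  generate_cohort(cohort_spec(n_participants = n, latent_aging_sd = 0,
                              female_delta_shift = 0,
                              biomarker_defs = bd, anthro_defs = ad,
                              seed = seed))
}

# Independent iteratively-reweighted least-squares reference for GLMs.
# Deliberately written from the textbook update, not via stats::glm.
irls_ref <- function(X, y, family) {
  beta <- rep(0, ncol(X))
  if (family$family == "poisson") beta[1] <- log(mean(y) + 1e-8)
  for (i in 1:200) {
    eta <- as.vector(X %*% beta)
    mu <- family$linkinv(eta)
    me <- family$mu.eta(eta)
    w <- me^2 / family$variance(mu)
    z <- eta + (y - mu) / me
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-13) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- as.vector(X %*% beta)
  mu <- family$linkinv(eta)
  w <- family$mu.eta(eta)^2 / family$variance(mu)
  se <- sqrt(diag(solve(crossprod(X, w * X))))
  list(coef = as.vector(beta), se = unname(as.vector(se)))
}

ols_ref <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% b
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coef = as.vector(b), se = unname(sqrt(diag(solve(crossprod(X)) * s2))))
}

# The non-collinear screen fixture: 19 age-linked candidates plus 3 null
# candidates orthogonalized against age in-sample (their sample correlation
# with CA is exactly zero), mirroring the candidate bookkeeping of the
# two-step screen (22 candidates, 3 expected drops).
screen_fixture <- function(n = 6000, seed = 1) {
  withr::with_seed(seed, {
    ca <- pmin(pmax(rnorm(n, 67, 10), 45), 90)
    slopes <- seq(0.15, 0.6, length.out = 19)
    signal <- lapply(seq_len(19), function(j) as.numeric(slopes[j] * scale(ca) + rnorm(n)))
    names(signal) <- paste0("marker_", sprintf("%02d", seq_len(19)))
    noise <- lapply(1:3, function(j) unname(resid(lm(rnorm(n) ~ ca))))
    names(noise) <- paste0("null_marker_", 1:3)
    tibble::tibble(chronological_age = ca, !!!signal, !!!noise)
  })
}

make_assoc_fixture <- function() {
  withr::with_seed(33, {
    n <- 30
    tibble::tibble(
      participant_id = 1:n,
      chronological_age = round(runif(n, 45, 90)),
      gender = factor(sample(c("male", "female"), n, TRUE),
                      levels = c("male", "female")),
      height = round(runif(n, 1.5, 1.85), 2),
      weight = round(runif(n, 50, 85), 1),
      waist = round(runif(n, 0.7, 1.05), 2),
      family_disease = rbinom(n, 1, 0.3),
      disease_kidney = rep(c(0L, 1L), 15),
      disease_heart = rbinom(n, 1, 0.4),
      ba = round(runif(n, 45, 90), 1)
    ) |>
      dplyr::mutate(bmi = weight / height^2)
  })
}
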