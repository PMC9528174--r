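#' A Body Shape Index
#'
#' `ABSI = WC / (BMI^(2/3) * Height^(1/2))`: waist circumference adjusted
#' for height and weight. With waist and height in metres and BMI in
#' kg/m^2 this is the mortality-risk body-shape index on its usual scale
#' (values around 0.07-0.09).
#'
#' @param waist waist circumference (m).
#' @param bmi body mass index (kg/m^2).
#' @param height height (m).
#' @return numeric vector.
#' @export
#' @examples
#' absi(waist = 0.85, bmi = 70 / 1.7^2, height = 1.7)
absi <- function(waist, bmi, height) {
  if (any(waist <= 0 | bmi <= 0 | height <= 0)) {
    abort("ABSI inputs must be positive.")
  }
  waist / (bmi^(2 / 3) * sqrt(height))
}

#' Waist-to-height ratio
#'
#' @param waist waist circumference.
#' @param height height, in the same unit as `waist`.
#' @return numeric vector.
#' @export
whtr <- function(waist, height) {
  if (any(height <= 0) || any(waist <= 0)) abort("inputs must be positive.")
  waist / height
}

#' Add health-risk indices to a cohort table
#'
#' @param data cohort table with `waist`, `height`, `bmi`.
#' @return `data` with `absi` and `whtr` columns appended.
#' @export
add_health_indices <- function(data) {
  dplyr::mutate(data,
                absi = absi(.data$waist, .data$bmi, .data$height),
                whtr = whtr(.data$waist, .data$height))
}

#' Quantile-group assignment with stable tie handling
#'
#' Splits an indicator into `n_groups` ordered groups whose sizes differ
#' by at most one; ties are broken by the stable participant order so the
#' partition is deterministic.
#'
#' @param x numeric indicator.
#' @param n_groups number of groups (default 5: Q1-Q5).
#' @return ordered factor `Q1`..`Qn`.
#' @export
quantile_groups <- function(x, n_groups = 5) {
  q <- dplyr::ntile(x, n_groups)
  factor(paste0("Q", q), levels = paste0("Q", seq_len(n_groups)),
         ordered = FALSE)
}

#' Three-category disease count
#'
#' Sums the seven disease flags and categorises as no disease, one
#' disease, or two-or-more.
#'
#' @param data cohort table with the disease-flag columns.
#' @param diseases names of the disease-flag columns.
#' @return `data` with `disease_count` (0-7) and `disease_cat`
#'   (factor `0`, `1`, `2+`) appended.
#' @export
add_disease_count <- function(data, diseases = disease_names()) {
  cnt <- rowSums(as.matrix(data[diseases]))
  dplyr::mutate(data,
                disease_count = as.integer(cnt),
                disease_cat = factor(ifelse(cnt >= 2, "2+", as.character(cnt)),
                                     levels = c("0", "1", "2+")))
}

ba_cohort_frame <- function(ba, cohort) {
  if (!is.data.frame(ba)) ba <- ba$predictions
  check_no_oracle(cohort, "association analysis")
  dplyr::inner_join(
    dplyr::select(ba, "participant_id", "model_tag", "ba"),
    cohort, by = "participant_id"
  )
}

assoc_row <- function(fit, term, ba_tag, outcome, model_kind, adjustment,
                      logistic = FALSE) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) {
    abort(paste0("term `", term, "` absent from the fit (degenerate design)."))
  }
  est <- sm[term, 1]; se <- sm[term, 2]; stat <- sm[term, 3]; p <- sm[term, 4]
  tibble::tibble(
    ba_tag = ba_tag, outcome = outcome, model_kind = model_kind,
    adjustment = adjustment, term = term, estimate = est, std_error = se,
    statistic = stat, p_value = p,
    odds_ratio = if (logistic) exp(est) else NA_real_,
    or_low = if (logistic) exp(est - qnorm(0.975) * se) else NA_real_,
    or_high = if (logistic) exp(est + qnorm(0.975) * se) else NA_real_
  )
}

adjust_terms <- function(adjustment, battery) {
  if (adjustment == "model1") return(character(0))
  if (battery == "risk") c("chronological_age", "bmi", "family_disease")
  else c("chronological_age", "family_disease")
}

#' Associations of BA with a continuous health-risk indicator
#'
#' Linear models of biological age on ABSI or WHtR, both as a continuous
#' exposure and as quintile groups contrasted against Q1. Model 1 is
#' crude; Model 2 adjusts for chronological age, BMI and family disease
#' status.
#'
#' @param ba BA predictions (tibble or a `ba_stack` / `ba_contrast`).
#' @param cohort cohort table (oracle column dropped).
#' @param indicator `"absi"` or `"whtr"`.
#' @param adjustment character vector from `c("model1", "model2")`.
#' @return a tibble of class `ba_assoc`: continuous-exposure rows plus one
#'   row per quintile contrast, per adjustment.
#' @export
risk_indicator_battery <- function(ba, cohort,
                                   indicator = c("absi", "whtr"),
                                   adjustment = c("model1", "model2")) {
  indicator <- match.arg(indicator)
  adjustment <- match.arg(adjustment, several.ok = TRUE)
  d <- ba_cohort_frame(ba, cohort)
  if (!indicator %in% names(d)) d <- add_health_indices(d)
  d$quintile <- quantile_groups(d[[indicator]])
  if (min(table(d$quintile)) < 2) abort("quintile group with fewer than 2 rows.")
  out <- list()
  for (adj in adjustment) {
    covars <- adjust_terms(adj, "risk")
    f_cont <- as.formula(paste("ba ~", paste(c(indicator, covars), collapse = " + ")))
    fit <- lm(f_cont, data = d)
    out[[length(out) + 1L]] <-
      assoc_row(fit, indicator, d$model_tag[1], indicator, "linear", adj)
    f_q <- as.formula(paste("ba ~", paste(c("quintile", covars), collapse = " + ")))
    fit_q <- lm(f_q, data = d)
    for (lev in levels(d$quintile)[-1]) {
      out[[length(out) + 1L]] <-
        assoc_row(fit_q, paste0("quintile", lev), d$model_tag[1],
                  paste0(indicator, "_quintile"), "linear", adj)
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("ba_assoc", class(res))
  res
}

#' Associations of BA with disease counts
#'
#' Two complementary fits per adjustment: (a) a linear model with BA as
#' the dependent variable and the three-category disease count as
#' predictor, giving BA increments for 1 and 2+ diseases relative to
#' disease-free participants; (b) a Poisson regression of the raw disease
#' count on BA. Model 2 adjusts for chronological age and family disease
#' status.
#'
#' @inheritParams risk_indicator_battery
#' @param diseases names of the disease-flag columns.
#' @return a `ba_assoc` tibble.
#' @export
disease_count_battery <- function(ba, cohort,
                                  adjustment = c("model1", "model2"),
                                  diseases = intersect(disease_names(), names(cohort))) {
  adjustment <- match.arg(adjustment, several.ok = TRUE)
  d <- ba_cohort_frame(ba, cohort)
  d <- add_disease_count(d, diseases)
  if (any(table(d$disease_cat) == 0)) abort("empty disease-count category.")
  out <- list()
  for (adj in adjustment) {
    covars <- adjust_terms(adj, "disease")
    f_lin <- as.formula(paste("ba ~", paste(c("disease_cat", covars), collapse = " + ")))
    fit_lin <- lm(f_lin, data = d)
    for (lev in c("1", "2+")) {
      out[[length(out) + 1L]] <-
        assoc_row(fit_lin, paste0("disease_cat", lev), d$model_tag[1],
                  "ba_increment", "linear", adj)
    }
    f_pois <- as.formula(paste("disease_count ~", paste(c("ba", covars), collapse = " + ")))
    fit_p <- glm(f_pois, data = d, family = poisson(),
                 control = list(epsilon = 1e-12, maxit = 100))
    out[[length(out) + 1L]] <-
      assoc_row(fit_p, "ba", d$model_tag[1], "disease_count", "poisson", adj)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("ba_assoc", class(res))
  res
}

#' Per-disease logistic associations with BA
#'
#' One logistic regression per disease flag, reporting the odds ratio per
#' one-year increase in BA with its 95% Wald interval. Fits showing signs
#' of separation (a flag perfectly predicted) are marked in the
#' `separation` column rather than silently accepted.
#'
#' @inheritParams disease_count_battery
#' @return a `ba_assoc` tibble with one row per (disease, adjustment).
#' @export
per_disease_battery <- function(ba, cohort,
                                adjustment = c("model1", "model2"),
                                diseases = intersect(disease_names(), names(cohort))) {
  adjustment <- match.arg(adjustment, several.ok = TRUE)
  d <- ba_cohort_frame(ba, cohort)
  out <- list()
  for (dis in diseases) {
    if (length(unique(d[[dis]])) < 2) {
      abort(paste0("disease flag `", dis, "` has a single class."))
    }
    for (adj in adjustment) {
      covars <- adjust_terms(adj, "disease")
      f <- as.formula(paste(dis, "~", paste(c("ba", covars), collapse = " + ")))
      fit <- suppressWarnings(glm(f, data = d, family = binomial(),
                                  control = list(epsilon = 1e-12, maxit = 100)))
      row <- assoc_row(fit, "ba", d$model_tag[1], dis, "logistic", adj,
                       logistic = TRUE)
      mu <- fitted(fit)
      row$separation <- !fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8) ||
        abs(coef(fit)[["ba"]]) > 10
      out[[length(out) + 1L]] <- row
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("ba_assoc", class(res))
  res
}

#' Forest-style plot of association results
#'
#' @param object a `ba_assoc` tibble.
#' @param ... ignored.
#' @return a ggplot object: estimates (odds ratios for logistic rows) with
#'   95% intervals per outcome, coloured by adjustment.
#' @method autoplot ba_assoc
#' @export
autoplot.ba_assoc <- function(object, ...) {
  d <- dplyr::mutate(
    object,
    center = ifelse(.data$model_kind == "logistic", .data$odds_ratio, .data$estimate),
    low = ifelse(.data$model_kind == "logistic", .data$or_low,
                 .data$estimate - qnorm(0.975) * .data$std_error),
    high = ifelse(.data$model_kind == "logistic", .data$or_high,
                  .data$estimate + qnorm(0.975) * .data$std_error),
    label = paste(.data$outcome, .data$term, sep = ": ")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$center, .data$label,
                                  colour = .data$adjustment)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$low, xmax = .data$high),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::labs(x = "estimate", y = NULL) +
    ggplot2::theme_minimal()
}
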