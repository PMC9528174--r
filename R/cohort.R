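#' Default biomarker definitions for the synthetic examination cohort
#'
#' One row per marker. Continuous markers follow
#' `base_mean + age_slope * (EA - 65) + quad * (EA - 65)^2 + gender_shift *
#' female + loading * F_block + noise`, where `EA = CA + delta` is effective
#' age (chronological age plus the hidden per-person aging offset) and
#' `F_block` is a standard-normal latent factor shared by all markers in the
#' same `corr_block`. Binary (urine dipstick) markers are Bernoulli with
#' logit `base_mean + age_slope * (EA - 65) + gender_shift * female`.
#'
#' Units follow routine Chinese physical-examination reporting (mmHg for
#' pressures, g/L hemoglobin, 10^9/L cell counts, mmol/L glucose and lipids,
#' U/L transaminases, umol/L bilirubin); height and waist are in metres so
#' that body-shape indices use coherent units. The three dipstick markers
#' urine sugar, urine ketone body and urine occult blood are generated with
#' no age or aging-rate signal: they are the markers the feature screen is
#' expected to discard.
#'
#' @return a tibble with columns `name`, `kind`, `base_mean`, `base_sd`,
#'   `age_slope`, `gender_shift`, `quad`, `corr_block`, `loading`,
#'   `delta_extra` (additional per-year-of-delta effect beyond the shared
#'   effective-age slope).
#' @export
default_biomarker_defs <- function() {
  tibble::tribble(
    ~name,              ~kind,        ~base_mean, ~base_sd, ~age_slope, ~gender_shift, ~quad,    ~corr_block, ~loading, ~delta_extra,
    "sbp",              "continuous", 132,        11,        0.50,      -2.0,           0,       "cardio",    11.0,     0.30,
    "dbp",              "continuous", 79,         6,        -0.18,      -1.5,           0,       "cardio",    7.0,      0.12,
    "hemoglobin",       "continuous", 143,        8,        -0.30,      -10.0,          0,       "hemat",     7.0,     -0.15,
    "white_blood_cell", "continuous", 6.2,        1.15,      0.012,     -0.25,          0,       "hemat",     0.70,     0.012,
    "platelets",        "continuous", 226,        35,       -0.90,      12.0,           0,       "hemat",     30.0,    -0.40,
    "fsg",              "continuous", 5.5,        0.95,      0.020,     -0.06,          4e-4,    "metab",     0.35,     0.020,
    "sgpt",             "continuous", 25,         6.5,      -0.16,      -5.5,           0,       "liver",     7.5,     -0.08,
    "sgot",             "continuous", 24,         4.5,       0.09,      -3.5,           0,       "liver",     6.0,     0.05,
    "serum_bilirubin",  "continuous", 13.5,       3.6,       0.045,     -1.6,           0,       "liver",     2.0,     0.02,
    "tc",               "continuous", 4.95,       0.50,      0.012,      0.28,         -4e-4,    "lipid",     0.75,     0.010,
    "tg",               "continuous", 1.55,       0.60,     -0.012,      0.09,          0,       "lipid",     0.32,     0.006,
    "ldl",              "continuous", 2.90,       0.42,      0.010,      0.16,          0,       "lipid",     0.65,     0.008,
    "hdl",              "continuous", 1.36,       0.27,      0.0035,     0.16,          0,       "lipid",    -0.12,     0.001,
    "urine_protein",    "binary",    -2.5,        NA,        0.045,     -0.25,          0,       NA,          NA,       0.030,
    "urine_sugar",      "binary",    -3.0,        NA,        0,          0,             0,       NA,          NA,       0,
    "urine_ketone",     "binary",    -3.3,        NA,        0,          0,             0,       NA,          NA,       0,
    "urine_occult",     "binary",    -3.0,        NA,        0,          0,             0,       NA,          NA,       0
  )
}

#' Default anthropometry definitions
#'
#' Height (m), weight (kg) and waist circumference (m) follow the same
#' linear effective-age model as the continuous biomarkers; BMI is derived
#' as `weight / height^2` and never drawn. Waist carries an additional
#' per-year-of-delta loading so that the hidden aging rate reaches
#' body-shape indices (ABSI, WHtR) beyond what chronological age explains.
#'
#' @return a tibble shaped like [default_biomarker_defs()].
#' @export
default_anthro_defs <- function() {
  tibble::tribble(
    ~name,    ~kind,        ~base_mean, ~base_sd, ~age_slope, ~gender_shift, ~quad, ~corr_block, ~loading, ~delta_extra,
    "height", "continuous", 1.685,      0.052,    -0.0020,    -0.125,        0,     "anthro",    0.020,    -0.0006,
    "weight", "continuous", 66.5,       5.0,      -0.25,      -8.0,          0,     "anthro",    6.5,      0.10,
    "waist",  "continuous", 0.885,      0.048,     0.0018,    -0.048,        0,     "anthro",    0.055,    0.0035
  )
}

#' Default disease definitions
#'
#' Each of the seven post-examination disease categories is Bernoulli with
#' logit `intercept + beta_age * (CA - 65) + beta_delta * delta +
#' beta_family * family_disease`. `beta_delta` is the planted effect of the
#' hidden aging rate: a useful biological-age estimate should recover it.
#'
#' @return a tibble with columns `name`, `intercept`, `beta_age`,
#'   `beta_delta`, `beta_family`.
#' @export
default_disease_defs <- function() {
  tibble::tribble(
    ~name,                     ~intercept, ~beta_age, ~beta_delta, ~beta_family,
    "disease_cerebrovascular", -3.2,        0.050,     0.080,       0.35,
    "disease_kidney",          -3.4,        0.030,     0.080,       0.30,
    "disease_heart",           -2.6,        0.045,     0.060,       0.40,
    "disease_vascular",        -2.9,        0.040,     0.045,       0.30,
    "disease_eye",             -2.8,        0.055,     0.070,       0.20,
    "disease_nervous",         -3.5,        0.035,     0.075,       0.25,
    "disease_other",           -1.8,        0.030,     0.050,       0.30
  )
}

#' Specify a synthetic physical-examination cohort
#'
#' @param n_participants number of participants to draw.
#' @param age_range closed interval of chronological age in years.
#' @param prop_female fraction of female participants.
#' @param latent_aging_sd SD (years) of the hidden per-person aging offset
#'   delta; 0 removes all aging-rate heterogeneity.
#' @param female_delta_shift mean shift (years) of delta for women; the
#'   default is slightly negative, mirroring the observation that women are
#'   biologically somewhat younger than men of the same age.
#' @param family_disease_rate marginal probability of a positive family
#'   disease history.
#' @param biomarker_defs,anthro_defs,disease_defs definition tables; see
#'   [default_biomarker_defs()], [default_anthro_defs()],
#'   [default_disease_defs()].
#' @param seed integer seed; a fixed seed yields a byte-identical cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 5000,
                        age_range = c(45, 90),
                        prop_female = 0.55,
                        latent_aging_sd = 4,
                        female_delta_shift = -0.5,
                        family_disease_rate = 0.15,
                        biomarker_defs = default_biomarker_defs(),
                        anthro_defs = default_anthro_defs(),
                        disease_defs = default_disease_defs(),
                        seed = 1L) {
  stopifnot(length(age_range) == 2, is.numeric(age_range))
  if (n_participants <= 0) abort("`n_participants` must be positive.")
  if (age_range[1] >= age_range[2]) abort("`age_range` must be increasing.")
  if (prop_female < 0 || prop_female > 1) abort("`prop_female` must be in [0, 1].")
  if (latent_aging_sd < 0) abort("`latent_aging_sd` must be >= 0.")
  if (nrow(biomarker_defs) == 0) abort("`biomarker_defs` must be nonempty.")
  cont <- dplyr::filter(biomarker_defs, .data$kind == "continuous")
  if (any(!is.na(cont$base_sd) & cont$base_sd <= 0)) {
    abort("continuous biomarkers need `base_sd` > 0.")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      age_range = as.numeric(age_range),
      prop_female = prop_female,
      latent_aging_sd = latent_aging_sd,
      female_delta_shift = female_delta_shift,
      family_disease_rate = family_disease_rate,
      biomarker_defs = biomarker_defs,
      anthro_defs = anthro_defs,
      disease_defs = disease_defs,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

draw_marker_block <- function(defs, ea_c, female, delta, factors, n) {
  out <- list()
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    lin <- d$base_mean + d$age_slope * ea_c + d$quad * ea_c^2 +
      d$gender_shift * female + d$delta_extra * delta
    if (d$kind == "continuous") {
      f <- if (!is.na(d$corr_block)) d$loading * factors[[d$corr_block]] else 0
      out[[d$name]] <- as.numeric(lin + f + rnorm(n, 0, d$base_sd))
    } else {
      out[[d$name]] <- rbinom(n, 1L, plogis(lin))
    }
  }
  out
}

#' Generate a synthetic physical-examination cohort
#'
#' Draws a participant table with the structure the downstream biological
#' age pipeline assumes: chronological age, gender, anthropometry with
#' derived BMI, 13 continuous biochemical markers, 4 binary urine dipstick
#' markers, 7 disease flags, a family disease flag — plus the oracle-only
#' `latent_delta` column holding each participant's hidden aging offset.
#' Chronological age is drawn from a normal distribution centred on the
#' middle of `age_range` (SD 10 y) truncated to the range, giving the
#' elderly-heavy shape of a 45-90 y examination cohort.
#'
#' @param spec a [cohort_spec()].
#' @return a tibble with one row per participant.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_participants = 200, seed = 7))
#' dplyr::glimpse(drop_oracle(coh))
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  with_seed(spec$seed, {
    mid <- mean(spec$age_range)
    ca <- rnorm(n, mid, 10)
    # resample out-of-range draws (truncation)
    bad <- which(ca < spec$age_range[1] | ca > spec$age_range[2])
    while (length(bad) > 0) {
      ca[bad] <- rnorm(length(bad), mid, 10)
      bad <- bad[ca[bad] < spec$age_range[1] | ca[bad] > spec$age_range[2]]
    }
    # the female fraction rises mildly with age (differential survival);
    # prop_female is the marginal probability at age 65
    p_f <- plogis(qlogis(spec$prop_female) + 0.02 * (ca - 65))
    female <- as.integer(runif(n) < p_f)
    delta <- rnorm(n, 0, spec$latent_aging_sd) +
      spec$female_delta_shift * female
    ea_c <- ca + delta - 65

    blocks <- unique(stats::na.omit(c(spec$biomarker_defs$corr_block,
                                      spec$anthro_defs$corr_block)))
    factors <- setNames(
      lapply(blocks, function(b) rnorm(n)), blocks
    )

    anthro <- draw_marker_block(spec$anthro_defs, ea_c, female, delta, factors, n)
    anthro$height <- pmax(anthro$height, 1.30)
    anthro$weight <- pmax(anthro$weight, 35)
    anthro$waist <- pmax(anthro$waist, 0.55)
    markers <- draw_marker_block(spec$biomarker_defs, ea_c, female, delta,
                                 factors, n)

    family <- rbinom(n, 1L, spec$family_disease_rate)
    diseases <- list()
    for (i in seq_len(nrow(spec$disease_defs))) {
      d <- spec$disease_defs[i, ]
      p <- plogis(d$intercept + d$beta_age * (ca - 65) +
                    d$beta_delta * delta + d$beta_family * family)
      diseases[[d$name]] <- rbinom(n, 1L, p)
    }

    tibble::tibble(
      participant_id = seq_len(n),
      chronological_age = ca,
      gender = factor(ifelse(female == 1, "female", "male"),
                      levels = c("male", "female")),
      height = anthro$height,
      weight = anthro$weight,
      waist = anthro$waist,
      bmi = anthro$weight / anthro$height^2,
      !!!markers,
      !!!diseases,
      family_disease = family,
      latent_delta = delta
    )
  })
}

#' Names of the candidate biological-age features
#'
#' The 22 candidate predictors offered to the feature screen: the 13
#' continuous biochemical markers, the 4 binary urine markers, and the 5
#' physical indicators (gender, height, weight, waist, BMI).
#'
#' @param spec optionally, a [cohort_spec()] whose marker names to use.
#' @return character vector of length 22 for the default definitions.
#' @export
ba_feature_names <- function(spec = cohort_spec()) {
  c(spec$biomarker_defs$name, "gender", "height", "weight", "waist", "bmi")
}

#' Names of the seven disease-flag columns
#' @param spec optionally, a [cohort_spec()].
#' @return character vector.
#' @export
disease_names <- function(spec = cohort_spec()) spec$disease_defs$name

#' Step-wise exclusion accounting for an analytic sample
#'
#' Applies the usual epidemiological exclusion cascade — outliers relative
#' to same-age-and-sex peers, records with too much missingness, and
#' participants outside the study age window — and returns the remaining
#' count together with an audit trail of each step.
#'
#' @param initial starting participant count.
#' @param outliers count excluded as same-age/sex outliers.
#' @param high_missing count excluded for excessive per-record missingness.
#' @param age_out count excluded for being outside the age window.
#' @return the final count, with an `audit` attribute: a tibble with one
#'   row per step (`step`, `excluded`, `remaining`).
#' @export
#' @examples
#' exclusion_accounting(418161, 30935, 309416, 666)
exclusion_accounting <- function(initial, outliers, high_missing, age_out) {
  counts <- c(initial, outliers, high_missing, age_out)
  if (any(counts < 0)) abort("counts must be nonnegative.")
  steps <- tibble::tibble(
    step = c("initial", "outliers", "high_missing", "age_out"),
    excluded = c(0, outliers, high_missing, age_out),
    remaining = initial - cumsum(c(0, outliers, high_missing, age_out))
  )
  if (any(steps$remaining < 0)) {
    abort("exclusions exceed the running total.")
  }
  out <- steps$remaining[nrow(steps)]
  attr(out, "audit") <- steps
  out
}
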