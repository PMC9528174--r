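#' Columns eligible for missingness injection
#'
#' The 19 maskable measurement columns: 13 continuous biochemical markers,
#' 4 urine dipstick markers, height and weight. Chronological age, gender,
#' waist, derived BMI, disease flags and family history are never masked.
#'
#' @param spec a [cohort_spec()].
#' @return character vector of column names.
#' @export
maskable_columns <- function(spec = cohort_spec()) {
  c(spec$biomarker_defs$name, "height", "weight")
}

#' Describe a missingness mechanism
#'
#' @param mechanism `"MCAR"` (each cell of the maskable block equally likely
#'   to be removed) or `"MNAR"` (per-variable target rates with removal
#'   probability increasing in the variable's value rank).
#' @param global_rate MCAR only: fraction of the maskable block removed.
#' @param per_variable_rate MNAR only: named numeric vector of per-column
#'   removal fractions; columns not named are left intact.
#' @param value_dependence MNAR only: strength of the upper-tail bias. The
#'   removal weight of a cell is `exp(value_dependence * z)` where `z` is
#'   the standardized within-column value rank; 0 reduces MNAR to
#'   stratified MCAR with per-column counts.
#' @param columns columns the mechanism may touch; defaults to
#'   [maskable_columns()].
#' @return an object of class `missingness_profile`.
#' @export
missingness_profile <- function(mechanism = c("MCAR", "MNAR"),
                                global_rate = 0.05,
                                per_variable_rate = NULL,
                                value_dependence = 1,
                                columns = maskable_columns()) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "MCAR") {
    if (global_rate < 0 || global_rate >= 1) abort("`global_rate` must be in [0, 1).")
  } else {
    if (is.null(per_variable_rate)) per_variable_rate <- default_mnar_rates()
    if (is.null(names(per_variable_rate)) || any(!nzchar(names(per_variable_rate)))) {
      abort("`per_variable_rate` must be a named vector.")
    }
    if (any(per_variable_rate < 0 | per_variable_rate >= 1)) {
      abort("per-variable rates must be in [0, 1).")
    }
    extra <- setdiff(names(per_variable_rate), columns)
    if (length(extra) > 0) {
      abort(paste0("rates given for non-maskable columns: ",
                   paste(extra, collapse = ", ")))
    }
    if (value_dependence < 0) abort("`value_dependence` must be >= 0.")
  }
  structure(
    list(mechanism = mechanism, global_rate = global_rate,
         per_variable_rate = per_variable_rate,
         value_dependence = value_dependence, columns = columns),
    class = "missingness_profile"
  )
}

#' Default per-variable MNAR rates
#'
#' A per-variable profile of the kind observed in routine examination data:
#' lipid-panel and transaminase measurements missing most often, and an
#' overall missing fraction of about 5% of the maskable block.
#'
#' @return named numeric vector over [maskable_columns()].
#' @export
default_mnar_rates <- function() {
  c(sbp = 0.03, dbp = 0.03, hemoglobin = 0.04, white_blood_cell = 0.04,
    platelets = 0.05, fsg = 0.06, sgpt = 0.07, sgot = 0.07,
    serum_bilirubin = 0.05, tc = 0.06, tg = 0.06, ldl = 0.08, hdl = 0.08,
    urine_protein = 0.03, urine_sugar = 0.03, urine_ketone = 0.03,
    urine_occult = 0.03, height = 0.025, weight = 0.025)
}

#' Inject missing values into a complete cohort
#'
#' Removes values from the maskable block under the requested mechanism and
#' records the removal locations. Realized counts are exact:
#' `round_half_up(rate * n)` per column under MNAR, and
#' `round_half_up(global_rate * n_cells)` over the whole block under MCAR.
#' Under MNAR with positive `value_dependence`, cells are drawn without
#' replacement with weight `exp(value_dependence * z_rank)`, so larger
#' values are more likely to go missing.
#'
#' @param data a complete cohort table.
#' @param profile a [missingness_profile()].
#' @param seed integer seed for the removal draw.
#' @return a list of class `ba_missing` with elements `data` (the table
#'   with `NA`s), `mask` (logical matrix, rows x maskable columns, `TRUE`
#'   where a value was removed), and `profile`.
#' @export
inject_missing <- function(data, profile, seed = 1L) {
  stopifnot(inherits(profile, "missingness_profile"))
  cols <- profile$columns
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("columns absent from `data`: ", paste(missing_cols, collapse = ", ")))
  }
  block <- as.matrix(data[cols])
  if (anyNA(block)) abort("the maskable block must be complete before injection.")
  n <- nrow(block)
  mask <- matrix(FALSE, n, length(cols), dimnames = list(NULL, cols))

  with_seed(seed, {
    if (profile$mechanism == "MCAR") {
      n_cells <- length(block)
      k <- round_half_up(profile$global_rate * n_cells)
      if (k > n_cells) abort("requested rate exceeds available cells.")
      if (k > 0) mask[sample.int(n_cells, k)] <- TRUE
    } else {
      for (v in names(profile$per_variable_rate)) {
        k <- round_half_up(profile$per_variable_rate[[v]] * n)
        if (k == 0) next
        if (k > n) abort("requested rate exceeds available cells.")
        r <- rank(block[, v], ties.method = "average")
        z <- as.numeric(scale(r))
        if (all(!is.finite(z))) z <- rep(0, n)  # constant column
        w <- exp(profile$value_dependence * z)
        mask[sample.int(n, k, prob = w), v] <- TRUE
      }
    }
  })

  out <- data
  for (j in seq_along(cols)) {
    out[[cols[j]]][mask[, j]] <- NA
  }
  structure(list(data = tibble::as_tibble(out), mask = mask, profile = profile),
            class = "ba_missing")
}
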