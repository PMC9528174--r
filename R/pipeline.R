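#' Split a cohort into disjoint, exhaustive train/test partitions
#'
#' @param data cohort table.
#' @param train_fraction fraction assigned to training (default 0.80).
#' @param seed seed for the draw.
#' @return list with `train`, `test`, `train_idx`.
#' @export
split_cohort <- function(data, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1).")
  }
  n <- nrow(data)
  idx <- with_seed(seed, sample.int(n, round_half_up(train_fraction * n)))
  list(train = data[idx, ], test = data[-idx, ], train_idx = idx)
}

#' Default end-to-end run configuration
#'
#' The study-scale settings: a 5,000-participant cohort, the MCAR rate
#' grid 5/10/20/30% plus the default per-variable MNAR profile, all five
#' imputers with tenfold replicate masking, the 22-candidate feature
#' screen, the five-family stacked ensemble with a spline meta-model, and
#' the three association batteries under both adjustment models.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; stage seeds are derived from it.
#' @return a named list understood by [run_pipeline()].
#' @export
default_run_config <- function(out_dir = tempfile("bioagestack_run_"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    n_participants = 5000L,
    stages = list(generate = TRUE, impute_bench = TRUE, select = TRUE,
                  train = TRUE, associate = TRUE),
    mcar_rates = c(0.05, 0.10, 0.20, 0.30),
    include_mnar = TRUE,
    impute_methods = c("mean", "knn", "chained_multiple",
                       "round_robin_regression", "autoencoder"),
    benchmark_folds = 10L,
    stacking_folds = 10L,
    train_fraction = 0.8,
    meta_family = "gam"
  )
}

write_stage <- function(tbl, out_dir, file) {
  path <- file.path(out_dir, file)
  write.csv(tbl, path, row.names = FALSE)
  path
}

#' Run the analysis pipeline end to end
#'
#' Executes, in order, the toggled stages: cohort generation, the
#' imputation benchmark, the feature screen, stacked / contrast BA model
#' training, and the association batteries. Each stage writes a CSV
#' artifact into `config$out_dir`; the run finishes by writing a manifest
#' recording each artifact's MD5 digest and the seed that produced it.
#'
#' @param config a list as produced by [default_run_config()], or a path
#'   to a YAML file holding one.
#' @return the manifest tibble, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- default_run_config()
  cfg[names(config)] <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, path, seed) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)), seed = seed
    )
  }
  stage_fail <- function(stage, e) {
    abort(paste0("pipeline stage `", stage, "` failed: ", conditionMessage(e)))
  }

  cohort <- NULL
  if (isTRUE(cfg$stages$generate)) {
    tryCatch({
      spec <- cohort_spec(n_participants = cfg$n_participants, seed = cfg$seed)
      cohort <- generate_cohort(spec)
      note("generate", write_stage(cohort, cfg$out_dir, "cohort_oracle_synthetic.csv"),
           cfg$seed)
      note("generate", write_stage(drop_oracle(cohort), cfg$out_dir, "cohort.csv"),
           cfg$seed)
      yaml::write_yaml(list(seed = cfg$seed, n = cfg$n_participants),
                       file.path(cfg$out_dir, "cohort_meta.yml"))
    }, error = function(e) stage_fail("generate", e))
  }
  if (is.null(cohort) && any(unlist(cfg$stages[-1]))) {
    path <- file.path(cfg$out_dir, "cohort.csv")
    if (!file.exists(path)) abort("pipeline stage `generate` is off and no cohort.csv artifact exists.")
    cohort <- tibble::as_tibble(utils::read.csv(path))
    cohort$gender <- factor(cohort$gender, levels = c("male", "female"))
  }
  analysis <- if (!is.null(cohort)) drop_oracle(cohort) else NULL

  if (isTRUE(cfg$stages$impute_bench)) {
    tryCatch({
      profiles <- lapply(cfg$mcar_rates, function(r)
        missingness_profile("MCAR", global_rate = r))
      if (isTRUE(cfg$include_mnar)) {
        profiles <- c(profiles, list(missingness_profile("MNAR")))
      }
      bench <- run_benchmark(analysis, profiles, cfg$impute_methods,
                             train_fraction = cfg$train_fraction,
                             folds = cfg$benchmark_folds, seed = cfg$seed + 1L)
      note("impute_bench", write_stage(bench, cfg$out_dir, "benchmark.csv"),
           cfg$seed + 1L)
      note("impute_bench",
           write_stage(summarize_benchmark(bench), cfg$out_dir,
                       "benchmark_summary.csv"), cfg$seed + 1L)
    }, error = function(e) stage_fail("impute_bench", e))
  }

  kept <- NULL
  if (isTRUE(cfg$stages$select)) {
    tryCatch({
      report <- select_features(analysis,
                                config = selection_config(seed = cfg$seed + 2L))
      kept <- report$feature[report$kept]
      note("select", write_stage(report, cfg$out_dir, "selection.csv"),
           cfg$seed + 2L)
    }, error = function(e) stage_fail("select", e))
  }

  stk <- moderate <- overfit <- NULL
  if (isTRUE(cfg$stages$train)) {
    tryCatch({
      if (is.null(kept)) kept <- ba_feature_names()
      parts <- split_cohort(analysis, cfg$train_fraction, seed = cfg$seed + 3L)
      stk <- stack_predict(parts$train, parts$test, kept,
                           folds = cfg$stacking_folds,
                           meta_family = cfg$meta_family, seed = cfg$seed + 3L)
      moderate <- fit_boost_contrast(parts$train, parts$test, kept,
                                     mode = "moderate", seed = cfg$seed + 3L)
      overfit <- fit_boost_contrast(parts$train, parts$test, kept,
                                    mode = "overfit", seed = cfg$seed + 3L)
      preds <- dplyr::bind_rows(stk$predictions, moderate$predictions,
                                overfit$predictions)
      metrics <- dplyr::bind_rows(stk$zoo$metrics, stk$metrics,
                                  moderate$metrics, overfit$metrics)
      note("train", write_stage(preds, cfg$out_dir, "ba_predictions.csv"),
           cfg$seed + 3L)
      note("train", write_stage(metrics, cfg$out_dir, "ba_metrics.csv"),
           cfg$seed + 3L)
      note("train",
           write_stage(aggregate_importance(stk$zoo, parts$train),
                       cfg$out_dir, "importance.csv"), cfg$seed + 3L)
      note("train",
           write_stage(dplyr::bind_rows(
             ba_distribution(stk, analysis),
             ba_distribution(moderate, analysis),
             ba_distribution(overfit, analysis)
           ), cfg$out_dir, "ba_distribution.csv"), cfg$seed + 3L)
    }, error = function(e) stage_fail("train", e))
  }

  if (isTRUE(cfg$stages$associate)) {
    tryCatch({
      if (is.null(stk)) abort("associate requires the train stage.")
      fits <- list(STK = stk, boost_moderate = moderate, boost_overfit = overfit)
      assoc <- dplyr::bind_rows(lapply(fits, function(f) {
        dplyr::bind_rows(
          dplyr::mutate(risk_indicator_battery(f, analysis, "absi"), battery = "risk"),
          dplyr::mutate(risk_indicator_battery(f, analysis, "whtr"), battery = "risk"),
          dplyr::mutate(disease_count_battery(f, analysis), battery = "count"),
          dplyr::mutate(per_disease_battery(f, analysis), battery = "disease")
        )
      }))
      note("associate", write_stage(assoc, cfg$out_dir, "associations.csv"),
           cfg$seed + 4L)
    }, error = function(e) stage_fail("associate", e))
  }

  man <- if (length(manifest) > 0) dplyr::bind_rows(manifest) else
    tibble::tibble(stage = character(), file = character(),
                   md5 = character(), seed = integer())
  write.csv(man, file.path(cfg$out_dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

md_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits, format = "g"))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Render a consolidated Markdown report from pipeline artifacts
#'
#' Assembles whichever stage artifacts exist in the run directory into a
#' single Markdown document: imputation benchmark summary, model metric
#' comparison, BA distributions by gender, and association tables.
#'
#' @param out_dir the pipeline run directory (holding `manifest.csv`).
#' @param file output file name within `out_dir`.
#' @return the path to the report, invisibly.
#' @export
render_report <- function(out_dir, file = "report.md") {
  man_path <- file.path(out_dir, "manifest.csv")
  if (!file.exists(man_path)) abort("no manifest.csv in `out_dir`; run the pipeline first.")
  sections <- c("# Biological-age pipeline report", "")
  grab <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p)) tibble::as_tibble(utils::read.csv(p, check.names = FALSE)) else NULL
  }
  bench <- grab("benchmark_summary.csv")
  if (!is.null(bench)) {
    sections <- c(sections, "## Imputation benchmark (fold mean +/- SD)", "",
                  md_table(bench), "")
  }
  sel <- grab("selection.csv")
  if (!is.null(sel)) {
    sections <- c(sections,
                  sprintf("## Feature screen: %d of %d candidates kept",
                          sum(sel$kept), nrow(sel)), "", md_table(sel), "")
  }
  met <- grab("ba_metrics.csv")
  if (!is.null(met)) {
    sections <- c(sections, "## Model metrics by partition", "",
                  md_table(met[c("model_tag", "partition", "rmse", "r2",
                                 "mae", "pearson_r")]), "")
  }
  dist <- grab("ba_distribution.csv")
  if (!is.null(dist)) {
    sections <- c(sections, "## BA distribution by gender", "",
                  md_table(dist), "")
  }
  imp <- grab("importance.csv")
  if (!is.null(imp)) {
    sections <- c(sections, "## Aggregate feature importance", "",
                  md_table(imp[c("feature", "aggregate")]), "")
  }
  assoc <- grab("associations.csv")
  if (!is.null(assoc)) {
    sections <- c(sections, "## Associations with health statuses", "",
                  md_table(assoc), "")
  }
  path <- file.path(out_dir, file)
  writeLines(sections, path)
  invisible(path)
}
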