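#' Configuration of the end-to-end pipeline
#'
#' Collects every stage's parameters with the study defaults: a 30-day
#' look-back window requiring at least 14 days of data, segment maxima as
#' features, a 70/30 walking-aid-stratified split, and a 7-fold
#' cross-validated hyperparameter grid. Exactly one data source must be
#' given: a simulation config, or paths to a sample CSV plus a metadata CSV.
#'
#' @param simulate A [sim_config()] for a synthetic cohort, or `NULL`.
#' @param wat_csv,metadata_csv Input CSV paths when not simulating.
#' @param simulate_test Optional [sim_config()] for a separate
#'   production-like test cohort, never seen during training or model
#'   selection.
#' @param window_days,min_days Profile window parameters.
#' @param null_granularity See [preprocess_cohort()].
#' @param reducer Segment reducer (default `"max"`).
#' @param train_fraction Training share of the stratified split.
#' @param cv_k Cross-validation folds.
#' @param cv_grid Hyperparameter grid; defaults to the full
#'   [default_cv_grid()].
#' @param scoring Cross-validation scoring, `"neg_mse"` or `"neg_mad"`.
#' @param importance_repeats Shuffles per feature for permutation
#'   importance.
#' @param seed Single pipeline seed; per-stage seeds (split,
#'   cross-validation, importance) are derived from it by fixed offsets so
#'   each stage is independently reproducible.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, wat_csv = NULL,
                            metadata_csv = NULL, simulate_test = NULL,
                            window_days = 30, min_days = 14,
                            null_granularity = "hourly", reducer = "max",
                            train_fraction = 0.7, cv_k = 7,
                            cv_grid = default_cv_grid(),
                            scoring = "neg_mse",
                            importance_repeats = 50, seed = 1L) {
  if (is.null(simulate) && (is.null(wat_csv) || is.null(metadata_csv))) {
    stop("either `simulate` or both `wat_csv` and `metadata_csv` are required",
         call. = FALSE)
  }
  structure(
    list(simulate = simulate, wat_csv = wat_csv, metadata_csv = metadata_csv,
         simulate_test = simulate_test, window_days = window_days,
         min_days = min_days, null_granularity = null_granularity,
         reducer = reducer, train_fraction = train_fraction, cv_k = cv_k,
         cv_grid = cv_grid, scoring = scoring,
         importance_repeats = importance_repeats, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields map directly to [pipeline_config()] arguments; a
#' `simulate:` (or `simulate_test:`) block maps to [sim_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_from <- function(block) {
    if (is.null(block)) return(NULL)
    do.call(sim_config, block)
  }
  args <- raw
  args$simulate <- sim_from(raw$simulate)
  args$simulate_test <- sim_from(raw$simulate_test)
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  canonical <- jsonlite::toJSON(
    rapply(unclass(config), unclass, how = "replace"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canonical, tmp)
  unname(tools::md5sum(tmp))
}

prepare_features <- function(series, truth, config, role) {
  prep <- preprocess_cohort(series, truth,
                            window_days = config$window_days,
                            min_days = config$min_days,
                            null_granularity = config$null_granularity)
  features <- build_feature_table(prep$profiles, truth,
                                  reducer = config$reducer, role = role)
  list(prep = prep, features = features)
}

#' Run the whole pipeline and write its artifacts
#'
#' Simulates (or reads) the tracker streams, builds the activity profiles
#' and the modeling table, performs the stratified split, selects
#' hyperparameters by cross-validation, fits the regression tree, scores it
#' on every dataset role, computes permutation importances, and writes all
#' artifacts under `output_dir`: `profiles.csv`, `features.csv`,
#' `model.json`, `report.json`, and a `manifest.json` recording the config
#' hash, the derived per-stage seeds, and the row counts at every stage
#' (including patients excluded by the minimum-days rule). Re-running with
#' the same configuration reproduces the artifacts byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for the artifacts (created if needed).
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the in-memory artifacts: `truth`,
#'   `profiles`, `excluded`, `features`, `split`, `cv`, `model`,
#'   `evaluations`, `importance`, `manifest`.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- list(split = config$seed + 1L, cv = config$seed + 2L,
                importance = config$seed + 3L)

  say("stage 1/6: input (%s)",
      if (is.null(config$simulate)) "reading CSVs" else "simulating cohort")
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
  } else {
    cohort <- list(series = read_wat_csv(config$wat_csv),
                   truth = read_metadata_csv(config$metadata_csv))
  }

  say("stage 2/6: preprocessing %d patients", length(unique(cohort$truth$patient_id)))
  main <- prepare_features(cohort$series, cohort$truth, config,
                           role = "modeling")
  write_profiles_csv(main$prep$profiles, file.path(output_dir, "profiles.csv"))
  write_features_csv(main$features, file.path(output_dir, "features.csv"))

  test_features <- NULL
  if (!is.null(config$simulate_test)) {
    say("stage 2b: preprocessing production-like test cohort")
    test_cohort <- generate_cohort(config$simulate_test)
    test <- prepare_features(test_cohort$series, test_cohort$truth, config,
                             role = "test")
    test_features <- test$features
  }

  say("stage 3/6: stratified split (fraction %.2f)", config$train_fraction)
  split <- stratified_split(main$features,
                            train_fraction = config$train_fraction,
                            seed = seeds$split)

  say("stage 4/6: cross-validating %d candidates over %d folds",
      nrow(config$cv_grid), config$cv_k)
  cv <- cross_validate(split$train, grid = config$cv_grid, k = config$cv_k,
                       scoring = config$scoring, seed = seeds$cv)
  model <- fit_tree(split$train, cv$best)
  write_model_json(model, file.path(output_dir, "model.json"))

  say("stage 5/6: evaluation")
  evaluations <- list(
    train = evaluate_model(model, split$train),
    validation = evaluate_model(model, split$validation)
  )
  if (!is.null(test_features) && nrow(test_features) > 0L) {
    evaluations$test <- evaluate_model(model, test_features)
  }

  say("stage 6/6: permutation importance (%d repeats)",
      config$importance_repeats)
  importance <- lapply(evaluations, function(ev) NULL)
  datasets <- list(train = split$train, validation = split$validation)
  if (!is.null(evaluations$test)) datasets$test <- test_features
  importance <- lapply(datasets, function(d) {
    permutation_importance(model, d, n_repeats = config$importance_repeats,
                           seed = seeds$importance)
  })

  report <- lapply(evaluations, eval_to_list)
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       matrix = "rowmajor", pretty = TRUE)

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    stage_seeds = seeds,
    counts = list(
      patients_input = length(unique(cohort$truth$patient_id)),
      profiles = nrow(main$prep$profiles),
      excluded_min_days = nrow(main$prep$excluded),
      train = nrow(split$train),
      validation = nrow(split$validation),
      test = if (is.null(test_features)) 0L else nrow(test_features)
    )
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    truth = cohort$truth, profiles = main$prep$profiles,
    excluded = main$prep$excluded, features = main$features,
    test_features = test_features, split = split, cv = cv, model = model,
    evaluations = evaluations, importance = importance, manifest = manifest
  ))
}
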