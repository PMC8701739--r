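# End-to-end orchestration: simulate -> preprocess -> infer -> featurize ->
# personalize -> stats -> evaluate, as one reproducible run driven by a
# single config and a single root seed (stage seeds are derived from it).

#' Default run configuration
#'
#' Every rule threshold documented in the package has a key here; see
#' [default_thresholds()] for the preprocessing entries.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    cohort = list(
      n_normal = 7, n_dementia = 6, days = 14, start_date = "2020-07-06"
    ),
    thresholds = default_thresholds(),
    personalization = list(min_history = 24, mode = "augment"),
    evaluation = list(folds = 10, num_trees = 500, importance = FALSE),
    stats = list(alpha = 0.05, adjust = FALSE)
  )
}

#' Read and validate a run configuration
#'
#' Reads a YAML config, fills unset keys from [default_run_config()], and
#' validates the required sections.
#'
#' @param path Path to a YAML file, or a named list.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop_config("config must be a YAML mapping")
  required <- c("cohort")
  for (key in required) {
    if (is.null(cfg[[key]])) stop_config(paste0("config is missing required key: '", key, "'"))
  }
  cfg <- modifyList(default_run_config(), cfg)
  if (is.null(cfg$cohort$n_normal) || is.null(cfg$cohort$n_dementia)) {
    stop_config("config key 'cohort' must set n_normal and n_dementia")
  }
  cfg
}

write_csv_q <- function(x, path) {
  # POSIXct columns rendered as fixed-format strings for byte-stable output
  for (cn in names(x)) {
    if (inherits(x[[cn]], "POSIXct")) x[[cn]] <- format_ts(x[[cn]])
  }
  readr::write_csv(x, path, progress = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes every stage with stage-derived seeds, writing all artifacts as
#' CSV under `out_dir` plus a JSON manifest (config hash, seed, stage file
#' list). Two runs with the same config produce byte-identical CSVs.
#'
#' @param config Config list or YAML path (see [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config = default_run_config(), out_dir, quiet = FALSE) {
  cfg <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "events"), showWarnings = FALSE)
  say <- function(stage, ...) if (!quiet) inform(paste0("[", stage, "] ", ...))

  say("simulate", "cohort of ", cfg$cohort$n_normal, "+", cfg$cohort$n_dementia,
    " persons x ", cfg$cohort$days, " days")
  cc <- cohort_config(
    n_normal = cfg$cohort$n_normal, n_dementia = cfg$cohort$n_dementia,
    days = cfg$cohort$days, start_date = cfg$cohort$start_date
  )
  cohort <- generate_cohort(cc, seed = derive_seed(cfg$seed, 1))
  write_csv_q(
    cohort$profiles[, c("person_id", "group", "mmse", "cdr")],
    file.path(out_dir, "cohort.csv")
  )
  for (pid in names(cohort$events)) {
    write_event_log(cohort$events[[pid]], file.path(out_dir, "events", paste0(pid, ".csv")))
  }

  say("preprocess/infer/featurize", "hourly bins, ADL rules, feature table")
  cf <- cohort_features(cohort, cfg$thresholds)
  write_csv_q(
    bind_rows(lapply(cf$per_person, function(p) p$binned)),
    file.path(out_dir, "binned_1h.csv")
  )
  write_csv_q(
    bind_rows(lapply(cf$per_person, function(p) p$adl$episodes)),
    file.path(out_dir, "adl_episodes.csv")
  )
  write_csv_q(
    bind_rows(lapply(cf$per_person, function(p) p$adl$outings)),
    file.path(out_dir, "outings.csv")
  )
  write_csv_q(cf$features, file.path(out_dir, "features_raw.csv"))

  say("personalize", "IQR anomaly features (mode ", cfg$personalization$mode, ")")
  pers <- personalize_features(
    cf$features, cohort$profiles,
    min_history = cfg$personalization$min_history,
    mode = cfg$personalization$mode
  )
  write_csv_q(pers, file.path(out_dir, "features_personalized.csv"))

  say("stats", "group comparison and appliance correlations")
  daily <- daily_use_counts(cohort, thresholds = cfg$thresholds)
  count_vars <- setdiff(names(daily), c("person_id", "date", "label"))
  stats_tbl <- compare_groups(daily, count_vars,
    alpha = cfg$stats$alpha, adjust = cfg$stats$adjust
  )
  write_csv_q(stats_tbl, file.path(out_dir, "stats_counts.csv"))
  corr <- appliance_correlations(daily, count_vars)
  for (g in names(corr$matrices)) {
    m <- as_tibble(corr$matrices[[g]])
    m <- dplyr::bind_cols(tibble(variable = count_vars), m)
    write_csv_q(m, file.path(out_dir, paste0("correlations_", g, ".csv")))
  }
  write_csv_q(corr$diff, file.path(out_dir, "correlation_diff.csv"))

  say("evaluate", cfg$evaluation$folds, "-fold random forest, 6 cells")
  mat <- run_matrix(
    cf$features, pers, cf$schema,
    folds = cfg$evaluation$folds, seed = derive_seed(cfg$seed, 6),
    num_trees = cfg$evaluation$num_trees,
    importance = isTRUE(cfg$evaluation$importance)
  )
  write_csv_q(mat$summary, file.path(out_dir, "eval_summary.csv"))
  if (!is.null(mat$importance)) {
    write_csv_q(mat$importance, file.path(out_dir, "importance.csv"))
  }

  manifest <- list(
    package = "adlsense",
    version = as.character(utils::packageVersion("adlsense")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    artifacts = sort(setdiff(
      list.files(out_dir, recursive = TRUE),
      "manifest.json"
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  say("done", "artifacts in ", out_dir)
  invisible(list(
    cohort = cohort, features = cf, personalized = pers,
    stats = stats_tbl, correlations = corr, evaluation = mat,
    manifest = manifest
  ))
}
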