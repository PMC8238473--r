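# Operational wiring: the monthly model-selection job, the daily ETL job,
# and a self-contained demonstration run. No scheduler is built in; both
# jobs are plain re-runnable commands for any external scheduler.

#' Build a pipeline configuration
#'
#' Collects every path and tunable of the operational loop under one root
#' directory: source CSVs, warehouse location, report directory, model and
#' curve artifacts, generator sizes, technique list, folds and seed.
#'
#' @param root Root directory for all artifacts.
#' @param cohort_n Training cohort size when no cohort CSV exists yet.
#' @param n_users,n_days Operational source sizes for generation.
#' @param families Candidate technique families.
#' @param folds Cross-validation folds.
#' @param seed Integer seed for every stochastic stage.
#' @param calibration A [cohort_calibration()].
#' @param etl An [etl_config()].
#' @return A list of class `cwb_config`.
#' @export
pipeline_config <- function(root, cohort_n = 2000L, n_users = 10L,
                            n_days = 30L,
                            families = c("J48", "RF", "NB", "KNN", "MLP"),
                            folds = 10L, seed = 1L,
                            calibration = cohort_calibration(),
                            etl = etl_config()) {
  structure(list(
    root = root,
    paths = list(
      cohort = file.path(root, "sources", "cohort.csv"),
      users = file.path(root, "sources", "source1_users.csv"),
      measurements = file.path(root, "sources", "source2_measurements.csv"),
      districts = file.path(root, "sources", "source3_districts.csv"),
      warehouse = file.path(root, "warehouse"),
      reports = file.path(root, "reports"),
      metrics = file.path(root, "model", "metrics.csv"),
      best_name = file.path(root, "model", "best_model.txt"),
      model = file.path(root, "model", "model.rds"),
      curve = file.path(root, "model", "curve.txt"),
      log = file.path(root, "pipeline.log")
    ),
    cohort_n = as.integer(cohort_n), n_users = as.integer(n_users),
    n_days = as.integer(n_days), families = families,
    folds = as.integer(folds), seed = as.integer(seed),
    calibration = calibration, etl = etl
  ), class = "cwb_config")
}

log_line <- function(config, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  dir.create(dirname(config$paths$log), recursive = TRUE,
             showWarnings = FALSE)
  cat(line, "\n", file = config$paths$log, append = TRUE, sep = "")
  message(line)
  invisible(line)
}

#' Generate the pipeline's source files
#'
#' Writes the training cohort and the three operational source CSVs under
#' the configured paths (skipping files that already exist).
#'
#' @param config A [pipeline_config()].
#' @return The config, invisibly.
#' @export
cmd_generate <- function(config) {
  dir.create(dirname(config$paths$cohort), recursive = TRUE,
             showWarnings = FALSE)
  if (!file.exists(config$paths$cohort)) {
    cohort <- generate_cohort(config$cohort_n, seed = config$seed,
                              calibration = config$calibration)
    write_cohort_csv(cohort, config$paths$cohort)
    log_line(config, "generate: cohort n=", config$cohort_n,
             " seed=", config$seed)
  }
  if (!file.exists(config$paths$users)) {
    src <- generate_user_sources(config$n_users, config$n_days,
                                 seed = config$seed + 1L)
    write_table_csv(src$users, config$paths$users)
    write_table_csv(src$measurements, config$paths$measurements)
    write_table_csv(district_fixture(), config$paths$districts)
    log_line(config, "generate: sources users=", config$n_users,
             " days=", config$n_days)
  }
  invisible(config)
}

#' Run the model-selection (DM) job
#'
#' The monthly job: cleanse the training cohort, cross-validate the five
#' techniques under both feature scenarios, rank by composite score, refit
#' the winner on all clean data, persist its name, the metrics table, the
#' serialized model and the fitted index curve.
#'
#' @param config A [pipeline_config()].
#' @param metrics Optional pre-computed metrics data.frame (`algorithm`,
#'   `sensitivity`, `accuracy`): training is bypassed and only ranking and
#'   name persistence run.
#' @return The `cwb_selection`, invisibly.
#' @export
cmd_dm_job <- function(config, metrics = NULL) {
  dir.create(dirname(config$paths$best_name), recursive = TRUE,
             showWarnings = FALSE)
  if (is.null(metrics)) {
    cmd_generate(config)
    raw <- read_cohort_csv(config$paths$cohort)
    res <- cleanse(raw)
    log_line(config, "dm-job: cleansed ", res$report$kept_n, "/",
             res$report$input_n, " records")
    sel <- select_best(res$clean, families = config$families,
                       seed = config$seed, k = config$folds,
                       name_file = config$paths$best_name)
    saveRDS(sel$model, config$paths$model)
  } else {
    sel <- select_best(metrics = metrics,
                       name_file = config$paths$best_name)
  }
  write_table_csv(sel$ranking, config$paths$metrics)
  curve <- fit_index_curve()
  write_index_curve(curve, config$paths$curve)
  log_line(config, "dm-job: best=", sel$best_name,
           " seed=", config$seed)
  invisible(sel)
}

#' Run the incremental ETL job
#'
#' The daily job: one incremental ETL pass over the configured sources
#' using the persisted best model and index curve. Fails with an
#' instructive error when the model-selection job has not run yet.
#'
#' @param config A [pipeline_config()].
#' @param at Upper date bound of the pass (default: today).
#' @return The `cwb_etl_report`, invisibly.
#' @export
cmd_etl_job <- function(config, at = Sys.Date()) {
  if (!file.exists(config$paths$model))
    stop("no trained model at ", config$paths$model,
         "; run cmd_dm_job() first")
  model <- readRDS(config$paths$model)
  curve <- read_index_curve(config$paths$curve)
  cmd_generate(config)
  sources <- list(
    users = read_table_csv(config$paths$users),
    measurements = read_table_csv(config$paths$measurements),
    districts = read_table_csv(config$paths$districts,
                               colClasses = "character")
  )
  wh <- if (file.exists(file.path(config$paths$warehouse, "fact.csv")))
    open_warehouse(config$paths$warehouse)
  else init_warehouse(config$paths$warehouse)
  report <- run_etl(wh, sources, model, curve, at = at, config = config$etl)
  log_line(config, "etl-job: facts=", report$facts_loaded,
           " quarantined=", report$quarantined)
  invisible(report)
}

#' End-to-end demonstration in a temporary directory
#'
#' Generates a small cohort and operational sources, selects a model with a
#' reduced technique list (decision tree and naive Bayes, 3 folds, for
#' speed), loads the warehouse, exports the reports, and prints one user's
#' current weighted index with its colour. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param root Working directory (default: a fresh temporary directory).
#' @param quiet Suppress progress logging (default TRUE).
#' @return Invisibly, a list with the config, the ETL report, the report
#'   file paths and the printed user summary.
#' @export
cmd_demo <- function(seed = 1L, root = tempfile("cardiowell_demo_"),
                     quiet = TRUE) {
  config <- pipeline_config(root, cohort_n = 400L, n_users = 6L,
                            n_days = 15L, families = c("J48", "NB"),
                            folds = 3L, seed = seed)
  run <- function(expr) if (quiet) suppressMessages(expr) else expr
  run(cmd_dm_job(config))
  report <- run(cmd_etl_job(config, at = as.Date("2019-12-31")))
  wh <- open_warehouse(config$paths$warehouse)
  paths <- export_report(wh, config$paths$reports)
  fact <- wh_read(wh, "fact")
  uid <- fact$id_user[1]
  h <- fact[fact$id_user == uid, c("index_date", "index_value")]
  names(h) <- c("date", "index_value")
  w <- weighted_index(h, max(as.Date(h$date)))
  cat(sprintf("user %d current weighted index: %.2f (%s)\n",
              uid, w, colour_of(w)))
  g <- global_index(wh)
  cat(sprintf("global index: %.2f (%s)\n", g, colour_of(g)))
  invisible(list(config = config, etl = report, reports = paths,
                 user = list(id = uid, weighted_index = w,
                             colour = as.character(colour_of(w))),
                 global = g))
}
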