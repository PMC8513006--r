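#' Pipeline configuration
#'
#' Flat configuration for the end-to-end pipeline: simulate (or read) the
#' accelerometer dataset, align and trim, extract window features, run
#' nested cross-validation and write reports.
#'
#' @param input_dir Directory holding `recording_*.csv` /
#'   `annotations_*.csv` files, or `NULL` to simulate the dataset.
#' @param sim A [sim_config()] used when simulating.
#' @param trim_front,trim_back Seconds trimmed from each bout (defaults 20
#'   and 5).
#' @param window_lengths Integer window lengths in seconds (each in 2..16).
#' @param tasks Character subset of `c("binary", "multiclass")`.
#' @param families Classifier families, or `"all"`.
#' @param seed Seed for the nested plan (and the simulator, unless `sim`
#'   carries its own).
#' @param out_dir Output directory for reports.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            sim = sim_config(seed = seed),
                            trim_front = 20, trim_back = 5,
                            window_lengths = 5,
                            tasks = "binary",
                            families = "all",
                            seed = 1,
                            out_dir = tempfile("wristft_out")) {
  if (identical(families, "all")) families <- .families()
  cfg <- list(input_dir = input_dir, sim = sim,
              trim_front = trim_front, trim_back = trim_back,
              window_lengths = as.integer(window_lengths),
              tasks = tasks, families = families,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!all(cfg$window_lengths %in% 2:16)) {
    stop("configuration error: window lengths must lie in 2..16 s",
         call. = FALSE)
  }
  if (!all(cfg$tasks %in% c("binary", "multiclass"))) {
    stop("configuration error: tasks must be 'binary' and/or 'multiclass'",
         call. = FALSE)
  }
  if (!all(cfg$families %in% .families())) {
    stop("configuration error: unknown classifier family",
         call. = FALSE)
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    stop("configuration error: seed must be set", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the arguments of [pipeline_config()]; keys under `sim:`
#' are passed to [sim_config()]. Missing keys take the defaults.
#'
#' @param path Path to the YAML file.
#' @param ... Overrides applied after reading (CLI flags beat the file).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  sim_args <- raw$sim
  raw$sim <- NULL
  if (!is.null(raw$seed) && is.null(sim_args$seed)) {
    sim_args$seed <- raw$seed
  }
  args <- raw[names(raw) %in% names(formals(pipeline_config))]
  args$sim <- do.call(sim_config, as.list(sim_args))
  do.call(pipeline_config, args)
}

.log_stage <- function(...) message("[wristft] ", ...)

#' Simulate and write the dataset (pipeline `simulate` subcommand)
#'
#' Writes one recording CSV and one annotation CSV per participant plus a
#' manifest with the seed, under `<out_dir>/data`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the data directory.
#' @export
cmd_simulate <- function(config) {
  validate_pipeline_config(config)
  data_dir <- file.path(config$out_dir, "data")
  .log_stage("simulating ", config$sim$n_participants,
             " participants (seed ", config$sim$seed, ")")
  sim <- simulate_dataset(config$sim)
  write_dataset(sim, data_dir, cfg = config$sim)
  .log_stage("wrote ", length(sim$recordings), " recordings and ",
             length(sim$logs), " annotation logs to ", data_dir)
  invisible(data_dir)
}

#' Load a dataset directory into labeled, trimmed segments
#'
#' Reads every `recording_<id>.csv` with its `annotations_<id>.csv`
#' companion and applies [align_and_trim()].
#'
#' @param dir Data directory.
#' @param trim_front,trim_back Trim seconds.
#' @param expected_rate Expected sampling rate, checked on read.
#' @return List of `labeled_segment`s over all participants.
#' @export
load_segments <- function(dir, trim_front = 20, trim_back = 5,
                          expected_rate = NULL) {
  rec_files <- sort(list.files(dir, "^recording_.*\\.csv$",
                               full.names = TRUE))
  if (length(rec_files) == 0) {
    stop("ingest error: no recording_*.csv files in ", dir, call. = FALSE)
  }
  segs <- list()
  for (rf in rec_files) {
    pid <- sub("^recording_(.*)\\.csv$", "\\1", basename(rf))
    af <- file.path(dir, paste0("annotations_", pid, ".csv"))
    if (!file.exists(af)) {
      stop("ingest error: missing annotation file ", af, call. = FALSE)
    }
    rec <- read_recording(rf, participant_id = pid,
                          expected_rate = expected_rate)
    logs <- read_annotations(af)
    if (!pid %in% names(logs)) {
      stop("ingest error: ", af, " has no entries for participant ", pid,
           call. = FALSE)
    }
    segs <- c(segs, align_and_trim(rec, logs[[pid]], trim_front, trim_back))
  }
  segs
}

#' Run the end-to-end pipeline (pipeline `run` subcommand)
#'
#' Simulates (or reads) the dataset, trims and labels it, extracts window
#' features, runs nested cross-validation for every requested window
#' length, task and classifier family, and writes one JSON report per
#' combination plus the resolved configuration, under `config$out_dir`.
#' Stage counts are logged to stderr.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a nested list of `nested_cv_report`s indexed by
#'   `"w<length>_<task>_<family>"`.
#' @export
cmd_run <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  data_dir <- config$input_dir
  if (is.null(data_dir)) data_dir <- cmd_simulate(config)
  segs <- load_segments(data_dir, config$trim_front, config$trim_back,
                        expected_rate = config$sim$sampling_rate)
  n_sec <- sum(vapply(segs, function(s) nrow(s$samples), 0)) /
    segs[[1]]$sampling_rate
  .log_stage("ingested ", length(segs), " labeled segments (",
             round(n_sec), " s retained after trimming)")

  reports <- list()
  for (w in config$window_lengths) {
    feats <- extract_features(segs, w)
    plan <- make_nested_plan(unique(feats$participant_id), config$seed)
    .log_stage(w, " s windows: ", nrow(feats), " windows, ",
               length(plan$folds), " outer folds")
    for (task in config$tasks) {
      for (fam in config$families) {
        rep <- run_nested_cv(feats, task, fam, plan)
        key <- sprintf("w%d_%s_%s", w, task, fam)
        reports[[key]] <- rep
        path <- file.path(config$out_dir, paste0(key, ".json"))
        write_report_json(rep, path)
        .log_stage(key, ": ",
                   paste(rep$summary$metric, "=",
                         format_mean_sd(rep$summary$mean, rep$summary$sd),
                         collapse = ", "))
      }
    }
  }
  resolved <- config
  resolved$sim$activity_params <- NULL   # keep the provenance file flat
  yaml::write_yaml(unclass(lapply(unclass(resolved), function(x)
    if (inherits(x, "sim_config")) unclass(x) else x)),
    file.path(config$out_dir, "resolved_config.yaml"))
  invisible(reports)
}

#' Write a nested-CV report to JSON
#'
#' Per-fold metrics and chosen hyperparameters, a mean/SD summary (with a
#' `"mean (SD)"` string formatted to 2 decimals), the pooled row-normalized
#' confusion matrix, per-fold ROC points (binary task) and the top-15
#' scaled feature importances (forest runs).
#'
#' @param report A `nested_cv_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  summ <- report$summary
  summ$formatted <- format_mean_sd(summ$mean, summ$sd)
  out <- list(
    task = report$task,
    family = report$family,
    summary = summ,
    folds = lapply(report$folds, function(f) {
      list(fold = f$fold, test_participant = f$test_participant,
           params = f$params, metrics = f$metrics, n_test = f$n_test)
    }),
    pooled_confusion_pct = as.data.frame(report$pooled_confusion),
    roc = if (!is.null(report$roc))
      lapply(report$roc, function(r) list(fpr = r$fpr, tpr = r$tpr)),
    top_importances = if (!is.null(report$importances))
      attr(forest_importances(report), "top")
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
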