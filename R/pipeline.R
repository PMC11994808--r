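#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline; printed study constants
#' (2500 training samples over 3 days, 72-h response window, 6-h sliding
#' window at 50% of steps above 0.10, more than 1 h persistence, 1000
#' bootstraps, 100 windows per control) are defaults here, never hard-coded
#' in the logic.
#'
#' @param ... Overrides for any config entry (see defaults in the source).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    twin = list(m = 250L, min_samples = 2500L, min_days = 3L),
    mcir = list(q = 0.95, block_minutes = 15L, min_valid_minutes = 3L),
    response = list(window_h = 72, slide_window_h = 6, frac = 0.5,
                    threshold = 0.10, persistence_blocks = 5L),
    stats = list(n_boot = 1000L, windows_per_control = 100L, seed = 1L))
  over <- list(...)
  for (grp in names(over)) {
    if (!grp %in% names(cfg))
      mcir_abort(sprintf("unknown config group '%s'", grp), "validation_error")
    for (key in names(over[[grp]])) {
      if (!key %in% names(cfg[[grp]]))
        mcir_abort(sprintf("unknown config key '%s$%s'", grp, key),
                   "validation_error")
      cfg[[grp]][[key]] <- over[[grp]][[key]]
    }
  }
  with(cfg$response, {
    if (frac <= 0 || frac > 1)
      mcir_abort("response$frac must be in (0, 1]", "validation_error")
    if (window_h < slide_window_h)
      mcir_abort("response$window_h must be >= slide_window_h",
                 "validation_error")
    if (threshold <= 0 || persistence_blocks <= 0)
      mcir_abort("response thresholds must be positive", "validation_error")
  })
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys are config groups.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Score one dose end to end
#'
#' Runs the full per-dose pipeline on one individual's biosignal series:
#' twin-filter the pre-dose data, train the digital twin, score pre-dose
#' residuals and calibrate the null, score post-dose residuals, compute the
#' MCIR and the per-dose response summary.  Sample counts at every filter
#' stage are logged for audit.
#'
#' @param series A `biosignal_series` covering the pre-dose baseline and the
#'   post-dose window.
#' @param dose_time Dose timestamp.
#' @param config A [pipeline_config()].
#' @param dose_number Metadata carried into the summary.
#' @return List: `mcir` (`mcir_series` over the whole span), `summary`
#'   (`response_summary`), `twin` (`twin_model`), `calibration`, `counts`
#'   (records at each stage).
#' @export
score_dose <- function(series, dose_time, config = pipeline_config(),
                       dose_number = NA_integer_) {
  dose_time <- as_utc(dose_time)
  pre <- series[series$time < dose_time, , drop = FALSE]
  twin <- train_twin(pre, m = config$twin$m,
                     min_samples = config$twin$min_samples,
                     min_days = config$twin$min_days)
  scor <- filter_for_twin(series, "scoring")
  res <- estimate_and_residual(twin, scor)
  blocks <- block_residuals(res, dose_time,
                            block_minutes = config$mcir$block_minutes,
                            min_valid_minutes = config$mcir$min_valid_minutes)
  base_blocks <- blocks[blocks$block_start < dose_time, , drop = FALSE]
  calib <- calibrate_null(base_blocks, q = config$mcir$q)
  mc <- compute_mcir(blocks, calib)
  summ <- response_summary(mc, dose_time,
                           participant_id = attr(series, "participant_id"),
                           dose_number = dose_number,
                           window_h = config$response$window_h,
                           slide_window_h = config$response$slide_window_h,
                           frac = config$response$frac,
                           threshold = config$response$threshold,
                           persistence_blocks = config$response$persistence_blocks)
  counts <- list(records_in = nrow(series),
                 pre_dose = nrow(pre),
                 training_filtered = twin$n_training,
                 scoring_filtered = nrow(scor),
                 blocks_total = nrow(blocks),
                 baseline_blocks = nrow(base_blocks))
  list(mcir = mc, summary = summ, twin = twin, calibration = calib,
       counts = counts)
}

#' Write a biosignal series as CSV
#'
#' Header `timestamp,hr,hrv,rr,activity,skin_temp,sqi`, ISO-8601 UTC
#' timestamps.
#'
#' @param series A `biosignal_series`.
#' @param path Output file path.
#' @export
write_biosignal_csv <- function(series, path) {
  out <- data.frame(timestamp = format(series$time, "%Y-%m-%dT%H:%M:%SZ",
                                       tz = "UTC"),
                    hr = series$hr, hrv = series$hrv, rr = series$rr,
                    activity = series$activity,
                    skin_temp = series$skin_temp, sqi = series$sqi)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read a biosignal series from CSV
#'
#' @param path CSV path in the [write_biosignal_csv()] dialect.
#' @param participant_id Identifier attached to the series.
#' @return A `biosignal_series`.
#' @export
read_biosignal_csv <- function(path, participant_id = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_biosignal_series(
    data.frame(time = as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC"),
               hr = as.numeric(df$hr), hrv = as.numeric(df$hrv),
               rr = as.numeric(df$rr), activity = as.numeric(df$activity),
               skin_temp = as.numeric(df$skin_temp),
               sqi = as.numeric(df$sqi)),
    participant_id)
}

#' Simulate a cohort and write it to disk
#'
#' One CSV per individual, a ground-truth JSON, a dose-event CSV and a
#' manifest recording the seeds.
#'
#' @param out_dir Output directory (created if needed).
#' @param n Cohort size.
#' @param seed Master seed.
#' @param config A [pipeline_config()] (recorded in the manifest).
#' @param ... Passed to [simulate_cohort()].
#' @return Invisibly, the manifest list.
#' @export
cmd_simulate <- function(out_dir, n, seed = 1L, config = pipeline_config(),
                         ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  coh <- simulate_cohort(n, seed = seed, ...)
  files <- character(n)
  for (i in seq_len(n)) {
    id <- attr(coh$series[[i]], "participant_id")
    files[i] <- file.path(out_dir, paste0(id, ".csv"))
    write_biosignal_csv(coh$series[[i]], files[i])
  }
  truth <- coh$truth
  truth$dose_time <- format(truth$dose_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  doses <- coh$doses
  doses$dose_time <- format(doses$dose_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(doses, file.path(out_dir, "doses.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(n = n, seed = seed, files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Score dose responses for series files on disk
#'
#' @param series_paths Character vector of biosignal CSV paths.
#' @param doses_path Dose-event CSV
#'   (`participant_id,dose_time,dose_number,vaccine_label`).
#' @param out_dir Output directory for per-dose MCIR CSVs and the summary
#'   table.
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary data frame (also written as
#'   `response_summaries.csv`).
#' @export
cmd_score <- function(series_paths, doses_path, out_dir,
                      config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  doses <- utils::read.csv(doses_path, stringsAsFactors = FALSE)
  rows <- list()
  for (p in series_paths) {
    id <- sub("[.]csv$", "", basename(p))
    s <- read_biosignal_csv(p, id)
    drow <- doses[doses$participant_id == id, , drop = FALSE]
    for (j in seq_len(nrow(drow))) {
      dt <- as.POSIXct(drow$dose_time[j], format = "%Y-%m-%dT%H:%M:%SZ",
                       tz = "UTC")
      sc <- score_dose(s, dt, config, dose_number = drow$dose_number[j])
      write_mcir_csv(sc$mcir,
                     file.path(out_dir,
                               sprintf("%s_dose%d_mcir.csv", id,
                                       drow$dose_number[j])))
      su <- sc$summary
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = id, dose_number = drow$dose_number[j],
        auc_total = su$auc_total, detectable = su$detectable,
        onset = if (is.null(su$onset)) "" else
          format(su$onset, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        offset = if (is.null(su$offset)) "" else
          format(su$offset, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        n_blocks_valid = su$n_blocks_valid)
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out_dir, "response_summaries.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Bootstrap validation of the detectable-response rule on a scored cohort
#'
#' @param study_decisions Logical decisions for the vaccinated doses.
#' @param control_mcir List of control `mcir_series`.
#' @param out_path Output JSON path.
#' @param config A [pipeline_config()].
#' @return Invisibly, the `performance_estimate`.
#' @export
cmd_validate <- function(study_decisions, control_mcir, out_path,
                         config = pipeline_config()) {
  if (length(control_mcir) == 0)
    mcir_abort("no control series supplied", "validation_error")
  pe <- bootstrap_performance(
    study_decisions, control_mcir,
    windows_per_control = config$stats$windows_per_control,
    n_boot = config$stats$n_boot, seed = config$stats$seed,
    window_h = config$response$window_h,
    slide_window_h = config$response$slide_window_h,
    frac = config$response$frac, threshold = config$response$threshold,
    persistence_blocks = config$response$persistence_blocks)
  jsonlite::write_json(
    list(tpr = pe$tpr, spc = pe$spc, fpr = pe$fpr, ppv = pe$ppv,
         npv = pe$npv, acc = pe$acc, ci95 = pe$ci95, n_boot = pe$n_boot,
         control_window_rate = pe$control_window_rate),
    out_path, auto_unbox = TRUE, digits = NA)
  invisible(pe)
}
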