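#' Write detected turns to CSV
#'
#' Columns: `sequence_id,turn_index,t_start_s,t_end_s,direction`
#' (comma separator, decimal point, header required).
#'
#' @param turns a `ski_turns` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_turns_csv <- function(turns, path) {
  d <- data.frame(sequence_id = turns$sequence_id,
                  turn_index = turns$turn_index,
                  t_start_s = turns$t_start, t_end_s = turns$t_end,
                  direction = turns$direction)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detected-turns CSV
#'
#' @param path CSV with header
#'   `sequence_id,turn_index,t_start_s,t_end_s,direction` (an optional
#'   `run_id` column is preserved for evaluation).
#' @return A `ski_turns` data.frame.
#' @export
read_turns_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "turn_index", "t_start_s", "t_end_s", "direction")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop_input("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  out <- data.frame(sequence_id = d$sequence_id, turn_index = d$turn_index,
                    t_start = d$t_start_s, t_end = d$t_end_s,
                    direction = d$direction, stringsAsFactors = FALSE)
  if (!is.null(d$run_id)) out$run_id <- d$run_id
  class(out) <- c("ski_turns", "data.frame")
  out
}

#' Read a reference-turns CSV
#'
#' @param path CSV with header `run_id,switch_time_s,direction`.
#' @return data.frame of reference turns.
#' @export
read_reference_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "switch_time_s", "direction")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop_input("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  d
}

#' Detect turns from two boot CSV files
#'
#' Reads the two streams, runs [detect_turns()], writes the turns CSV and a
#' JSON summary (per-sequence turn counts and mean durations), and logs the
#' sequence count to standard error.
#'
#' @param left_csv,right_csv per-boot CSVs
#'   (header `time_s,gyro_x,gyro_y,gyro_z`).
#' @param out_path output turns CSV; the summary JSON goes next to it with
#'   suffix `_summary.json` unless `summary_path` is given.
#' @param config_path optional YAML configuration.
#' @param summary_path optional explicit JSON path.
#' @return Invisibly, the detected `ski_turns`.
#' @export
cmd_detect <- function(left_csv, right_csv, out_path, config_path = NULL,
                       summary_path = NULL) {
  cfg <- load_config(config_path)
  left <- read_gyro_csv(left_csv, side = "left", units = cfg$sampling$units)
  right <- read_gyro_csv(right_csv, side = "right", units = cfg$sampling$units)
  # unit conversion already applied on read; the pipeline works in rad/s
  cfg$sampling$units <- "rad/s"
  turns <- detect_turns(left, right, cfg)
  write_turns_csv(turns, out_path)
  smry <- sequence_summary(turns)
  if (is.null(summary_path)) {
    summary_path <- sub("\\.csv$", "", out_path)
    summary_path <- paste0(summary_path, "_summary.json")
  }
  jsonlite::write_json(
    list(n_turns = nrow(turns), n_sequences = nrow(smry), sequences = smry),
    summary_path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  message(sprintf("detected %d turn(s) in %d sequence(s); wrote %s and %s",
                  nrow(turns), nrow(smry), out_path, summary_path))
  invisible(turns)
}

#' Evaluate a turns CSV against a reference CSV
#'
#' Writes a JSON report with per-run and pooled counts and metrics, field
#' names `AT`, `TP`, `FP`, `FN`, `Ratio`, `Precision`, `Recall`.
#'
#' @param turns_csv detected turns (see [write_turns_csv()]).
#' @param reference_csv reference turns (`run_id,switch_time_s,direction`).
#' @param out_path report JSON path.
#' @param config_path optional YAML configuration (matching mode, tolerance
#'   fallback).
#' @return Invisibly, the report list from [evaluate_runs()].
#' @export
cmd_evaluate <- function(turns_csv, reference_csv, out_path, config_path = NULL) {
  cfg <- load_config(config_path)
  det <- read_turns_csv(turns_csv)
  ref <- read_reference_csv(reference_csv)
  if (nrow(ref) == 0L) {
    warning("empty reference; all metrics undefined (NaN)")
  }
  rep <- if (nrow(ref) == 0L) {
    cc <- confusion_counts(0L, nrow(det), 0L)
    list(per_run = metrics_row("run1", cc), pooled = metrics_row("pooled", cc))
  } else {
    evaluate_runs(det, ref, mode = cfg$evaluation$matching,
                  default_turn_duration = cfg$evaluation$default_turn_duration)
  }
  jsonlite::write_json(rep, out_path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  message(sprintf("evaluated %d detected vs %d reference turn(s); wrote %s",
                  nrow(det), nrow(ref), out_path))
  invisible(rep)
}

#' Generate simulated fixture files
#'
#' Writes `left.csv`, `right.csv`, `truth.csv` and an echo of the effective
#' configuration (`config.yaml`) into `out_dir`. Byte-identical for a fixed
#' seed.
#'
#' @param out_dir output directory (created if missing).
#' @param config_path optional YAML configuration (its `simulator:` section
#'   is used).
#' @param seed optional seed override.
#' @return Invisibly, the `ski_sim` object.
#' @export
cmd_simulate <- function(out_dir, config_path = NULL, seed = NULL) {
  cfg <- load_config(config_path)
  sc <- as_sim_config(cfg$simulator)
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  run <- simulate_run(sc)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_gyro_csv(run$left, file.path(out_dir, "left.csv"))
  write_gyro_csv(run$right, file.path(out_dir, "right.csv"))
  write.csv(run$truth, file.path(out_dir, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  cfg$simulator <- unclass(sc)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  message(sprintf("simulated %d true turn(s) (seed %d); wrote 4 files to %s",
                  nrow(run$truth), sc$seed, out_dir))
  invisible(run)
}

#' Train elimination thresholds from a feature CSV
#'
#' @param features_csv CSV with header `delta_omega,dt,eliminated`.
#' @param out_path JSON output with `theta1`, `theta2`, `cv_accuracy`.
#' @param fold_count,seed see [train_elimination_thresholds()].
#' @return Invisibly, the `elimination_thresholds` object.
#' @export
cmd_train_thresholds <- function(features_csv, out_path, fold_count = 5, seed = 1) {
  if (!file.exists(features_csv)) stop_input("file not found: ", features_csv)
  d <- read.csv(features_csv, stringsAsFactors = FALSE)
  fit <- train_elimination_thresholds(d, fold_count = fold_count, seed = seed)
  jsonlite::write_json(unclass(fit), out_path, auto_unbox = TRUE, digits = NA)
  message(sprintf("theta1 = %.4g rad/s, theta2 = %.4g s (CV accuracy %.3f); wrote %s",
                  fit$theta1, fit$theta2, fit$cv_accuracy, out_path))
  invisible(fit)
}

# plain list (e.g. from YAML) -> sim_config
as_sim_config <- function(x) {
  if (inherits(x, "sim_config")) return(x)
  segs <- lapply(x$segments, function(s) do.call(sim_segment, s))
  sim_config(seed = x$seed, fs = x$fs, segments = segs,
             noise_sd = x$noise_sd,
             saddle_probability = x$saddle_probability,
             saddle_amplitude = x$saddle_amplitude,
             saddle_period = x$saddle_period,
             stop_oscillation_amplitude = x$stop_oscillation_amplitude,
             leg_asymmetry = x$leg_asymmetry,
             inter_segment_gap = x$inter_segment_gap)
}
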