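#' Read a trajectory CSV
#'
#' Expects columns `frame`, `time_s`, `x_mm`, `y_mm`, `heading_deg` (an
#' optional `valid` column restricts rows to valid frames). Time must be
#' strictly increasing; the first offending row is named otherwise.
#'
#' @param path CSV file path.
#' @return A [trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "x_mm", "y_mm", "heading_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop(sprintf("time_s not strictly increasing at row %d", bad[1] + 1))
  trajectory(df$time_s, df$x_mm, df$y_mm, df$heading_deg)
}

#' Write a trajectory CSV
#'
#' @param traj A [trajectory()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "fly_trajectory"))
  df <- data.frame(frame = seq_len(nrow(traj)), time_s = traj$time,
                   x_mm = traj$x, y_mm = traj$y, heading_deg = traj$heading,
                   valid = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read/write trial-record tables
#'
#' Trial tables are plain CSV with the trial-record columns (`fly_id`,
#' `group`, `trial_index`, `assay`, stimulation window, kinematic summaries,
#' `jump`, `reach`, `labeling`).
#'
#' @param path CSV path.
#' @return A data.frame of trials.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fly_id", "group", "trial_index")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_trials_csv
#' @param trials Trial data.frame.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Write a frame stack as a multi-frame TIFF
#'
#' Intensities are scaled by `max_intensity` into the unit range the TIFF
#' writer expects; the scale is restored by [read_movie_tiff()].
#'
#' @param frames 3D array `[rows, cols, frames]` or list of matrices.
#' @param path Output `.tif` path.
#' @param max_intensity Full-scale intensity (default the stack maximum).
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(frames, path, max_intensity = NULL) {
  if (is.list(frames)) frames <- simplify2array(frames)
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (is.null(max_intensity)) max_intensity <- max(frames, 1e-12)
  lst <- lapply(seq_len(dim(frames)[3]), function(k)
    pmin(pmax(frames[, , k] / max_intensity, 0), 1))
  tiff::writeTIFF(lst, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-frame TIFF as a frame stack
#'
#' @param path `.tif` path.
#' @param max_intensity Full-scale intensity used when writing (default 1).
#' @return 3D array `[rows, cols, frames]`.
#' @export
read_movie_tiff <- function(path, max_intensity = 1) {
  lst <- tiff::readTIFF(path, all = TRUE)
  simplify2array(lst) * max_intensity
}

#' Read/write stimulus epochs as JSON
#'
#' @param epochs Epochs data.frame (`stimulus_id`, `start`, `stop`, optional
#'   `expansion_stop`).
#' @param path JSON path.
#' @return The epochs data.frame (reader) or `path` invisibly (writer).
#' @export
write_epochs_json <- function(epochs, path) {
  jsonlite::write_json(epochs, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_epochs_json
#' @export
read_epochs_json <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected so typos in parameter names (e.g. percentile
#' values) fail loudly instead of being silently ignored. Missing keys fall
#' back to defaults matching the assay conventions baked into the package
#' (50 Hz arena tracking, 1 s stimulation scored over the full second,
#' 97.7/2.3 percentile thresholds, Savitzky-Golay window 7 order 2, calcium
#' baseline window 300 frames at the 10th percentile with 98th-percentile
#' per-fly normalization).
#'
#' @param path `.yaml`/`.yml`/`.json` file.
#' @return A named list of class `run_config` with all defaults resolved.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  defaults <- list(
    frame_rate = 50, stim_onset = 1, stim_duration = 1,
    scoring_window = 1, jump_window = 0.5,
    percentile_upper = 97.7, percentile_lower = 2.3,
    sg_window = 7, sg_order = 2, smooth_window = 5,
    baseline_window = 300, baseline_percentile = 10,
    normalization_percentile = 98, response_half_width = 2,
    n_flies = 10, trials_per_fly = 5, control_flies = 20,
    response_kind = "backward", response_magnitude = 10,
    response_probability = 0.5, seed = 1)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  class(out) <- "run_config"
  out
}

#' Run the simulate-track-score behavioral pipeline
#'
#' Executes the configured stages end to end: simulate a control cohort and
#' an activated cohort, derive control-percentile thresholds, classify the
#' activated trials and report penetrance for each behavior. All randomness
#' derives from the config seed, so re-running a config reproduces the
#' result tables exactly.
#'
#' @param config A `run_config` (see [read_run_config()]) or a named list of
#'   overrides to the defaults.
#' @param out_dir Optional directory; when given, trial tables, thresholds
#'   (JSON, with provenance) and penetrance tables are written there.
#' @return A list: `thresholds`, `control_trials`, `activated_trials`
#'   (classified), `penetrance` (one row per behavior), `config`.
#' @export
run_behavior_pipeline <- function(config = list(), out_dir = NULL) {
  if (!inherits(config, "run_config")) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp), add = TRUE)
    yaml::write_yaml(config, tmp)
    config <- read_run_config(tmp)
  }
  ctrl <- simulate_arena_trials(behavior_sim_params(
    n_flies = config$control_flies, trials_per_fly = config$trials_per_fly,
    frame_rate = config$frame_rate, stim_onset = config$stim_onset,
    stim_duration = config$stim_duration, response_kind = "none",
    group = "control", seed = config$seed))
  act <- simulate_arena_trials(behavior_sim_params(
    n_flies = config$n_flies, trials_per_fly = config$trials_per_fly,
    frame_rate = config$frame_rate, stim_onset = config$stim_onset,
    stim_duration = config$stim_duration,
    response_kind = config$response_kind,
    response_magnitude = config$response_magnitude,
    response_probability = config$response_probability,
    group = "activated", seed = config$seed + 1))
  th <- compute_thresholds(ctrl$trials,
                           percentile_upper = config$percentile_upper,
                           percentile_lower = config$percentile_lower)
  scored <- classify_trials(act$trials, th)
  pen <- do.call(rbind, lapply(c("forward", "backward", "turn", "jump"),
                               function(b) penetrance(scored, b)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials_csv(ctrl$trials, file.path(out_dir, "control_trials.csv"))
    write_trials_csv(scored, file.path(out_dir, "activated_trials.csv"))
    utils::write.csv(pen, file.path(out_dir, "penetrance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(unclass(th), list(control_group = "control", seed = config$seed)),
      file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "config_resolved.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(thresholds = th, control_trials = ctrl$trials,
       activated_trials = scored, penetrance = pen, config = config)
}
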