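#' Parameters for simulated two-photon calcium movies
#'
#' Emulates single-glomerulus recordings: a 90 x 128 frame at 10 Hz
#' containing a glomerulus-shaped (elliptical) region whose pixels follow a
#' baseline plus stimulus-locked indicator transients (instantaneous rise,
#' exponential decay), with Gaussian pixel noise and rigid integer frame
#' jitter.
#'
#' @param movie_shape `c(rows, cols)` (default `c(90, 128)`).
#' @param frame_rate Hz (default 10).
#' @param glomerulus_center `c(row, col)` in pixels (default frame center).
#' @param glomerulus_axes `c(semi_row, semi_col)` in pixels (default
#'   `c(10, 14)`).
#' @param baseline_intensity Glomerulus resting intensity (default 100).
#' @param background_intensity Surround intensity (default 20).
#' @param response_amplitude Named numeric vector of fractional response
#'   amplitudes per stimulus id (peak dF/F of the injected transient).
#' @param indicator_decay_tau Indicator decay time constant, seconds
#'   (default 1.5).
#' @param noise_sd Gaussian pixel noise SD in intensity units (default 2).
#' @param jitter_max Maximum rigid integer shift per frame, pixels
#'   (default 3).
#' @param pre_time Seconds of baseline before the first epoch (default 5).
#' @param epoch_duration,inter_epoch Stimulus epoch length and gap, seconds
#'   (defaults 4 and 8); the transient rises at `expansion_stop`, placed at
#'   the end of each epoch.
#' @param seed Integer seed (mandatory).
#' @return An object of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(movie_shape = c(90, 128), frame_rate = 10,
                               glomerulus_center = NULL,
                               glomerulus_axes = c(10, 14),
                               baseline_intensity = 100,
                               background_intensity = 20,
                               response_amplitude = c(loom_dark = 1,
                                                      loom_bright = 0.25,
                                                      luminance_matched = 0.5),
                               indicator_decay_tau = 1.5, noise_sd = 2,
                               jitter_max = 3, pre_time = 5,
                               epoch_duration = 4, inter_epoch = 8, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(glomerulus_center)) glomerulus_center <- movie_shape / 2
  stopifnot(indicator_decay_tau > 0, jitter_max >= 0, noise_sd >= 0,
            frame_rate > 0, all(glomerulus_axes > 0))
  if (glomerulus_center[1] + glomerulus_axes[1] > movie_shape[1] ||
      glomerulus_center[1] - glomerulus_axes[1] < 1 ||
      glomerulus_center[2] + glomerulus_axes[2] > movie_shape[2] ||
      glomerulus_center[2] - glomerulus_axes[2] < 1)
    stop("glomerulus does not fit inside the frame")
  structure(as.list(environment()), class = "calcium_sim_params")
}

#' Simulate a calcium movie with known ground truth
#'
#' Builds one continuous recording covering the scheduled stimulus
#' presentations. Glomerulus pixels follow
#' `baseline * (1 + a * kernel(t))` where the kernel rises instantaneously
#' at each epoch's expansion stop and decays exponentially with the
#' indicator time constant; `a` is the scheduled stimulus's amplitude.
#' Whole frames are rigidly shifted by integer jitter drawn uniformly in
#' `[-jitter_max, jitter_max]` per axis (vacated pixels filled with the
#' background intensity), then Gaussian noise is added.
#'
#' @param params A [calcium_sim_params()] object.
#' @param schedule A data.frame with a `stimulus_id` column, e.g. from
#'   [randomized_block_schedule()]; every id must have an amplitude in
#'   `params$response_amplitude`.
#' @return A list: `movie` (a [calcium_movie()] with an `epochs` table
#'   carrying `expansion_stop` markers), `ground_truth` (list with the ROI
#'   `mask`, per-frame `shifts`, the unshifted noise-free resting frame
#'   `reference`, per-epoch `amplitudes`, and the noise-free ROI-mean trace
#'   `clean_F`).
#' @export
simulate_calcium_movie <- function(params, schedule) {
  stopifnot(inherits(params, "calcium_sim_params"), is.data.frame(schedule))
  ids <- as.character(schedule$stimulus_id)
  if (!all(ids %in% names(params$response_amplitude)))
    stop("schedule contains stimulus ids without a configured amplitude")
  set.seed(as.integer(params$seed))
  fr <- params$frame_rate
  n_ep <- length(ids)
  starts <- params$pre_time +
    (seq_len(n_ep) - 1) * (params$epoch_duration + params$inter_epoch)
  stops <- starts + params$epoch_duration
  if (n_ep > 1 && any(starts[-1] < stops[-n_ep]))
    stop("schedule epochs overlap")
  epochs <- data.frame(stimulus_id = ids, start = starts, stop = stops,
                       expansion_stop = stops, stringsAsFactors = FALSE)
  total <- stops[n_ep] + params$inter_epoch
  n_frames <- floor(total * fr)
  t <- (seq_len(n_frames) - 1) / fr

  kernel <- numeric(n_frames)
  amps <- params$response_amplitude[ids]
  for (e in seq_len(n_ep)) {
    after <- t >= epochs$expansion_stop[e]
    kernel[after] <- kernel[after] +
      amps[e] * exp(-(t[after] - epochs$expansion_stop[e]) / params$indicator_decay_tau)
  }

  mask <- ellipse_roi(params$movie_shape, params$glomerulus_center,
                      params$glomerulus_axes)
  base <- matrix(params$background_intensity, params$movie_shape[1],
                 params$movie_shape[2])
  base[mask] <- params$baseline_intensity

  shifts <- data.frame(frame = seq_len(n_frames),
                       dy = sample(-params$jitter_max:params$jitter_max,
                                   n_frames, replace = TRUE),
                       dx = sample(-params$jitter_max:params$jitter_max,
                                   n_frames, replace = TRUE))
  frames <- array(0, c(params$movie_shape, n_frames))
  npx <- prod(params$movie_shape)
  for (k in seq_len(n_frames)) {
    f <- base
    f[mask] <- params$baseline_intensity * (1 + kernel[k])
    f <- shift_frame(f, shifts$dy[k], shifts$dx[k],
                     fill = params$background_intensity)
    if (params$noise_sd > 0)
      f <- f + matrix(rnorm(npx, 0, params$noise_sd),
                      params$movie_shape[1], params$movie_shape[2])
    frames[, , k] <- f
  }
  movie <- calcium_movie(frames, frame_rate = fr, epochs = epochs,
                         fly_id = "sim_fly", stimulus_id = "mixed")
  list(movie = movie,
       ground_truth = list(mask = mask, shifts = shifts, reference = base,
                           amplitudes = stats::setNames(as.numeric(amps), ids),
                           epoch_amplitude = data.frame(epoch = seq_len(n_ep),
                                                        stimulus_id = ids,
                                                        amplitude = as.numeric(amps)),
                           clean_F = params$baseline_intensity * (1 + kernel)),
       params = params)
}
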