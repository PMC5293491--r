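#' Modeled LED display geometry
#'
#' Describes the cylindrical LED arena as seen from the fly at its center:
#' angular extent in azimuth and elevation and the angular pitch of one LED
#' pixel. Azimuth increases rightward from the visual midline and elevation
#' upward; the display spans `[-azimuth_extent/2, azimuth_extent/2]` by
#' `[-elevation_extent/2, elevation_extent/2]`. Frames are stored as matrices
#' with rows = elevation (top row = highest elevation) and columns = azimuth
#' (first column = leftmost).
#'
#' @param azimuth_extent Total azimuthal extent in degrees (default 216).
#' @param elevation_extent Total elevation extent in degrees (default 72).
#' @param pixel_pitch Degrees subtended per pixel (default 2.25).
#' @param intensity_levels Number of gray levels (default 256); rendered
#'   intensities lie in `[0, intensity_levels - 1]`.
#' @return An object of class `display_geometry` with the grid dimensions
#'   (`n_azimuth`, `n_elevation`) resolved.
#' @export
display_geometry <- function(azimuth_extent = 216, elevation_extent = 72,
                             pixel_pitch = 2.25, intensity_levels = 256) {
  stopifnot(pixel_pitch > 0, azimuth_extent > 0, elevation_extent > 0,
            intensity_levels >= 2)
  n_az <- azimuth_extent / pixel_pitch
  n_el <- elevation_extent / pixel_pitch
  if (abs(n_az - round(n_az)) > 1e-9 || abs(n_el - round(n_el)) > 1e-9)
    stop("display extents must be integer multiples of pixel_pitch")
  structure(list(azimuth_extent = azimuth_extent,
                 elevation_extent = elevation_extent,
                 pixel_pitch = pixel_pitch,
                 intensity_levels = as.integer(intensity_levels),
                 n_azimuth = as.integer(round(n_az)),
                 n_elevation = as.integer(round(n_el))),
            class = "display_geometry")
}

#' Looming stimulus parameters
#'
#' A loom is an expanding disk mimicking an object of radius r approaching at
#' constant speed v; its time course is governed solely by the ratio r/v
#' (units of time). The disk appears at `theta_min` full angular diameter and
#' expands through `n_sizes` discrete sizes to `theta_max`.
#'
#' @param r_over_v Ratio of object radius to approach speed, seconds
#'   (default 0.55 s, i.e. 550 ms).
#' @param theta_min,theta_max Initial and final full angular diameters in
#'   degrees (defaults 4.5 and 54).
#' @param n_sizes Number of distinct disk sizes (default 35).
#' @param polarity `"dark_on_bright"` (default) or `"bright_on_dark"`.
#' @param center Disk center as `c(azimuth, elevation)` in degrees.
#' @param frame_rate Display frame rate in Hz (default 60).
#' @param pre_hold,post_hold Seconds the initial/final disk is held static
#'   before/after expansion (default 1 s each).
#' @return An object of class `loom_params`.
#' @export
loom_params <- function(r_over_v = 0.55, theta_min = 4.5, theta_max = 54,
                        n_sizes = 35,
                        polarity = c("dark_on_bright", "bright_on_dark"),
                        center = c(0, 0), frame_rate = 60,
                        pre_hold = 1, post_hold = 1) {
  polarity <- match.arg(polarity)
  if (!(r_over_v > 0)) stop("r_over_v must be positive")
  if (!(theta_min > 0 && theta_min < theta_max && theta_max < 180))
    stop("need 0 < theta_min < theta_max < 180")
  if (n_sizes < 2) stop("n_sizes must be at least 2")
  stopifnot(frame_rate > 0, pre_hold >= 0, post_hold >= 0, length(center) == 2)
  structure(list(r_over_v = r_over_v, theta_min = theta_min,
                 theta_max = theta_max, n_sizes = as.integer(n_sizes),
                 polarity = polarity, center = as.numeric(center),
                 frame_rate = frame_rate, pre_hold = pre_hold,
                 post_hold = post_hold),
            class = "loom_params")
}

#' Angular diameter of a looming object
#'
#' Closed form for constant-approach-velocity looming: an object of radius r
#' approaching at speed v subtends the full angle
#' \deqn{\theta(t) = 2\,\arctan\!\big((r/v)/t\big)}
#' at time-to-collision t. The expansion speed is set by the single parameter
#' r/v.
#'
#' @param time_to_collision Time remaining until collision, seconds (> 0).
#'   Vectorized.
#' @param r_over_v Ratio of radius to approach speed, seconds (> 0).
#' @return Full angular diameter in degrees; strictly decreasing in
#'   `time_to_collision`.
#' @export
loom_angular_diameter <- function(time_to_collision, r_over_v) {
  if (any(!is.finite(time_to_collision)) || any(time_to_collision <= 0))
    stop("time_to_collision must be positive")
  if (!is.finite(r_over_v) || r_over_v <= 0) stop("r_over_v must be positive")
  2 * atan(r_over_v / time_to_collision) * 180 / pi
}

#' Time-to-collision at which a loom reaches a given diameter
#'
#' Inverts [loom_angular_diameter()]: `t = (r/v) / tan(theta/2)`.
#'
#' @param theta_deg Full angular diameter in degrees, in (0, 180). Vectorized.
#' @param r_over_v Ratio of radius to approach speed, seconds (> 0).
#' @return Time-to-collision in seconds.
#' @export
loom_time_to_collision <- function(theta_deg, r_over_v) {
  if (any(theta_deg <= 0) || any(theta_deg >= 180))
    stop("theta_deg must lie in (0, 180)")
  if (!is.finite(r_over_v) || r_over_v <= 0) stop("r_over_v must be positive")
  r_over_v / tan(theta_deg / 2 * pi / 180)
}

# Pixel centers along azimuth (left to right) and elevation (top to bottom).
display_axes <- function(display) {
  p <- display$pixel_pitch
  az <- -display$azimuth_extent / 2 + (seq_len(display$n_azimuth) - 0.5) * p
  el <- display$elevation_extent / 2 - (seq_len(display$n_elevation) - 0.5) * p
  list(azimuth = az, elevation = el)
}

# Fractional coverage of each display pixel by a disk of full angular
# diameter theta centered at center = c(az, el), by ss x ss supersampling.
disk_coverage <- function(theta_deg, center, display, ss = 8) {
  p <- display$pixel_pitch
  r <- theta_deg / 2
  ax <- display_axes(display)
  off <- ((seq_len(ss) - 0.5) / ss - 0.5) * p
  cov <- matrix(0, display$n_elevation, display$n_azimuth)
  # restrict work to the disk's bounding box
  jx <- which(abs(ax$azimuth - center[1]) <= r + p)
  iy <- which(abs(ax$elevation - center[2]) <= r + p)
  if (!length(jx) || !length(iy)) return(cov)
  for (i in iy) {
    ey <- ax$elevation[i] + off
    dy2 <- outer(rep(1, ss), (ey - center[2])^2)      # ss x ss, cols vary in y
    for (j in jx) {
      exx <- ax$azimuth[j] + off
      dx2 <- outer((exx - center[1])^2, rep(1, ss))
      cov[i, j] <- mean(dx2 + dy2 <= r^2)
    }
  }
  cov
}

#' Generate a looming-disk frame sequence
#'
#' Renders a dark (or bright) looming disk on the modeled display. The disk
#' steps through `n_sizes` diameters spaced uniformly between `theta_min` and
#' `theta_max`; each size appears at the moment the constant-approach closed
#' form \eqn{\theta(t)=2\arctan((r/v)/t)} first reaches it, so the time course
#' is exact at size transitions. Edge pixels are anti-aliased by fractional
#' pixel coverage of the ideal circle. The initial disk is held for
#' `pre_hold` seconds before expansion and the final disk for `post_hold`
#' seconds after it.
#'
#' @param params A [loom_params()] object.
#' @param display A [display_geometry()] object.
#' @return An object of class `stimulus_sequence`: a list with `frames` (list
#'   of matrices, intensities in `[0, intensity_levels - 1]`), `timestamps`
#'   (seconds), `angular_diameter` (degrees per frame, non-decreasing),
#'   `epoch_markers` (named list with `onset` and `expansion_stop` times),
#'   `size_table` (data.frame of emitted diameters and their presentation
#'   times and times-to-collision), `kind`, and the generating parameters.
#' @export
generate_loom_sequence <- function(params = loom_params(),
                                   display = display_geometry()) {
  stopifnot(inherits(params, "loom_params"), inherits(display, "display_geometry"))
  half_span_az <- display$azimuth_extent / 2
  half_span_el <- display$elevation_extent / 2
  if (params$theta_max / 2 + abs(params$center[2]) > half_span_el ||
      params$theta_max / 2 + abs(params$center[1]) > half_span_az)
    stop(sprintf("disk of diameter %g deg does not fit the display at center (%g, %g)",
                 params$theta_max, params$center[1], params$center[2]))

  diameters <- seq(params$theta_min, params$theta_max,
                   length.out = params$n_sizes)
  ttc <- loom_time_to_collision(diameters, params$r_over_v)  # decreasing
  # expansion starts at t = pre_hold; size i appears at pre_hold + (ttc[1] - ttc[i])
  onset_times <- params$pre_hold + (ttc[1] - ttc)
  expansion_stop <- onset_times[params$n_sizes]
  total <- expansion_stop + params$post_hold
  dt <- 1 / params$frame_rate
  timestamps <- seq(0, total, by = dt)

  bg <- display$intensity_levels - 1
  idx <- findInterval(timestamps, onset_times)  # 0 during pre-hold
  idx[idx < 1] <- 1L
  ang <- diameters[idx]

  frame_cache <- vector("list", params$n_sizes)
  frames <- vector("list", length(timestamps))
  for (k in seq_along(timestamps)) {
    i <- idx[k]
    if (is.null(frame_cache[[i]])) {
      cov <- disk_coverage(diameters[i], params$center, display)
      f <- if (params$polarity == "dark_on_bright") bg * (1 - cov) else bg * cov
      frame_cache[[i]] <- f
    }
    frames[[k]] <- frame_cache[[i]]
  }
  structure(list(frames = frames, timestamps = timestamps,
                 angular_diameter = ang,
                 epoch_markers = list(onset = params$pre_hold,
                                      expansion_stop = expansion_stop),
                 size_table = data.frame(diameter = diameters,
                                         time_to_collision = ttc,
                                         presentation_time = onset_times),
                 kind = if (params$polarity == "dark_on_bright") "loom_dark" else "loom_bright",
                 params = params, display = display),
            class = "stimulus_sequence")
}

#' Luminance-matched scramble control
#'
#' Builds the control stimulus that darkens with the same per-frame total
#' luminance as a dark loom but carries no coherent edge motion: within each
#' frame, every darkened pixel is relocated to a uniformly random position
#' inside the footprint of the final (maximum-size) disk. Per-frame dark-pixel
#' count, total intensity, and the intensity histogram are preserved exactly.
#'
#' @param seq A `stimulus_sequence` of kind `loom_dark`.
#' @param seed Integer seed; the scramble is deterministic given the seed.
#' @return A `stimulus_sequence` of kind `luminance_matched`.
#' @export
luminance_match <- function(seq, seed) {
  stopifnot(inherits(seq, "stimulus_sequence"))
  if (!identical(seq$kind, "loom_dark"))
    stop("luminance_match requires a dark loom sequence")
  set.seed(as.integer(seed))
  bg <- seq$display$intensity_levels - 1
  final_cov <- disk_coverage(max(seq$angular_diameter), seq$params$center,
                             seq$display)
  mask_idx <- which(final_cov > 0)
  frames <- lapply(seq$frames, function(f) {
    dark <- which(f < bg)
    if (!length(dark)) return(f)
    if (any(!(dark %in% mask_idx)))
      stop("frame has dark pixels outside the final-disk footprint")
    out <- matrix(bg, nrow(f), ncol(f))
    dest <- sample(mask_idx, length(dark))
    out[dest] <- f[dark]
    out
  })
  out <- seq
  out$frames <- frames
  out$kind <- "luminance_matched"
  out$seed <- as.integer(seed)
  out
}

#' Generate a translating object or bar stimulus
#'
#' A dark rectangle of the given angular size translates at constant angular
#' speed along the azimuth at fixed elevation. Edges are anti-aliased by
#' exact fractional pixel coverage (separable rectangle/pixel overlap).
#'
#' @param width_deg,height_deg Object size in degrees.
#' @param speed Angular speed in degrees/second (> 0).
#' @param start_azimuth,end_azimuth Azimuth of the object center at the start
#'   and end of the traversal, degrees (negative = left of midline).
#' @param elevation Elevation of the object center, degrees.
#' @param display A [display_geometry()].
#' @param frame_rate Frames per second.
#' @return A `stimulus_sequence` of kind `"object"` (or `"bar"` when the
#'   object spans the full display height).
#' @export
generate_object_motion <- function(width_deg, height_deg, speed,
                                   start_azimuth, end_azimuth, elevation,
                                   display = display_geometry(),
                                   frame_rate = 60) {
  stopifnot(inherits(display, "display_geometry"),
            width_deg > 0, height_deg > 0, speed > 0, frame_rate > 0)
  if (start_azimuth == end_azimuth) stop("start and end azimuth must differ")
  if (height_deg > display$elevation_extent)
    stop("object taller than the display")
  duration <- abs(end_azimuth - start_azimuth) / speed
  n_frames <- floor(duration * frame_rate) + 1L
  if (n_frames < 1) stop("stimulus spans zero frames")
  timestamps <- (seq_len(n_frames) - 1) / frame_rate
  centers <- start_azimuth + sign(end_azimuth - start_azimuth) * speed * timestamps
  # make sure the final frame sits exactly at the end azimuth
  if (abs(centers[n_frames] - end_azimuth) > 1e-9) {
    timestamps <- c(timestamps, duration)
    centers <- c(centers, end_azimuth)
    n_frames <- n_frames + 1L
  }

  ax <- display_axes(display)
  p <- display$pixel_pitch
  bg <- display$intensity_levels - 1
  # elevation overlap is constant across frames
  el_lo <- elevation - height_deg / 2; el_hi <- elevation + height_deg / 2
  ov_el <- pmax(0, pmin(ax$elevation + p / 2, el_hi) - pmax(ax$elevation - p / 2, el_lo)) / p
  frames <- lapply(centers, function(cz) {
    az_lo <- cz - width_deg / 2; az_hi <- cz + width_deg / 2
    ov_az <- pmax(0, pmin(ax$azimuth + p / 2, az_hi) - pmax(ax$azimuth - p / 2, az_lo)) / p
    bg * (1 - outer(ov_el, ov_az))
  })
  kind <- if (height_deg >= display$elevation_extent) "bar" else "object"
  structure(list(frames = frames, timestamps = timestamps,
                 angular_diameter = NULL,
                 epoch_markers = list(onset = 0, offset = timestamps[length(timestamps)]),
                 object_azimuth = centers, duration = duration,
                 kind = kind, display = display),
            class = "stimulus_sequence")
}

#' Randomized block trial schedule
#'
#' Orders stimulus presentations in a randomized block structure: each block
#' contains every stimulus exactly once in random order, and blocks are
#' concatenated for the requested number of repetitions.
#'
#' @param stimulus_ids Character or numeric vector of distinct stimulus ids.
#' @param n_repetitions Number of blocks (>= 1).
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return A data.frame with columns `block`, `position`, `stimulus_id`.
#' @export
randomized_block_schedule <- function(stimulus_ids, n_repetitions, seed) {
  if (!length(stimulus_ids)) stop("stimulus_ids must be non-empty")
  if (anyDuplicated(stimulus_ids)) stop("stimulus_ids must be distinct")
  if (n_repetitions < 1) stop("n_repetitions must be >= 1")
  set.seed(as.integer(seed))
  k <- length(stimulus_ids)
  blocks <- lapply(seq_len(n_repetitions), function(b) {
    data.frame(block = b, position = seq_len(k),
               stimulus_id = stimulus_ids[sample.int(k)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, blocks)
}
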