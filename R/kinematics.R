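#' Construct a fly trajectory
#'
#' Per-frame position (mm) and heading (degrees, the direction the fly faces,
#' in [0, 360)) of one fly in one trial, on a uniform time base.
#'
#' @param time Seconds per frame, strictly increasing and uniformly spaced.
#' @param x,y Position in mm.
#' @param heading Heading in degrees, `[0, 360)`.
#' @param frame_rate Frames per second; if missing, inferred from `time`.
#' @param arena_id Optional label for the arena/assay.
#' @return A data.frame of class `fly_trajectory` with columns
#'   `time`, `x`, `y`, `heading` and attributes `frame_rate`, `arena_id`.
#' @export
trajectory <- function(time, x, y, heading, frame_rate = NULL, arena_id = NA) {
  n <- length(time)
  stopifnot(n >= 2, length(x) == n, length(y) == n, length(heading) == n)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("time must be uniformly spaced within a trial")
  if (is.null(frame_rate)) frame_rate <- 1 / mean(dt)
  out <- data.frame(time = time, x = x, y = y, heading = heading %% 360)
  attr(out, "frame_rate") <- frame_rate
  attr(out, "arena_id") <- arena_id
  class(out) <- c("fly_trajectory", "data.frame")
  out
}

#' Unwrap a circular heading series
#'
#' Removes 360-degree jumps so that successive differences have magnitude
#' below 180 degrees; the output equals the input modulo 360.
#'
#' @param heading Heading series in degrees, values in `[0, 360)`.
#' @return Continuous heading series in degrees.
#' @export
unwrap_heading <- function(heading) {
  if (!length(heading)) stop("empty heading series")
  d <- diff(heading)
  d <- ((d + 180) %% 360) - 180
  heading[1] + c(0, cumsum(d))
}

#' Body-frame forward/backward velocity
#'
#' Projects the fly's motion onto its body axis: the smoothed path speed is
#' signed by agreement between the instantaneous displacement direction and
#' the heading (positive when moving in the direction the fly faces, negative
#' when retreating backward). Displacements are smoothed with a centered
#' moving average before differentiation.
#'
#' @param traj A [trajectory()].
#' @param smooth_window Centered moving-average window in frames (odd,
#'   default 5).
#' @return A data.frame of class `kinematic_series` with columns `time`,
#'   `forward_velocity` (mm/s) and `fv_valid` (FALSE at edge frames where the
#'   smoothing window lacks full support).
#' @export
body_frame_velocity <- function(traj, smooth_window = 5) {
  stopifnot(inherits(traj, "fly_trajectory"))
  n <- nrow(traj)
  if (smooth_window %% 2 != 1) stop("smooth_window must be odd")
  if (n < smooth_window + 2) stop("trajectory shorter than smoothing window")
  fr <- attr(traj, "frame_rate")
  xs <- moving_average(traj$x, smooth_window)
  ys <- moving_average(traj$y, smooth_window)
  # centered differences of the smoothed path
  vx <- c(NA, (xs[-(1:2)] - xs[seq_len(n - 2)]) * fr / 2, NA)
  vy <- c(NA, (ys[-(1:2)] - ys[seq_len(n - 2)]) * fr / 2, NA)
  speed <- sqrt(vx^2 + vy^2)
  hd <- traj$heading * pi / 180
  align <- vx * cos(hd) + vy * sin(hd)    # |v| cos(angle between v and heading)
  sgn <- ifelse(speed > 0, sign(align), 0)
  fv <- ifelse(speed > 0, speed * sgn, 0)
  half <- (smooth_window - 1) / 2
  valid <- rep(TRUE, n)
  valid[seq_len(half + 1)] <- FALSE
  valid[seq(n - half, n)] <- FALSE
  fv[!valid] <- NA_real_
  out <- data.frame(time = traj$time, forward_velocity = fv, fv_valid = valid)
  attr(out, "frame_rate") <- fr
  class(out) <- c("kinematic_series", "data.frame")
  out
}

moving_average <- function(x, w) {
  half <- (w - 1) / 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(half + 1):(half + length(x))]
}

#' Angular velocity via a sliding Savitzky-Golay filter
#'
#' Differentiates the unwrapped heading with a Savitzky-Golay least-squares
#' polynomial filter, scaled by the frame rate to degrees/second. The
#' derivative is exact (to floating tolerance) for polynomial headings of
#' degree at most `sg_order` at interior frames.
#'
#' @param traj A [trajectory()].
#' @param sg_window Filter window length in frames (odd, default 7).
#' @param sg_order Polynomial order (default 2, must be < `sg_window`).
#' @return A data.frame of class `kinematic_series` with columns `time`,
#'   `angular_velocity` (deg/s, positive = counterclockwise viewed from
#'   above), `angular_speed` (its absolute value) and `av_valid` (FALSE at
#'   edge frames without full window support).
#' @export
angular_velocity <- function(traj, sg_window = 7, sg_order = 2) {
  stopifnot(inherits(traj, "fly_trajectory"))
  if (sg_window %% 2 != 1) stop("sg_window must be odd")
  if (sg_order >= sg_window) stop("sg_order must be smaller than sg_window")
  n <- nrow(traj)
  if (n < sg_window) stop("trajectory shorter than the Savitzky-Golay window")
  fr <- attr(traj, "frame_rate")
  h <- unwrap_heading(traj$heading)
  av <- signal::sgolayfilt(h, p = sg_order, n = sg_window, m = 1, ts = 1 / fr)
  half <- (sg_window - 1) / 2
  valid <- rep(TRUE, n)
  valid[seq_len(half)] <- FALSE
  valid[seq(n - half + 1, n)] <- FALSE
  av[!valid] <- NA_real_
  out <- data.frame(time = traj$time, angular_velocity = av,
                    angular_speed = abs(av), av_valid = valid)
  attr(out, "frame_rate") <- fr
  class(out) <- c("kinematic_series", "data.frame")
  out
}

#' Combine velocity and turning series on one time base
#'
#' @param fv Output of [body_frame_velocity()].
#' @param av Output of [angular_velocity()] for the same trajectory.
#' @return A merged `kinematic_series` data.frame.
#' @export
kinematic_series <- function(fv, av) {
  stopifnot(nrow(fv) == nrow(av), all(abs(fv$time - av$time) < 1e-9))
  out <- data.frame(time = fv$time,
                    forward_velocity = fv$forward_velocity,
                    fv_valid = fv$fv_valid,
                    angular_velocity = av$angular_velocity,
                    angular_speed = av$angular_speed,
                    av_valid = av$av_valid)
  attr(out, "frame_rate") <- attr(fv, "frame_rate")
  class(out) <- c("kinematic_series", "data.frame")
  out
}

#' Kinematic summary over a stimulation window
#'
#' Arithmetic means over frames whose timestamps fall in
#' `[window_start, window_start + window_duration)`. Edge frames flagged
#' invalid by the upstream filters are excluded.
#'
#' @param series A `kinematic_series` with any of `forward_velocity`,
#'   `angular_velocity`, `angular_speed`.
#' @param window_start,window_duration Window placement in seconds.
#' @return A one-row data.frame with `mean_forward_velocity`,
#'   `mean_angular_speed`, `mean_signed_angular_velocity` (NA for series that
#'   lack the corresponding column) and `n_frames`.
#' @export
trial_window_summary <- function(series, window_start, window_duration) {
  stopifnot(window_duration > 0)
  sel <- series$time >= window_start & series$time < window_start + window_duration
  if (!any(sel)) stop("window contains no frames")
  mean_of <- function(col, valid_col) {
    if (is.null(series[[col]])) return(NA_real_)
    v <- series[[col]][sel]
    if (!is.null(series[[valid_col]])) v <- v[series[[valid_col]][sel]]
    if (!length(v)) stop("window contains no valid frames for ", col)
    mean(v)
  }
  data.frame(mean_forward_velocity = mean_of("forward_velocity", "fv_valid"),
             mean_angular_speed = mean_of("angular_speed", "av_valid"),
             mean_signed_angular_velocity = mean_of("angular_velocity", "av_valid"),
             n_frames = sum(sel))
}

#' Total signed walking distance
#'
#' Time-integral of body-frame forward velocity over the valid frames of the
#' series: forward walking contributes positively, backward walking
#' negatively.
#'
#' @param series A `kinematic_series` with `forward_velocity`.
#' @return Distance in mm.
#' @export
total_signed_distance <- function(series) {
  if (!nrow(series)) stop("empty series")
  fr <- attr(series, "frame_rate")
  v <- series$forward_velocity
  if (!is.null(series$fv_valid)) v <- v[series$fv_valid]
  sum(v) / fr
}

#' Takeoff sequence duration
#'
#' Time from the first moment of wing movement to the last moment of tarsal
#' contact with the ground, from manually annotated frame indices.
#'
#' @param wing_frame Frame index of the first wing movement.
#' @param release_frame Frame index of the last tarsal contact
#'   (>= `wing_frame`).
#' @param frame_rate Recording frame rate in Hz (6000 for the high-speed
#'   single-fly assay).
#' @return Duration in milliseconds.
#' @export
takeoff_sequence_duration <- function(wing_frame, release_frame, frame_rate) {
  if (missing(wing_frame) || missing(release_frame) ||
      is.na(wing_frame) || is.na(release_frame))
    stop("both wing-movement and tarsal-release annotations are required")
  if (release_frame < wing_frame)
    stop("tarsal release cannot precede wing movement")
  stopifnot(frame_rate > 0)
  (release_frame - wing_frame) / frame_rate * 1000
}
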