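#' Parameters for simulated arena optogenetics trials
#'
#' Defines the study conditions emulated by the behavioral generator: flies
#' walking freely in a circular arena, recorded at 50 Hz, with a 1 s
#' red-light stimulation flanked by 1 s pre- and post-windows. With
#' probability `response_probability` a trial carries a stimulation-locked
#' behavioral episode of the configured kind (backward walking, turning, or
#' jumping), ramped on and off over `ramp` seconds.
#'
#' @param n_flies Number of flies (default 10).
#' @param trials_per_fly Trials per fly (default 5).
#' @param frame_rate Tracking frame rate in Hz (default 50).
#' @param stim_onset,stim_duration Stimulation window in seconds (defaults
#'   1 and 1; trials span `stim_onset + stim_duration + post` seconds).
#' @param post Post-stimulation recording in seconds (default 1).
#' @param baseline_speed_mean,baseline_speed_sd Per-trial baseline walking
#'   speed distribution, mm/s (defaults 5 and 2).
#' @param response_kind One of `"none"`, `"backward"`, `"forward"`,
#'   `"turn_left"`, `"turn_right"`, `"jump"`.
#' @param response_magnitude Episode strength: mm/s for walking kinds
#'   (default 10), deg/s for turning (default 200 when a turning kind is
#'   chosen and the magnitude is left at its walking default).
#' @param response_probability Ground-truth per-trial penetrance in [0, 1].
#' @param heading_noise_sd Heading diffusion, deg/sqrt(s) (default 30).
#' @param arena_radius Arena radius in mm (default 50); flies reflect off the
#'   wall.
#' @param group Group label recorded in the trial table.
#' @param seed Integer seed (mandatory).
#' @return An object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(n_flies = 10, trials_per_fly = 5,
                                frame_rate = 50, stim_onset = 1,
                                stim_duration = 1, post = 1,
                                baseline_speed_mean = 5,
                                baseline_speed_sd = 2,
                                response_kind = "none",
                                response_magnitude = NULL,
                                response_probability = 0,
                                heading_noise_sd = 30,
                                arena_radius = 50,
                                group = "sim", seed) {
  if (missing(seed)) stop("seed is mandatory")
  response_kind <- match.arg(response_kind,
                             c("none", "backward", "forward", "turn_left",
                               "turn_right", "jump"))
  if (is.null(response_magnitude))
    response_magnitude <- if (grepl("^turn", response_kind)) 200 else 10
  stopifnot(response_probability >= 0, response_probability <= 1,
            is.finite(response_magnitude), n_flies >= 1, trials_per_fly >= 1,
            frame_rate > 0, stim_duration > 0, heading_noise_sd >= 0)
  structure(as.list(environment()), class = "behavior_sim_params")
}

# one trajectory; episode (logical) injects the stimulation-locked behavior
simulate_one_trajectory <- function(p, episode) {
  dt <- 1 / p$frame_rate
  total <- p$stim_onset + p$stim_duration + p$post
  time <- seq(0, total - dt, by = dt)
  n <- length(time)
  in_stim <- time >= p$stim_onset & time < p$stim_onset + p$stim_duration
  ramp <- 0.1
  # smooth 0->1->0 envelope over the stimulation window
  env <- pmin(1, pmax(0, pmin((time - p$stim_onset) / ramp,
                              (p$stim_onset + p$stim_duration - time) / ramp)))
  env[!in_stim & env < 0] <- 0

  base_speed <- max(0.1, rnorm(1, p$baseline_speed_mean, p$baseline_speed_sd))
  speed <- base_speed + as.numeric(stats::filter(rnorm(n, 0, 1.5),
                                                 rep(1 / 5, 5), sides = 2,
                                                 circular = TRUE))
  speed <- pmax(speed, 0)
  heading <- cumsum(c(runif(1, 0, 360),
                      rnorm(n - 1, 0, p$heading_noise_sd * sqrt(dt))))[seq_len(n)]

  if (episode && p$response_kind %in% c("backward", "forward")) {
    target <- if (p$response_kind == "backward") -p$response_magnitude else p$response_magnitude
    speed <- speed * (1 - env) + target * env
  }
  if (episode && grepl("^turn", p$response_kind)) {
    drift <- if (p$response_kind == "turn_left") p$response_magnitude else -p$response_magnitude
    heading <- heading + cumsum(drift * env * dt)
  }

  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, -10, 10); y[1] <- runif(1, -10, 10)
  hd <- heading * pi / 180
  for (k in seq_len(n - 1)) {
    x[k + 1] <- x[k] + speed[k] * cos(hd[k]) * dt
    y[k + 1] <- y[k] + speed[k] * sin(hd[k]) * dt
    rr <- sqrt(x[k + 1]^2 + y[k + 1]^2)
    if (rr > p$arena_radius) {         # reflect off the arena wall
      x[k + 1] <- x[k + 1] * (2 * p$arena_radius - rr) / rr
      y[k + 1] <- y[k + 1] * (2 * p$arena_radius - rr) / rr
      heading[(k + 1):n] <- heading[(k + 1):n] +
        2 * (atan2(-y[k + 1], -x[k + 1]) * 180 / pi - heading[k + 1])
      hd <- heading * pi / 180
    }
  }
  trajectory(time, x, y, heading %% 360, frame_rate = p$frame_rate,
             arena_id = "sim_arena")
}

#' Simulate arena optogenetics trials with known ground truth
#'
#' Generates smooth random-walk trajectories for a cohort of flies, injects
#' stimulation-locked behavioral episodes with the configured per-trial
#' probability, and scores each trajectory through the kinematics module
#' ([body_frame_velocity()], [angular_velocity()],
#' [trial_window_summary()]) to produce a trial table ready for
#' [compute_thresholds()] / [classify_trials()].
#'
#' @param params A [behavior_sim_params()] object.
#' @return A list with `trajectories` (list of [trajectory()] objects, named
#'   `fly_trial`), `trials` (trial-record data.frame with windowed kinematic
#'   summaries and manual-style `jump`/`reach` flags), and `ground_truth`
#'   (data.frame flagging which trials carry an episode). Deterministic given
#'   the seed.
#' @export
simulate_arena_trials <- function(params) {
  stopifnot(inherits(params, "behavior_sim_params"))
  set.seed(as.integer(params$seed))
  rows <- list(); gt <- list(); trajs <- list()
  i <- 0
  for (fly in seq_len(params$n_flies)) {
    for (tr in seq_len(params$trials_per_fly)) {
      i <- i + 1
      episode <- runif(1) < params$response_probability &&
        params$response_kind != "none"
      traj <- simulate_one_trajectory(params, episode)
      ks <- kinematic_series(body_frame_velocity(traj),
                             angular_velocity(traj))
      sm <- trial_window_summary(ks, params$stim_onset, params$stim_duration)
      fly_id <- sprintf("fly%02d", fly)
      rows[[i]] <- data.frame(
        fly_id = fly_id, group = params$group, trial_index = tr,
        assay = "arena", stim_onset = params$stim_onset,
        stim_duration = params$stim_duration,
        mean_forward_velocity = sm$mean_forward_velocity,
        mean_angular_speed = sm$mean_angular_speed,
        mean_signed_angular_velocity = sm$mean_signed_angular_velocity,
        jump = episode && params$response_kind == "jump",
        reach = FALSE, labeling = "unknown", stringsAsFactors = FALSE)
      gt[[i]] <- data.frame(fly_id = fly_id, trial_index = tr,
                            episode = episode,
                            kind = if (episode) params$response_kind else "none",
                            stringsAsFactors = FALSE)
      trajs[[paste0(fly_id, "_", tr)]] <- traj
    }
  }
  list(trajectories = trajs,
       trials = do.call(rbind, rows),
       ground_truth = do.call(rbind, gt),
       params = params)
}

#' Render a synthetic fly video from a trajectory
#'
#' Draws an anti-aliased bright ellipse (the fly body) at each frame's
#' position and heading on a dark background, plus Gaussian noise, so the
#' tracker can be validated against the generating trajectory.
#'
#' @param traj A [trajectory()] with positions in pixel units.
#' @param body_axes `c(semi_major, semi_minor)` of the body ellipse in
#'   pixels (default `c(8, 4)`); the major axis aligns with the heading.
#' @param image_shape `c(rows, cols)` of the frames.
#' @param noise_sd Gaussian noise SD in intensity units (default 0).
#' @param body_intensity Peak body intensity (default 1).
#' @param seed Integer seed for the noise.
#' @return A 3D array `[rows, cols, frames]`.
#' @export
simulate_fly_video <- function(traj, body_axes = c(8, 4), image_shape,
                               noise_sd = 0, body_intensity = 1, seed = 1) {
  stopifnot(inherits(traj, "fly_trajectory"), length(image_shape) == 2)
  if (2 * max(body_axes) > min(image_shape))
    stop("fly body larger than the frame")
  if (any(traj$x < 1 + body_axes[1]) || any(traj$x > image_shape[2] - body_axes[1]) ||
      any(traj$y < 1 + body_axes[1]) || any(traj$y > image_shape[1] - body_axes[1]))
    stop("trajectory does not fit inside the image")
  set.seed(as.integer(seed))
  n <- nrow(traj)
  out <- array(0, c(image_shape, n))
  ss <- 4; off <- ((seq_len(ss) - 0.5) / ss - 0.5)
  for (k in seq_len(n)) {
    cx <- traj$x[k]; cy <- traj$y[k]
    th <- traj$heading[k] * pi / 180
    r0 <- max(1, floor(cy - body_axes[1] - 1)); r1 <- min(image_shape[1], ceiling(cy + body_axes[1] + 1))
    c0 <- max(1, floor(cx - body_axes[1] - 1)); c1 <- min(image_shape[2], ceiling(cx + body_axes[1] + 1))
    f <- matrix(0, image_shape[1], image_shape[2])
    for (r in r0:r1) for (cc in c0:c1) {
      ys <- r + off - cy; xs <- cc + off - cx
      # rotate into body frame; image y increases downward, so flip sign
      u <- outer(xs, rep(1, ss)) * cos(th) + outer(rep(1, ss), -ys) * sin(th)
      v <- -outer(xs, rep(1, ss)) * sin(th) + outer(rep(1, ss), -ys) * cos(th)
      f[r, cc] <- body_intensity * mean((u / body_axes[1])^2 + (v / body_axes[2])^2 <= 1)
    }
    if (noise_sd > 0) f <- f + matrix(rnorm(length(f), 0, noise_sd),
                                      image_shape[1], image_shape[2])
    out[, , k] <- f
  }
  out
}
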