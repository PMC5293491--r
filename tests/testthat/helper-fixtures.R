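# shared fixture builders for the test suite

make_series <- function(time, fv = NULL, av = NULL, frame_rate = NULL) {
  out <- data.frame(time = time)
  if (!is.null(fv)) { out$forward_velocity <- fv; out$fv_valid <- TRUE }
  if (!is.null(av)) {
    out$angular_velocity <- av
    out$angular_speed <- abs(av)
    out$av_valid <- TRUE
  }
  if (is.null(frame_rate)) frame_rate <- 1 / mean(diff(time))
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("kinematic_series", "data.frame")
  out
}

# trial table with given per-trial mean velocities / angular speeds
make_trials <- function(v, a = rep(0, length(v)), fly_id = NULL,
                        trial_index = NULL) {
  n <- length(v)
  data.frame(fly_id = if (is.null(fly_id)) sprintf("f%02d", seq_len(n)) else fly_id,
             group = "test", trial_index = if (is.null(trial_index)) seq_len(n) else trial_index,
             mean_forward_velocity = v, mean_angular_speed = a,
             mean_signed_angular_velocity = a,
             stringsAsFactors = FALSE)
}

# independent Mann-Whitney oracle: enumerate every assignment of the pooled
# values to groups, computing U by direct pairwise win/tie counting
mw_enumeration_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); N <- length(pooled)
  u_direct <- function(xa, xb)
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  u_obs <- u_direct(a, b)
  mu <- na * (N - na) / 2
  idx <- utils::combn(N, na)
  us <- apply(idx, 2, function(ii) u_direct(pooled[ii], pooled[-ii]))
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# small noise-free calcium movie (short, for motion-correction tests)
small_calcium_sim <- function(seed, noise_sd = 0, jitter_max = 3,
                              n_epochs = 1) {
  p <- calcium_sim_params(movie_shape = c(48, 64),
                          glomerulus_center = c(24, 32),
                          glomerulus_axes = c(6, 9),
                          noise_sd = noise_sd, jitter_max = jitter_max,
                          pre_time = 2, epoch_duration = 2, inter_epoch = 3,
                          response_amplitude = c(loom_dark = 1),
                          seed = seed)
  schedule <- data.frame(stimulus_id = rep("loom_dark", n_epochs))
  simulate_calcium_movie(p, schedule)
}
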