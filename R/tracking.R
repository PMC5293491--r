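#' Track fly centroid and orientation by image moments
#'
#' A moment-based tracker for single-fly videos: per frame the bright
#' fly-like blob is segmented by thresholding and connected-component
#' labeling, the centroid is taken from intensity-weighted first moments and
#' the body orientation from the principal axis of the second central
#' moments. The 180-degree axis ambiguity is resolved by aligning the
#' orientation with the smoothed displacement direction. Frames with zero
#' or multiple qualifying blobs are flagged as gaps, not errors.
#'
#' Coordinates follow the math convention used by the trajectory type:
#' `x` = column, `y` = row, heading measured counterclockwise from +x with
#' the image row axis pointing down (so heading 90 degrees points toward
#' smaller row indices).
#'
#' @param video 3D array `[rows, cols, frames]`.
#' @param frame_rate Frames per second.
#' @param threshold Segmentation intensity threshold (default half the
#'   maximum intensity of the stack).
#' @param min_area Minimum blob area in pixels (default 10).
#' @return A data.frame with columns `frame`, `time`, `x`, `y`,
#'   `heading` (degrees in `[0, 360)`) and `valid` (FALSE for flagged gaps);
#'   attribute `frame_rate`.
#' @export
track_centroid_orientation <- function(video, frame_rate,
                                       threshold = NULL, min_area = 10) {
  stopifnot(is.array(video), length(dim(video)) == 3, frame_rate > 0)
  if (is.null(threshold)) threshold <- max(video) / 2
  n <- dim(video)[3]
  x <- y <- axis_deg <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (k in seq_len(n)) {
    f <- video[, , k]
    bw <- f > threshold
    if (!any(bw)) next
    lab <- EBImage::bwlabel(bw)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    if (length(keep) != 1) next       # zero or multiple qualifying blobs
    sel <- lab == keep
    w <- f * sel
    tw <- sum(w)
    cols <- matrix(seq_len(ncol(f)), nrow(f), ncol(f), byrow = TRUE)
    rows <- matrix(seq_len(nrow(f)), nrow(f), ncol(f))
    cx <- sum(w * cols) / tw
    cy <- sum(w * rows) / tw
    # central second moments in math coordinates (y up = -row)
    dx <- cols - cx; dy <- -(rows - cy)
    mu20 <- sum(w * dx * dx) / tw
    mu02 <- sum(w * dy * dy) / tw
    mu11 <- sum(w * dx * dy) / tw
    x[k] <- cx; y[k] <- cy
    axis_deg[k] <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    valid[k] <- TRUE
  }
  # resolve the 180-degree ambiguity with the smoothed displacement direction
  heading <- axis_deg %% 180
  vi <- which(valid)
  if (length(vi) >= 3) {
    xs <- x; ys <- y
    xs[vi] <- moving_average(x[vi], min(5, length(vi) - (1 - length(vi) %% 2)))
    ys[vi] <- moving_average(y[vi], min(5, length(vi) - (1 - length(vi) %% 2)))
    for (j in seq_along(vi)) {
      k <- vi[j]
      k0 <- vi[max(1, j - 1)]; k1 <- vi[min(length(vi), j + 1)]
      disp <- atan2(-(ys[k1] - ys[k0]), xs[k1] - xs[k0]) * 180 / pi
      d <- (disp - heading[k]) %% 360
      if (d > 90 && d < 270) heading[k] <- (heading[k] + 180) %% 360
    }
  }
  out <- data.frame(frame = seq_len(n), time = (seq_len(n) - 1) / frame_rate,
                    x = x, y = y, heading = heading %% 360, valid = valid)
  attr(out, "frame_rate") <- frame_rate
  out
}

#' Convert tracker output to a trajectory
#'
#' Keeps the leading run of valid frames (trajectories require a gap-free
#' uniform time base); errors if fewer than `min_frames` valid frames open
#' the recording.
#'
#' @param tracked Output of [track_centroid_orientation()].
#' @param min_frames Minimum usable length (default 10).
#' @return A [trajectory()] in pixel units.
#' @export
tracked_to_trajectory <- function(tracked, min_frames = 10) {
  ok <- tracked$valid
  run <- which(!ok)[1]
  n <- if (is.na(run)) nrow(tracked) else run - 1
  if (n < min_frames) stop("fewer than ", min_frames, " leading valid frames")
  trajectory(tracked$time[seq_len(n)], tracked$x[seq_len(n)],
             tracked$y[seq_len(n)], tracked$heading[seq_len(n)],
             frame_rate = attr(tracked, "frame_rate"))
}
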