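#' Construct a calcium movie
#'
#' A two-photon recording: a stack of frames with the acquisition frame rate
#' and the timing of the visual-stimulus epochs. Frames are stored as a 3D
#' array `[row, col, frame]`.
#'
#' @param frames 3D numeric array `[rows, cols, n_frames]`.
#' @param frame_rate Acquisition rate in Hz (nominal 10).
#' @param epochs A data.frame of stimulus epochs with columns `stimulus_id`,
#'   `start`, `stop` (seconds) and, for looming stimuli, `expansion_stop`.
#' @param fly_id,stimulus_id Optional labels.
#' @return An object of class `calcium_movie`.
#' @export
calcium_movie <- function(frames, frame_rate, epochs = NULL,
                          fly_id = NA, stimulus_id = NA) {
  stopifnot(is.array(frames), length(dim(frames)) == 3, frame_rate > 0)
  if (!is.null(epochs)) {
    stopifnot(is.data.frame(epochs), all(c("start", "stop") %in% names(epochs)))
    if (any(epochs$stop <= epochs$start)) stop("epochs must have stop > start")
  }
  structure(list(frames = frames, frame_rate = frame_rate, epochs = epochs,
                 fly_id = fly_id, stimulus_id = stimulus_id),
            class = "calcium_movie")
}

#' Elliptical region-of-interest mask
#'
#' Convenience generator for glomerulus-shaped ROIs on synthetic movies
#' (real ROIs are hand-drawn and supplied as data).
#'
#' @param shape `c(rows, cols)` of the frame.
#' @param center `c(row, col)` of the ellipse center (pixels).
#' @param axes `c(semi_row, semi_col)` semi-axes in pixels.
#' @return A logical matrix mask with at least one pixel set.
#' @export
ellipse_roi <- function(shape, center, axes) {
  stopifnot(length(shape) == 2, length(center) == 2, length(axes) == 2,
            all(axes > 0))
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  m <- ((rows - center[1]) / axes[1])^2 + ((cols - center[2]) / axes[2])^2 <= 1
  if (!any(m)) stop("empty ROI mask")
  m
}

# integer-translate a matrix by (dy, dx), filling vacated pixels with `fill`
shift_frame <- function(f, dy, dx, fill) {
  nr <- nrow(f); nc <- ncol(f)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy; src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- f[src_r[ok_r], src_c[ok_c]]
  out
}

# cross-correlation of frame against reference over all circular shifts (FFT)
xcorr_surface <- function(frame, reference) {
  Re(fft(fft(frame) * Conj(fft(reference)), inverse = TRUE))
}

#' Rigid motion compensation by cross-correlation
#'
#' For every frame, finds the integer translation that maximizes the
#' cross-correlation with a reference image and undoes it. Shifts are
#' restricted to a search radius; ties are broken by smallest shift
#' magnitude, then row-major order. Pixels vacated by the correction are
#' filled with the median of the frame's border pixels. Frames whose best
#' correlation sits on the boundary of the search radius are flagged (the
#' true shift may exceed the allowed range) but still corrected.
#'
#' @param movie A [calcium_movie()].
#' @param reference Reference image (matrix); default is the mean of the
#'   first 30 frames (or all frames if fewer).
#' @param max_shift Search radius in pixels (default 10).
#' @return A list: `movie` (corrected [calcium_movie()]) and `shifts`
#'   (data.frame `frame`, `dy`, `dx`, `flagged`). `dy`/`dx` are the detected
#'   displacements of each frame relative to the reference.
#' @export
motion_correct <- function(movie, reference = NULL, max_shift = 10) {
  stopifnot(inherits(movie, "calcium_movie"), max_shift >= 0)
  d <- dim(movie$frames)
  nr <- d[1]; nc <- d[2]; nf <- d[3]
  if (is.null(reference)) {
    k <- min(30, nf)
    reference <- apply(movie$frames[, , seq_len(k), drop = FALSE], c(1, 2), mean)
  }
  if (!all(dim(reference) == c(nr, nc)))
    stop("reference dimensions must match the frames")
  # enumerate allowed shifts once, ordered by magnitude then row-major
  dys <- rep(-max_shift:max_shift, times = 2 * max_shift + 1)
  dxs <- rep(-max_shift:max_shift, each = 2 * max_shift + 1)
  ord <- order(dys^2 + dxs^2, dys, dxs)
  dys <- dys[ord]; dxs <- dxs[ord]
  fref <- Conj(fft(reference - mean(reference)))
  corrected <- movie$frames
  shifts <- data.frame(frame = seq_len(nf), dy = 0L, dx = 0L, flagged = FALSE)
  for (k in seq_len(nf)) {
    f <- movie$frames[, , k]
    cc <- Re(fft(fft(f - mean(f)) * fref, inverse = TRUE))
    # surface index (i, j) corresponds to circular shift (i-1, j-1)
    vals <- cc[cbind(dys %% nr + 1, dxs %% nc + 1)]
    best <- which.max(vals)       # first max in magnitude/row-major order
    dy <- dys[best]; dx <- dxs[best]
    flagged <- max_shift > 0 && (abs(dy) == max_shift || abs(dx) == max_shift)
    border <- c(f[1, ], f[nr, ], f[, 1], f[, nc])
    corrected[, , k] <- shift_frame(f, -dy, -dx, fill = median(border))
    shifts$dy[k] <- dy; shifts$dx[k] <- dx; shifts$flagged[k] <- flagged
  }
  out <- movie
  out$frames <- corrected
  list(movie = out, shifts = shifts)
}

#' Extract an ROI fluorescence trace
#'
#' Per-frame arithmetic mean of the pixel intensities under the mask.
#'
#' @param movie A [calcium_movie()].
#' @param roi Logical matrix matching the frame dimensions.
#' @return Numeric vector `F` of per-frame mean fluorescence.
#' @export
extract_trace <- function(movie, roi) {
  stopifnot(inherits(movie, "calcium_movie"), is.matrix(roi))
  d <- dim(movie$frames)
  if (!all(dim(roi) == d[1:2])) stop("ROI dimensions must match the frames")
  idx <- which(roi)
  if (!length(idx)) stop("empty ROI mask")
  apply(movie$frames, 3, function(f) mean(f[idx]))
}

#' Sliding-percentile baseline
#'
#' Baseline fluorescence F0 at each frame is a low percentile (default the
#' 10th) of the fluorescence within a sliding window (default 300 frames)
#' centered on that frame; windows are truncated at the edges of the series.
#'
#' @param F Fluorescence series.
#' @param window Window length in frames (default 300).
#' @param percentile Percentile in (0, 100) (default 10).
#' @return Numeric vector `F0` of the same length as `F`.
#' @export
sliding_baseline <- function(F, window = 300, percentile = 10) {
  n <- length(F)
  if (n < 2) stop("series must have at least 2 frames")
  if (window < 1) stop("window must be positive")
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    unname(quantile(F[lo:hi], percentile / 100, type = 7))
  }, numeric(1))
}

#' Fractional fluorescence change
#'
#' Computes dF/F = (F - F0) / F0 element-wise. When the raw fluorescence
#' minimum is at or below zero, a small positive offset is added to both F
#' and F0 before the ratio so the denominator stays positive (synthetic or
#' background-subtracted data can dip to zero; photon-count data rarely
#' does).
#'
#' @param F Fluorescence series.
#' @param F0 Baseline series from [sliding_baseline()], same length.
#' @param floor_offset Offset added when `min(F) <= 0` (default 1 intensity
#'   unit).
#' @return dF/F series.
#' @export
compute_dff <- function(F, F0, floor_offset = 1) {
  stopifnot(length(F) == length(F0))
  if (min(F) <= 0) { F <- F + floor_offset; F0 <- F0 + floor_offset }
  bad <- which(F0 <= 0)
  if (length(bad))
    stop("non-positive baseline after flooring at frames: ",
         paste(head(bad, 5), collapse = ", "))
  (F - F0) / F0
}

#' Normalize dF/F traces per fly
#'
#' For combining responses across animals, each fly's dF/F traces are
#' divided by the 98th percentile of the pooled dF/F of that fly across all
#' visual stimuli within one experiment.
#'
#' @param traces A named list of dF/F numeric vectors, one per stimulus, all
#'   from the same fly.
#' @param percentile Pooled percentile used as the normalizer (default 98).
#' @return A list with `traces` (normalized list) and
#'   `normalization_constant`.
#' @export
normalize_per_fly <- function(traces, percentile = 98) {
  stopifnot(is.list(traces), length(traces) >= 1)
  pooled <- unlist(traces, use.names = FALSE)
  norm <- unname(quantile(pooled, percentile / 100, type = 7))
  if (!(norm > 0)) stop("non-positive normalization constant")
  list(traces = lapply(traces, function(x) x / norm),
       normalization_constant = norm)
}

#' Mean dF/F in a response window
#'
#' Mean of the dF/F trace either in a symmetric window around the time the
#' looming stimulus stops expanding (where the response peaks) or over the
#' whole stimulus epoch. Windows are half-open:
#' `[stop - half_width, stop + half_width)` and `[start, stop)`.
#'
#' @param dff dF/F series.
#' @param frame_rate Frames per second of the trace.
#' @param epoch One row of an epochs data.frame (with `start`, `stop`, and
#'   `expansion_stop` for looming epochs).
#' @param window_kind `"around_expansion_stop"` (default) or `"whole_epoch"`.
#' @param half_width Half-width of the peak window in seconds (default 2).
#' @return Scalar mean dF/F.
#' @export
response_window_mean <- function(dff, frame_rate, epoch,
                                 window_kind = c("around_expansion_stop", "whole_epoch"),
                                 half_width = 2) {
  window_kind <- match.arg(window_kind)
  t <- (seq_along(dff) - 1) / frame_rate
  if (window_kind == "around_expansion_stop") {
    stop_t <- epoch$expansion_stop
    if (is.null(stop_t) || is.na(stop_t))
      stop("epoch has no expansion_stop marker")
    sel <- t >= stop_t - half_width & t < stop_t + half_width
  } else {
    sel <- t >= epoch$start & t < epoch$stop
  }
  if (!any(sel)) stop("response window lies outside the trace")
  mean(dff[sel])
}

#' Group response summary across flies
#'
#' Responses are summarized hierarchically: each fly contributes the mean of
#' its repeated presentations, and the group statistic is the mean +/- SEM
#' over flies.
#'
#' @param per_fly_values A list (one element per fly) of numeric vectors of
#'   per-repetition response values, or a numeric vector of per-fly means.
#' @return A list with `mean`, `sem` (sample SD over flies / sqrt(n)) and
#'   `n` (number of flies).
#' @export
group_response <- function(per_fly_values) {
  if (is.list(per_fly_values))
    per_fly_values <- vapply(per_fly_values, mean, numeric(1))
  n <- length(per_fly_values)
  if (n < 2) stop("SEM requires at least 2 flies")
  list(mean = mean(per_fly_values), sem = sd(per_fly_values) / sqrt(n), n = n)
}
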