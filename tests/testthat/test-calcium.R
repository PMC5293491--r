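test_that("motion correction recovers planted rigid shifts", {
  sim <- small_calcium_sim(seed = 31, noise_sd = 0, jitter_max = 0)
  ref <- sim$movie$frames[, , 1]

  # a constant movie yields all-zero shifts
  mc0 <- motion_correct(sim$movie, reference = ref, max_shift = 5)
  expect_true(all(mc0$shifts$dy == 0) && all(mc0$shifts$dx == 0))
  expect_false(any(mc0$shifts$flagged))

  # a planted (3, -2) translation is recovered and undone
  shifted <- sim$movie
  shifted$frames[, , 2] <- lcpipe:::shift_frame(ref, 3, -2, fill = 20)
  mc <- motion_correct(shifted, reference = ref, max_shift = 5)
  expect_equal(c(mc$shifts$dy[2], mc$shifts$dx[2]), c(3, -2))
  # corrected interior matches the reference
  expect_equal(mc$movie$frames[10:40, 10:55, 2], ref[10:40, 10:55])

  # translation equivariance: pre-shifting a frame by (a, b) moves its
  # recovered shift by exactly (a, b)
  again <- shifted
  again$frames[, , 2] <- lcpipe:::shift_frame(shifted$frames[, , 2], 1, 2,
                                              fill = 20)
  mc2 <- motion_correct(again, reference = ref, max_shift = 8)
  expect_equal(c(mc2$shifts$dy[2], mc2$shifts$dx[2]), c(3 + 1, -2 + 2))

  expect_error(motion_correct(sim$movie, reference = ref[1:10, 1:10]),
               "dimensions")
})

test_that("recovered shifts match an exhaustive-search oracle", {
  # independent oracle: direct overlap correlation at every candidate shift
  oracle_shift <- function(frame, ref, max_shift) {
    best <- c(0, 0); best_v <- -Inf
    nr <- nrow(ref); nc <- ncol(ref)
    for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
      rs <- max(1, 1 + dy):min(nr, nr + dy)
      cs <- max(1, 1 + dx):min(nc, nc + dx)
      a <- frame[rs, cs]; b <- ref[rs - dy, cs - dx]
      v <- sum((a - mean(a)) * (b - mean(b)))
      if (v > best_v) { best_v <- v; best <- c(dy, dx) }
    }
    best
  }
  sim <- small_calcium_sim(seed = 32, noise_sd = 0, jitter_max = 4)
  ref <- matrix(20, 48, 64); ref[sim$ground_truth$mask] <- 100
  mc <- motion_correct(sim$movie, reference = ref, max_shift = 6)
  gt <- sim$ground_truth$shifts
  expect_equal(mc$shifts$dy, gt$dy)
  expect_equal(mc$shifts$dx, gt$dx)
  for (k in seq(1, dim(sim$movie$frames)[3], by = 13)) {
    o <- oracle_shift(sim$movie$frames[, , k], ref, 6)
    expect_equal(c(mc$shifts$dy[k], mc$shifts$dx[k]), o)
  }
})

test_that("trace extraction is the mean under the mask and is linear", {
  f <- array(0, c(8, 8, 3))
  f[, , 1] <- 2; f[, , 2] <- 5; f[, , 3] <- 7
  mv <- calcium_movie(f, frame_rate = 10)
  roi <- matrix(FALSE, 8, 8); roi[3:5, 3:5] <- TRUE
  expect_equal(extract_trace(mv, roi), c(2, 5, 7))
  single <- matrix(FALSE, 8, 8); single[4, 4] <- TRUE
  f[4, 4, ] <- c(9, 9, 9)
  mv2 <- calcium_movie(f, frame_rate = 10)
  expect_equal(extract_trace(mv2, single), c(9, 9, 9))
  # union of two disjoint equal-size masks averages the two traces
  m1 <- matrix(FALSE, 8, 8); m1[1:2, 1:2] <- TRUE
  m2 <- matrix(FALSE, 8, 8); m2[7:8, 7:8] <- TRUE
  set.seed(1); mv3 <- calcium_movie(array(rnorm(8 * 8 * 4), c(8, 8, 4)), 10)
  expect_equal(extract_trace(mv3, m1 | m2),
               (extract_trace(mv3, m1) + extract_trace(mv3, m2)) / 2)
  expect_error(extract_trace(mv, matrix(FALSE, 8, 8)), "empty")
})

test_that("sliding baseline is the windowed percentile with truncated edges", {
  expect_equal(sliding_baseline(rep(3, 40), window = 10), rep(3, 40))
  # per-window sort oracle on a sawtooth
  F <- rep(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 12)
  F0 <- sliding_baseline(F, window = 30, percentile = 10)
  half <- 15
  oracle <- vapply(seq_along(F), function(i) {
    w <- F[max(1, i - half):min(length(F), i + half)]
    s <- sort(w); h <- (length(w) - 1) * 0.1 + 1
    lo <- floor(h); s[lo] + (h - lo) * (s[min(lo + 1, length(w))] - s[lo])
  }, numeric(1))
  expect_equal(F0, oracle)
  # a 10th-percentile baseline sits at or below F on >= 90% of frames
  set.seed(7)
  Fn <- 100 + rnorm(600)
  F0n <- sliding_baseline(Fn, window = 300, percentile = 10)
  expect_gte(mean(F0n <= Fn), 0.85)
  expect_error(sliding_baseline(5), "at least 2")
  expect_error(sliding_baseline(1:10, window = 0), "positive")
})

test_that("dF/F is the fractional change and floors non-positive input", {
  F <- c(10, 20, 30); F0 <- c(10, 10, 10)
  expect_equal(compute_dff(F, F), rep(0, 3))
  expect_equal(compute_dff(2 * F0, F0), rep(1, 3))
  # with the offset floor the denominator stays positive for zero-based data
  expect_equal(compute_dff(c(0, 1), c(0, 0)), c(0, 1))
  expect_error(compute_dff(c(0, 1), c(-5, -5)), "non-positive")
  expect_error(compute_dff(1:3, 1:2))
})

test_that("dF/F on a stationary noisy baseline has a small positive bias", {
  # the 10th-percentile baseline sits below the mean, so dF/F is biased
  # slightly positive; quantify that the median bias stays below 5%
  set.seed(12)
  F <- 100 + rnorm(900, 0, 2)
  dff <- compute_dff(F, sliding_baseline(F))
  expect_gt(median(dff), 0)
  expect_lt(median(dff), 0.05)
})

test_that("per-fly normalization pins the pooled 98th percentile at one", {
  set.seed(4)
  traces <- list(loom = runif(300, 0, 2), object = runif(200, 0, 1))
  nz <- normalize_per_fly(traces)
  pooled <- unlist(nz$traces)
  expect_equal(unname(quantile(pooled, 0.98, type = 7)), 1)
  # scale invariance
  nz2 <- normalize_per_fly(lapply(traces, function(x) 3.7 * x))
  expect_equal(nz2$traces, nz$traces, tolerance = 1e-12)
  # idempotence
  nz3 <- normalize_per_fly(nz$traces)
  expect_equal(nz3$traces, nz$traces, tolerance = 1e-12)
  expect_equal(nz3$normalization_constant, 1, tolerance = 1e-12)
  expect_error(normalize_per_fly(list(a = c(-1, -2))), "non-positive")
})

test_that("response windows average the documented frame spans", {
  ep <- data.frame(start = 2, stop = 6, expansion_stop = 6)
  dff <- rep(0.5, 100)
  expect_equal(response_window_mean(dff, 10, ep), 0.5)
  expect_equal(response_window_mean(dff, 10, ep, "whole_epoch"), 0.5)
  # half-open [stop - 2, stop + 2) at 10 Hz covers exactly 40 frames
  marked <- seq_along(dff) %in% which((seq_along(dff) - 1) / 10 >= 4 &
                                        (seq_along(dff) - 1) / 10 < 8)
  expect_equal(sum(marked), 40)
  ind <- rep(0, 100); ind[marked] <- 1
  expect_equal(response_window_mean(ind, 10, ep), 1)
  # triangular transient centered on the expansion stop: the window mean
  # equals the closed-form triangle average
  t <- (0:99) / 10
  tri <- pmax(0, 1 - abs(t - 6) / 2)
  got <- response_window_mean(tri, 10, ep)
  expect_equal(got, mean(tri[t >= 4 & t < 8]))
  expect_equal(got, 0.5, tolerance = 0.02)   # continuous triangle average
  expect_error(response_window_mean(dff, 10, data.frame(start = 2, stop = 6)),
               "expansion_stop")
})

test_that("group responses average per-fly repetition means first", {
  expect_equal(group_response(c(0.2, 0.4))$mean, 0.3)
  expect_equal(group_response(rep(0.7, 5))$sem, 0)
  # unbalanced repetitions: per-fly-first differs from naive pooling
  reps <- list(flyA = c(0.2, 0.4), flyB = c(0.9, 0.8, 0.7, 0.6, 0.5))
  g <- group_response(reps)
  expect_equal(g$mean, mean(c(mean(reps$flyA), mean(reps$flyB))))
  expect_equal(g$mean, 0.5)                       # hand-computed
  expect_false(isTRUE(all.equal(g$mean, mean(unlist(reps)))))
  expect_equal(g$n, 2)
  expect_error(group_response(0.4), "2 flies")
})
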