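test_that("loom angular diameter follows the constant-approach closed form", {
  # independent re-statement of the closed form on a dense grid
  tt <- 10^seq(-2, 2, length.out = 2000)
  rv <- 0.55
  expected <- 2 * atan2(rv, tt) * 180 / pi
  expect_equal(loom_angular_diameter(tt, rv), expected, tolerance = 1e-12)
  expect_true(all(diff(loom_angular_diameter(tt, rv)) < 0))
  # symmetry point: t = r/v subtends 90 degrees
  expect_equal(loom_angular_diameter(0.55, 0.55), 90)
  # limit: very distant object subtends almost nothing
  expect_lt(loom_angular_diameter(1e6, 0.55), 1e-3)
  expect_error(loom_angular_diameter(-1, 0.55))
  expect_error(loom_angular_diameter(1, 0))
})

test_that("diameter inversion matches a bisection oracle on the monotone form", {
  rv <- 0.55
  bisect <- function(theta) {
    lo <- 1e-6; hi <- 1e4
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (loom_angular_diameter(mid, rv) > theta) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (theta in c(4.5, 20, 54, 90, 150)) {
    expect_equal(loom_time_to_collision(theta, rv), bisect(theta),
                 tolerance = 1e-8)
  }
})

test_that("loom sequence spans theta_min to theta_max with consistent timing", {
  seq_def <- generate_loom_sequence(loom_params(), display_geometry())
  expect_equal(seq_def$angular_diameter[1], 4.5)
  expect_equal(tail(seq_def$angular_diameter, 1), 54)
  expect_true(all(diff(seq_def$angular_diameter) >= 0))
  expect_equal(length(unique(seq_def$angular_diameter)), 35)
  expect_equal(length(seq_def$frames), length(seq_def$timestamps))
  # re-evaluating the closed form at each size's time-to-collision
  # reproduces the emitted diameter
  st <- seq_def$size_table
  expect_equal(loom_angular_diameter(st$time_to_collision, 0.55), st$diameter,
               tolerance = 1e-9)
  # presentation order: later sizes correspond to smaller time-to-collision
  expect_true(all(diff(st$time_to_collision) < 0))
  expect_true(all(diff(st$presentation_time) > 0))
  expect_equal(seq_def$epoch_markers$expansion_stop,
               st$presentation_time[nrow(st)])
  # all intensities within the display's gray range
  rng <- range(unlist(seq_def$frames))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 255)
})

test_that("two-size loom emits exactly the endpoints", {
  s <- generate_loom_sequence(loom_params(n_sizes = 2), display_geometry())
  expect_equal(sort(unique(s$angular_diameter)), c(4.5, 54))
})

test_that("a disk that does not fit the display is rejected by name", {
  expect_error(
    generate_loom_sequence(loom_params(theta_max = 80), display_geometry()),
    "80")
})

test_that("luminance matching conserves per-frame darkening exactly", {
  s <- generate_loom_sequence(loom_params(frame_rate = 20), display_geometry())
  lm1 <- luminance_match(s, seed = 7)
  lm2 <- luminance_match(s, seed = 7)
  expect_identical(lm1$frames, lm2$frames)   # deterministic given seed
  expect_equal(lm1$kind, "luminance_matched")
  final_mask <- which(s$frames[[length(s$frames)]] < 255)
  for (k in seq(1, length(s$frames), by = 17)) {
    f <- s$frames[[k]]; g <- lm1$frames[[k]]
    expect_equal(sum(g), sum(f))                       # total intensity
    expect_equal(sum(g < 255), sum(f < 255))           # dark-pixel count
    expect_equal(sort(g[g < 255]), sort(f[f < 255]))   # intensity histogram
    expect_true(all(which(g < 255) %in% final_mask))   # inside final disk
  }
  # frames with zero dark pixels would pass through unchanged
  blank <- s
  blank$frames <- list(matrix(255, 32, 96))
  blank$angular_diameter <- blank$angular_diameter[1]
  blank$timestamps <- 0
  expect_identical(luminance_match(blank, 1)$frames[[1]], blank$frames[[1]])
  # only dark looms can be luminance matched
  bright <- s; bright$kind <- "loom_bright"
  expect_error(luminance_match(bright, 1), "dark loom")
})

test_that("object motion translates at constant speed over the stated span", {
  # the published traversal: -18 to +108 degrees at 22.5 deg/s
  o <- generate_object_motion(9, 9, 22.5, -18, 108, 0)
  expect_equal(o$duration, abs(108 - (-18)) / 22.5)
  expect_equal(o$object_azimuth[1], -18)
  expect_equal(tail(o$object_azimuth, 1), 108)
  steps <- diff(o$object_azimuth[-length(o$object_azimuth)])
  expect_equal(steps, rep(22.5 / 60, length(steps)))
  rng <- range(unlist(o$frames))
  expect_gte(rng[1], 0); expect_lte(rng[2], 255)

  # speed = full extent per second at 2 Hz puts the object at start,
  # midpoint, end on successive frames
  o3 <- generate_object_motion(9, 9, 40, 0, 40, 0, frame_rate = 2)
  expect_equal(o3$object_azimuth, c(0, 20, 40))

  expect_error(generate_object_motion(9, 80, 22.5, -18, 108, 0), "taller")
  expect_error(generate_object_motion(9, 9, 22.5, 10, 10, 0))
})

test_that("randomized block schedule permutes every stimulus once per block", {
  ids <- c("loom_dark", "loom_bright", "lum_match", "object")
  sch <- randomized_block_schedule(ids, 3, seed = 4)
  expect_equal(nrow(sch), 12)
  for (b in 1:3)
    expect_setequal(sch$stimulus_id[sch$block == b], ids)
  expect_identical(sch, randomized_block_schedule(ids, 3, seed = 4))
  # distinct seeds produce distinct orders essentially always (4! = 24
  # equally likely block orders)
  orders <- vapply(1:20, function(s)
    paste(randomized_block_schedule(ids, 1, seed = s)$stimulus_id,
          collapse = ""), character(1))
  expect_gt(length(unique(orders)), 10)
  expect_error(randomized_block_schedule(c("a", "a"), 2, 1), "distinct")
  expect_error(randomized_block_schedule(character(0), 2, 1))
  one <- randomized_block_schedule("only", 3, 1)
  expect_equal(one$stimulus_id, rep("only", 3))
})
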