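test_that("thresholds come from control percentiles with the linear rule", {
  # degenerate distribution: every cut collapses to the shared value
  deg <- compute_thresholds(make_trials(rep(7, 30), rep(7, 30)))
  expect_equal(deg$forward_cut, 7)
  expect_equal(deg$backward_cut, 7)
  expect_equal(deg$turn_cut, 7)

  # brute-force sort-and-interpolate quantile oracle on 1..100
  v <- sample(1:100)
  th <- compute_thresholds(make_trials(v, v))
  interp <- function(x, p) {
    s <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h); s[lo] + (h - lo) * (s[min(lo + 1, length(x))] - s[lo])
  }
  expect_equal(th$forward_cut, interp(v, 0.977))
  expect_equal(th$backward_cut, interp(v, 0.023))
  expect_equal(th$turn_cut, interp(v, 0.977))

  # the 97.7/2.3 percentiles of a standard normal sit near +/- 2 SD
  set.seed(1)
  z <- rnorm(2e5)
  thn <- compute_thresholds(make_trials(z, abs(z)))
  expect_equal(thn$forward_cut, 2.0, tolerance = 0.02)
  expect_equal(thn$backward_cut, -2.0, tolerance = 0.02)

  expect_error(compute_thresholds(make_trials(rnorm(10))), "20")
})

test_that("trial classification uses strict inequalities and independent flags", {
  th <- structure(list(forward_cut = 5, backward_cut = -5, turn_cut = 300),
                  class = "threshold_set")
  tr <- make_trials(c(7, -6, 5, -5, 0), c(100, 350, 300, 299, 301))
  sc <- classify_trials(tr, th)
  expect_equal(sc$forward, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(sc$backward, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sc$turn, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_error(classify_trials(data.frame(x = 1), th))
})

test_that("independent control halves flag each tail near the nominal rate", {
  set.seed(8)
  n <- 4000
  flagged_fw <- flagged_bw <- 0
  for (i in 1:4) {
    a <- make_trials(rnorm(n), abs(rnorm(n)))
    b <- make_trials(rnorm(n), abs(rnorm(n)))
    sc <- classify_trials(b, compute_thresholds(a))
    flagged_fw <- flagged_fw + sum(sc$forward)
    flagged_bw <- flagged_bw + sum(sc$backward)
  }
  expect_lt(abs(flagged_fw / (4 * n) - 0.023), 0.006)
  expect_lt(abs(flagged_bw / (4 * n) - 0.023), 0.006)
})

test_that("penetrance counts trials or flies with exact intervals attached", {
  tr <- make_trials(rep(0, 10))
  tr$backward <- c(rep(TRUE, 3), rep(FALSE, 7))
  p <- penetrance(tr, "backward")
  expect_equal(p$fraction, 0.3)
  expect_equal(p$numerator, 3); expect_equal(p$denominator, 10)
  expect_true(p$ci_low <= p$fraction && p$fraction <= p$ci_high)
  expect_equal(unname(unlist(clopper_pearson_ci(3, 10))),
               c(p$ci_low, p$ci_high))

  # a fly with one flagged trial of five counts once under unit = flies
  tr2 <- make_trials(rep(0, 10), fly_id = rep(c("A", "B"), each = 5),
                     trial_index = rep(1:5, 2))
  tr2$jump <- c(TRUE, rep(FALSE, 9))
  pf <- penetrance(tr2, "jump", unit = "flies")
  expect_equal(pf$numerator, 1); expect_equal(pf$denominator, 2)
  expect_equal(pf$fraction, 0.5)

  # invariance to trial order and fly relabeling for unit = trials
  perm <- sample(nrow(tr))
  expect_equal(penetrance(tr[perm, ], "backward")$fraction, p$fraction)
  expect_error(penetrance(tr, "grooming"), "unknown behavior")

  # binomial sampling oracle: estimated fraction approaches the flag
  # probability and the exact interval covers it
  set.seed(21)
  for (prob in c(0.2, 0.7)) {
    big <- make_trials(rep(0, 3000))
    big$turn <- runif(3000) < prob
    pb <- penetrance(big, "turn")
    expect_lt(abs(pb$fraction - prob), 0.03)
    expect_lt(pb$ci_high - pb$ci_low, 0.04)   # exact interval is tight at n = 3000
  }
})

test_that("penetrance aggregates pool correctly across strata", {
  tr <- make_trials(rep(0, 15), fly_id = rep(c("A", "B", "C"), each = 5),
                    trial_index = rep(1:5, 3))
  set.seed(2)
  tr$jump <- runif(15) < 0.4
  one <- aggregate_penetrance(tr[tr$fly_id == "A", ], "jump", by = "per_fly")
  expect_equal(nrow(one), 1)
  expect_equal(one$denominator, 5)
  per_trial <- aggregate_penetrance(tr, "jump", by = "per_trial_index")
  pooled <- aggregate_penetrance(tr, "jump", by = "pooled")
  expect_equal(sum(per_trial$numerator), pooled$numerator)
  expect_equal(sum(per_trial$denominator), pooled$denominator)
  expect_error(aggregate_penetrance(tr[, -1], "jump", by = "per_fly"))
})

test_that("lateralized trials mirror signed turning onto the right side", {
  tr <- make_trials(rep(0, 4), a = c(30, -10, 25, 40))
  tr$mean_signed_angular_velocity <- c(30, -10, 25, 40)
  tr$mean_angular_speed <- abs(tr$mean_signed_angular_velocity)
  tr$labeling <- c("unilateral_left", "unilateral_left",
                   "unilateral_right", "bilateral")
  m <- mirror_lateralized(tr)
  expect_equal(m$mean_signed_angular_velocity, c(-30, 10, 25, 40))
  expect_equal(m$labeling[1:2], rep("unilateral_right", 2))
  expect_equal(m$labeling[3:4], c("unilateral_right", "bilateral"))
  # unsigned quantities and trial count conserved
  expect_equal(m$mean_angular_speed, tr$mean_angular_speed)
  expect_equal(nrow(m), nrow(tr))
  # involution on the signed field: flipping the mirrored rows back
  # restores the original magnitudes
  expect_equal(abs(m$mean_signed_angular_velocity),
               abs(tr$mean_signed_angular_velocity))
  # hand-computed combined mean on the 4-trial toy set:
  # (-30 + 10 + 25 + 40) / 4
  uni <- m[m$labeling == "unilateral_right", ]
  expect_equal(mean(m$mean_signed_angular_velocity), 45 / 4)
  expect_equal(mean(uni$mean_signed_angular_velocity), 5 / 3)
  tr$labeling[1] <- "unknown"
  expect_error(mirror_lateralized(tr), "unknown")
})

test_that("box-plot summaries follow the declared conventions", {
  b <- boxplot_summary(1:5)
  expect_equal(b$median, 3)
  eq <- boxplot_summary(rep(4, 10))
  expect_equal(eq$q1, eq$q3)
  expect_equal(length(eq$outliers), 0)
  set.seed(9)
  z <- rnorm(2e5)
  bn <- boxplot_summary(z)
  # whiskers include 95% of the data: near +/- 1.96 for a standard normal
  expect_equal(bn$whisker_low, -1.96, tolerance = 0.03)
  expect_equal(bn$whisker_high, 1.96, tolerance = 0.03)
  expect_equal(bn$notch_high - bn$median, 1.57 * (bn$q3 - bn$q1) / sqrt(bn$n))
  expect_error(boxplot_summary(1:4), "5")
})
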