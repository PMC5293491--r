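#' Control-percentile classification thresholds
#'
#' Derives the behavioral classification cutoffs from control-group trials:
#' a trial is scored as a phenotype only when its windowed mean kinematics
#' fall beyond the stated percentiles of the control distribution. The
#' defaults (97.7th / 2.3rd) roughly correspond to two standard deviations
#' from the mean of a normal distribution; percentiles are used because the
#' behavioral distributions are non-normal. Percentiles use linear
#' interpolation between closest order statistics.
#'
#' @param control_trials A data.frame of control trials with columns
#'   `mean_forward_velocity` and `mean_angular_speed`.
#' @param percentile_upper,percentile_lower Upper/lower percentiles
#'   (defaults 97.7 and 2.3).
#' @param min_n Minimum number of control trials required (default 20).
#' @return An object of class `threshold_set`: `forward_cut`, `backward_cut`,
#'   `turn_cut`, `control_n`, the percentiles and the quantile rule.
#' @export
compute_thresholds <- function(control_trials, percentile_upper = 97.7,
                               percentile_lower = 2.3, min_n = 20) {
  stopifnot(is.data.frame(control_trials))
  n <- nrow(control_trials)
  if (n < min_n)
    stop(sprintf("need at least %d control trials, got %d", min_n, n))
  v <- control_trials$mean_forward_velocity
  a <- control_trials$mean_angular_speed
  if (is.null(v) || is.null(a))
    stop("control trials must carry mean_forward_velocity and mean_angular_speed")
  structure(list(
    forward_cut = unname(quantile(v, percentile_upper / 100, type = 7, na.rm = TRUE)),
    backward_cut = unname(quantile(v, percentile_lower / 100, type = 7, na.rm = TRUE)),
    turn_cut = unname(quantile(a, percentile_upper / 100, type = 7, na.rm = TRUE)),
    control_n = n,
    percentile_upper = percentile_upper,
    percentile_lower = percentile_lower,
    quantile_rule = "linear interpolation (type 7)"),
    class = "threshold_set")
}

#' Classify trials against control thresholds
#'
#' Converts windowed mean kinematics into logical behavior flags:
#' forward walking when mean velocity exceeds the upper cut, backward walking
#' when it falls below the lower cut, turning when mean angular speed exceeds
#' the turn cut. Inequalities are strict: a value exactly at a cut is within
#' the normal range. Manual jump/reach annotations pass through unchanged.
#'
#' @param trials A data.frame of trials with kinematic summary columns.
#' @param thresholds A [compute_thresholds()] result.
#' @return `trials` with added logical columns `forward`, `backward`, `turn`.
#' @export
classify_trials <- function(trials, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"), is.data.frame(trials))
  v <- trials$mean_forward_velocity
  a <- trials$mean_angular_speed
  if (is.null(v) || is.null(a))
    stop("locomotion scoring requires mean_forward_velocity and mean_angular_speed")
  trials$forward <- v > thresholds$forward_cut
  trials$backward <- v < thresholds$backward_cut
  trials$turn <- a > thresholds$turn_cut
  trials
}

#' Behavioral penetrance with exact binomial confidence interval
#'
#' Penetrance is the fraction of trials (or flies) of a group in which a
#' given behavior was observed. With `unit = "flies"`, a fly counts as
#' positive when at least one of its trials is flagged.
#'
#' @param trials A data.frame with a logical column named after `behavior`
#'   (`forward`, `backward`, `turn`, `jump`, or `reach`) and, for
#'   `unit = "flies"`, a `fly_id` column.
#' @param behavior Behavior label to score.
#' @param unit `"trials"` (default) or `"flies"`.
#' @param conf_level Confidence level for the Clopper-Pearson interval
#'   (default 0.95).
#' @return A one-row data.frame: `behavior`, `numerator`, `denominator`,
#'   `unit`, `fraction`, `ci_low`, `ci_high`, `ci_method`.
#' @export
penetrance <- function(trials, behavior, unit = c("trials", "flies"),
                       conf_level = 0.95) {
  unit <- match.arg(unit)
  if (!nrow(trials)) stop("empty trial list")
  flags <- trials[[behavior]]
  if (is.null(flags))
    stop(sprintf("unknown behavior '%s': no such column", behavior))
  flags <- as.logical(flags)
  if (unit == "flies") {
    if (is.null(trials$fly_id)) stop("unit = 'flies' requires fly_id")
    per_fly <- tapply(flags, trials$fly_id, function(x) any(x, na.rm = TRUE))
    k <- sum(per_fly); n <- length(per_fly)
  } else {
    k <- sum(flags, na.rm = TRUE); n <- sum(!is.na(flags))
  }
  ci <- clopper_pearson_ci(k, n, alpha = 1 - conf_level)
  data.frame(behavior = behavior, numerator = k, denominator = n,
             unit = unit, fraction = k / n,
             ci_low = ci[1], ci_high = ci[2],
             ci_method = "Clopper-Pearson", stringsAsFactors = FALSE)
}

#' Penetrance aggregated by stratum
#'
#' Reports penetrance pooled over all trials, per trial index (all flies of
#' the same trial number), or per fly (all trials of the same fly).
#'
#' @param trials Trial data.frame as for [penetrance()].
#' @param behavior Behavior label.
#' @param by `"pooled"`, `"per_trial_index"`, or `"per_fly"`.
#' @param conf_level Confidence level for the intervals.
#' @return A data.frame with one penetrance row per stratum (plus a `stratum`
#'   column for the stratified forms).
#' @export
aggregate_penetrance <- function(trials, behavior,
                                 by = c("pooled", "per_trial_index", "per_fly"),
                                 conf_level = 0.95) {
  by <- match.arg(by)
  if (by == "pooled")
    return(penetrance(trials, behavior, unit = "trials", conf_level = conf_level))
  key <- switch(by, per_trial_index = "trial_index", per_fly = "fly_id")
  if (is.null(trials[[key]]))
    stop(sprintf("aggregation '%s' requires column '%s'", by, key))
  strata <- split(trials, trials[[key]])
  out <- do.call(rbind, lapply(names(strata), function(s) {
    row <- penetrance(strata[[s]], behavior, unit = "trials",
                      conf_level = conf_level)
    cbind(stratum = s, row, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mirror unilateral-left trials onto the right
#'
#' For lateralized-activation analysis, trials from animals labeled only in
#' the left hemisphere are reversed (signed angular velocity negated) and
#' combined with right-hemisphere trials, so all unilateral data share one
#' reference side. Unsigned quantities and all other trials are unchanged.
#'
#' @param trials A data.frame with columns `labeling` (one of `bilateral`,
#'   `unilateral_left`, `unilateral_right`, `none`, `unknown`) and
#'   `mean_signed_angular_velocity`.
#' @return The trial data.frame with left trials mirrored and relabeled
#'   `unilateral_right` (a logical `mirrored` column records which).
#' @export
mirror_lateralized <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (is.null(trials$labeling)) stop("trials must carry a labeling column")
  if (any(trials$labeling == "unknown"))
    stop("cannot mirror trials with unknown labeling")
  left <- trials$labeling == "unilateral_left"
  if (any(left) && is.null(trials$mean_signed_angular_velocity))
    stop("mirroring requires mean_signed_angular_velocity")
  trials$mirrored <- left
  if (any(left)) {
    trials$mean_signed_angular_velocity[left] <-
      -trials$mean_signed_angular_velocity[left]
    trials$labeling[left] <- "unilateral_right"
  }
  trials
}

#' Five-number box-plot summary with notches
#'
#' Summary following the convention used for the behavioral figures: the box
#' spans the inner quartile range with the median as dividing line, notches
#' give the 95% confidence interval of the median
#' (median +/- 1.57 IQR / sqrt(n)), the whiskers include 95% of the data
#' (2.5th to 97.5th percentile), and points beyond the whiskers are outliers.
#'
#' @param values Numeric vector (at least 5 values).
#' @return A list with `median`, `q1`, `q3`, `notch_low`, `notch_high`,
#'   `whisker_low`, `whisker_high`, `outliers`, `n`.
#' @export
boxplot_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 5) stop("boxplot_summary needs at least 5 values")
  q <- unname(quantile(values, c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7))
  iqr <- q[4] - q[2]
  notch <- 1.57 * iqr / sqrt(n)
  list(median = q[3], q1 = q[2], q3 = q[4],
       notch_low = q[3] - notch, notch_high = q[3] + notch,
       whisker_low = q[1], whisker_high = q[5],
       outliers = values[values < q[1] | values > q[5]], n = n)
}
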