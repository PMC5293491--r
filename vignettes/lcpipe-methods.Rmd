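---
title: "Models and methods behind lcpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lcpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcpipe)
```

This vignette explains the models implemented by lcpipe, the choices made
where the underlying assay conventions leave room, and what the synthetic
validation does and does not establish about real data.

## Looming stimuli

A dark disk expanding on a screen is the standard proxy for an object on a
collision course. For an object of radius $r$ approaching at constant speed
$v$, the full subtended angle at time-to-collision $t$ is
$$\theta(t) = 2\arctan\!\frac{r/v}{t},$$
so the entire time course is set by the single parameter $r/v$ (seconds).
`loom_angular_diameter()` is this closed form; `loom_time_to_collision()`
its analytic inverse.

The modeled display is a cylinder covering 216° of azimuth and 72° of
elevation at 2.25° per LED pixel (96 × 32 pixels). Rendered disks step
through a finite series of sizes, as LED hardware does; the defaults are 35
sizes from 4.5° to 54° full diameter. Design choices worth making explicit:

- **Size spacing.** The sizes are spaced uniformly in angular diameter, and
  each size appears at the instant $\theta(t)$ first reaches it, so the
  constant-approach time course is exact at every size transition. Spacing
  uniformly in time or in pixel increments would be equally consistent with
  a "series of disk sizes"; uniform-in-size is the simplest rule that keeps
  the endpoints exact, and it is recorded in the emitted `size_table` so a
  different spacing can be swapped in.
- **Edge rendering.** Edge pixels take the fractional area of the ideal
  circle covering them (8 × 8 supersampling), i.e. intensity linear in
  covered area. Frames hold continuous intensities in
  $[0, \text{levels}-1]$ rather than quantized integers, so conservation
  properties are exact.
- **Polarity and holds.** A bright loom is the dark loom's polarity
  inversion about the background. The initial 4.5° disk is held 1 s before
  expansion and the final 54° disk 1 s after (configurable); the hold
  durations are conventions of this implementation.

The luminance-matched control relocates every darkened pixel of each frame
to a uniformly random position inside the footprint of the final disk.
This preserves the per-frame dark-pixel count, total intensity and
intensity histogram exactly — the stimulus darkens with the same temporal
profile but carries no coherent edge motion. The scramble is deterministic
given its seed.

Translating spots and bars move at constant angular speed along the
azimuth; rectangle/pixel overlap is computed analytically (separable in the
two axes), and the final frame is pinned to the exact end azimuth.

## Kinematics

Tracked output (per-frame position and heading) is converted to body-frame
quantities:

- **Forward/backward velocity** is the smoothed path speed signed by the
  agreement between displacement and heading — positive when the fly moves
  in the direction it faces, negative when it retreats. Displacement is
  smoothed with a centered 5-frame moving average (0.1 s at the 50 Hz arena
  frame rate) before a centered difference; the "smoothing filter" is not
  further specified by the assay convention, and a centered moving average
  is the simplest choice consistent with it.
- **Angular velocity** is the Savitzky–Golay first derivative of the
  unwrapped heading, scaled to deg/s. Defaults are window 7, order 2 at
  50 Hz (≈0.1 s of effective smoothing); for 6000 Hz high-speed recordings
  a window of 301 frames achieves the same effective span. Savitzky–Golay
  derivatives are exact for polynomial signals up to the fit order, which
  the tests exploit as an oracle.
- **Edge validity.** Frames where a filter lacks full support carry a
  `FALSE` validity flag and are excluded from window summaries; they are
  never zero-padded, which would bias means near window edges.
- **Sign conventions.** Positive angular velocity is counterclockwise
  viewed from above. Turning toward/away from a stimulated side is defined
  on top of this by `mirror_lateralized()`, which negates the signed mean
  of left-hemisphere trials and pools them with right-hemisphere trials.
- **Tracking.** The bundled tracker segments one bright blob per frame
  (threshold + connected components), takes the centroid from
  intensity-weighted first moments and the orientation from the principal
  axis of second central moments, resolving the 180° axis ambiguity with
  the smoothed displacement direction. It replaces a template-matching
  tracker whose template is not available; because the trajectory contract
  is identical, every downstream stage is tracker-agnostic. Frames with
  zero or several qualifying blobs become flagged gaps rather than errors.

## Behavioral classification and penetrance

Thresholds derive only from control trials: the 97.7th percentile of
control mean velocities (forward cut), the 2.3rd (backward cut), and the
97.7th of control mean angular speeds (turn cut). These percentiles
correspond to roughly ±2 SD under normality but remain meaningful for the
skewed distributions real cohorts produce. Two conventions are pinned
down explicitly:

- **Quantile rule:** linear interpolation between closest order statistics
  (`stats::quantile` type 7), recorded in the `threshold_set` object.
- **Strict inequality:** a trial exactly at a cut is within the normal
  range; "beyond" a percentile is read strictly.

A consequence of percentile thresholds worth keeping in mind: trials drawn
from the same distribution as the controls are flagged at ≈2.3% per tail
*by construction*. Scored penetrance therefore carries a small upward bias
of ≈ 0.023 × (1 − p) relative to a generating episode probability p; the
validation suite measures recovery with this property visible rather than
correcting for it, since the scoring convention itself does not correct
for it.

Penetrance is reported per trial or per fly (a fly counts once if any of
its trials is flagged), with exact Clopper–Pearson intervals computed from
the beta-quantile form of the binomial tails. The Mann–Whitney statistic
uses midranks; exact two-sided p-values come from full enumeration of all
group assignments (valid under ties) up to a combined sample size of 14,
and otherwise from the normal approximation with tie and continuity
corrections. Box-plot summaries follow the notched convention: notches at
median ± 1.57·IQR/√n, whiskers at the 2.5th/97.5th percentiles so they
span 95% of the data.

## Calcium ΔF/F pipeline

Frames are rigidly registered by maximizing the cross-correlation with a
reference image over integer shifts within a search radius (default 10 px);
the default reference is the mean of the first 30 frames. How the reference
is built matters: averaging frames that are themselves jittered blurs the
reference and can bias every recovered shift by a common offset of about
the mean jitter (±1 px), so when a motion-free anchor frame is available
it should be passed explicitly as `reference`. Choices:

- Integer shifts only, matching a plain cross-correlation registration;
  ties break to the smallest shift magnitude, then row-major order.
- Frames whose correlation peak lies on the search boundary are flagged
  (their true shift may be larger) but still corrected.
- Pixels vacated by a correction are filled with the median of the frame's
  border pixels, a neutral estimate of the background.

The ROI trace is the plain mean under the mask (masks are inputs; real
ones are hand-drawn around a glomerulus, and `ellipse_roi()` builds
synthetic ones). The baseline $F_0$ at each frame is the 10th percentile
of the trace in a 300-frame window centered on the frame — at 10 Hz a 30 s
window, long relative to the indicator transients, so transients barely
move the baseline. Windows are truncated at the series edges; whether the
original convention was centered or trailing is not determined, and
centered is the symmetric default. $\Delta F/F = (F - F_0)/F_0$; when a
series dips to zero or below (possible for synthetic or
background-subtracted data), a 1-unit offset is added to both series
first so the ratio stays defined.

For across-animal comparisons each fly's ΔF/F is divided by the 98th
percentile of its pooled ΔF/F across all stimuli in the experiment
(scale-invariant and idempotent). Loom responses are summarized as the
mean ΔF/F in the half-open window $[t_{stop} - 2\,\mathrm{s},
t_{stop} + 2\,\mathrm{s})$ around the moment expansion stops — the window
where loom responses peak — or over the whole epoch for non-looming
stimuli; half-open endpoints make the frame counts reproducible (exactly
40 frames at 10 Hz). Group summaries take each fly's mean across
repetitions first, then mean ± SEM across flies, so unbalanced repetition
counts do not overweight any animal.

## Anatomy

The eye is modeled as a circle of $n \approx 750$ equal-area columns
mapped uniformly onto the lobula, giving
$D = 2\sqrt{n/\pi} \approx 31$ columns per axis. An arbor spreading
fractions $f_{AP}$ and $f_{DV}$ of the two axes is treated as a planar
ellipse with those semi-axis fractions, covering
$\frac{\pi}{4}(f_{AP} D)(f_{DV} D) = f_{AP} f_{DV}\, n$ columns. The
implementation evaluates the ellipse form and the tests assert the
algebraic identity with the product form. Output is a real number —
callers round for display — and no correction is applied for the known
overestimation of large arbors, since none is established.

## What the synthetic generators emulate

The behavioral generator produces per-trial trajectories at 50 Hz with 1 s
pre-stimulation, 1 s stimulation, and 1 s post windows: per-trial baseline
walking speed drawn from N(5, 2²) mm/s, heading diffusing at 30 deg/√s,
and — with the configured per-trial probability — a stimulation-locked
episode (backward walking at −10 mm/s, turning at 200 deg/s, or a jump
flag) ramped on and off over 100 ms so window means depend on window
placement realistically. Flies reflect off the arena wall. The default
cohort sizes (10 flies × 5 trials experimental, 20 × 5 control) match the
scale of real screen cohorts (~50–110 trials per line). The calcium
generator renders a 90 × 128 movie at 10 Hz with an elliptical glomerulus
(baseline 100 over background 20), transients with instantaneous rise and
exponential decay (τ = 1.5 s) scaled by per-stimulus fractional
amplitudes, Gaussian pixel noise (SD 2), and rigid integer jitter within
±3 px.

These generators reproduce the statistical structure the analyses assume —
not fly biomechanics, indicator nonlinearity, photon shot noise, slow
drift, or non-rigid tissue motion. Passing the recovery suites therefore
certifies the *analysis code* (thresholding behaves like order statistics
should, registration finds planted shifts, ΔF/F recovers planted
amplitudes, penetrance recovers planted probabilities); it does not
certify tracker accuracy on real video or registration on real tissue,
which require their own ground truth.

## Problem sizes and tolerances in the validation suite

The suites run at sizes chosen to give tight Monte-Carlo error while
staying desk-scale: 10⁶ draws for the percentile-vs-SD calibration
(±0.02), 5000-point grids for closed-form agreement (10⁻⁹ relative), all
(k, n ≤ 50) pairs for Clopper–Pearson inversion (10⁻⁶), sampled splits of
a pooled n = 10 for Mann–Whitney enumeration (exact equality), 20 seeds of
three-amplitude movies for ΔF/F recovery (±15% relative, ordering in every
seed), and 10 seeds × 50 trials per generating probability for penetrance
recovery (mean inside the exact binomial 95% acceptance region). Exact
coverage of Clopper–Pearson is computed by enumeration over the binomial
support rather than by simulation, which is both faster and stronger.

## Known limitations

- The tracker assumes one fly-like blob; overlapping flies or reflections
  become gaps.
- Motion correction is rigid and integer-valued; subpixel or non-rigid
  motion leaves residuals.
- The ellipse arbor model overestimates coverage for large, irregular
  arbors.
- Manual annotations (jump, reach, takeoff frames) are consumed as data;
  the package does not detect them from video.
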