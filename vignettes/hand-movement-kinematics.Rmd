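---
title: "Video-based hand-movement kinematics: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video-based hand-movement kinematics: models, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(reachtrack)
```

## The measurement problem

A low-cost way to quantify upper-limb motor control is to film the back of
the hand from above while the participant moves a high-contrast fiducial
marker between two squares shown on a monitor, at a trained slow pace
(25.7 mm/s). The camera sees a 183-mm field of view at 30 frames per second;
an 18 x 18 mm dark adhesive square carrying a bright 12-mm circle rides on
the hand. Software finds the circle in every frame, records its centroid,
and the trajectory is reduced to five kinematic metrics whose age trends and
test-retest reliability are the scientific outputs.

`reachtrack` re-implements that measurement chain offline: a synthetic frame
and cohort generator stands in for the camera and the participants, so every
stage can be validated against known ground truth.

## Fiducial detection

**Calibration.** Before a trial the marker is held still and one frame is
grabbed. `calibrate_threshold()` sweeps every integer gray threshold and
marks a threshold *valid* when binarizing at it yields exactly one
circle-like connected component (minimum area of a half-radius disc,
equivalent radius within +/-40% of the expected circle radius,
isoperimetric circularity `4*pi*A/P^2 >= 0.8`). The stored operating
threshold is the median of the contiguous valid run, which centers the
working point between "background bleeds in" and "circle erodes away".

**Per-frame recognition.** `detect_fiducial()` binarizes at the calibrated
threshold, labels connected components (EBImage), applies the same three
gates, and among survivors keeps the most circular component (ties broken
by area). The reported position is the *intensity-weighted* centroid of the
component's pixels: because rendered and real edges are anti-aliased over
roughly one pixel, weighting by intensity recovers the sub-pixel position
(~0.03 px RMS on noiseless renders; <= 0.5 px RMS with pixel noise up to 5
gray levels). The circle radius is reported as the equivalent-area radius;
it is *not* used to infer vertical position, which this measurement chain
cannot resolve.

The circularity cutoff (0.8) and radius tolerance (40%) are conventional,
configurable values. An axis-aligned square artifact measures ~pi/4 = 0.785
in the continuum but, digitized, can flirt with 0.8, so discrimination does
not rely on the cutoff alone: the circle's own circularity (~0.94 as
digitized) wins the ranking whenever both survive. Elongated or irregular
bright artifacts fall below the cutoff outright.

**Dropouts.** Runs of up to `max_gap` (default 3 frames, 0.1 s) consecutive
misses bracketed by detections are filled by linear interpolation and
flagged; longer runs stay invalid and are excluded from kinematics.

**Conventions.** Images are numeric matrices `[row = y, col = x]`, gray
0..255, origin at the top-left pixel, pixel centers at integer coordinates.
Color input collapses to luminance with the ITU-R BT.601 weights. Frame
stacks are exchanged as numbered PNG directories; no video container
decoding is attempted.

## Task structure and segmentation

A *trial* is six *subtasks* in fixed order (four with 100-px targets, one
62-px, one 50-px), separated by 10-s rests on a central 100-px square. The
two target squares are 138 mm apart center-to-center, vertically centered.
Each subtask starts with an initiation arrival at the left target and then
five movements between the targets; the initiation move is not analyzed.

`run_state_machine()` replays the online logic from geometry alone: a
centroid inside the active square (closed test -- the boundary counts as
inside) is an arrival; arrivals flip the active side; five post-initiation
arrivals complete the subtask. Rest blocks are delimited by the protocol
sequence (completion to next initiation), not inferred from motion. If
per-frame status flags recorded at acquisition time are supplied, the
machine can replay those instead and reports any disagreement with the
geometric recomputation.

`extract_segments()` then cuts each movement into:

* a **travel segment** -- frames strictly after the last frame inside the
  departure square, through the arrival frame (half-open `[start,
  arrival + 1)`, 0-based);
* an **endpoint segment** -- frames after the arrival through the frame of
  horizontal direction reversal (the extreme-x frame in the travel
  direction, zero-displacement runs absorbed). The arrival frame itself is
  assigned to the travel segment so that segments never overlap and, with
  the within-square gaps, tile the trial's frames exactly once. If the
  centroid leaves the target without reversing, that endpoint is marked
  missing and excluded from offset averages.

## The five metrics

With scale `mm_per_px = fov_width_mm / image_width_px` and frame interval
`1/fps`:

1. **Mean speed** (mm/s): mean of instantaneous speeds (Euclidean centroid
   displacement x scale x fps) over a travel segment's frame pairs.
2. **Mean |acceleration|** (mm/s^2): consecutive instantaneous speeds
   differenced and multiplied by fps, magnitudes averaged over the segment.
   The magnitude is deliberate: over a start-and-stop segment a signed mean
   cancels to ~0, while the mean magnitude tracks how unsteady the motion
   is, which is the quantity that shows age trends.
3. **Percent speed error**: `100 * (mean_speed - 25.7) / 25.7`, computed
   from each segment's mean speed and then averaged across segments.
4. **Center offset** (mm, signed): horizontal distance from the reversal
   point to the target center, projected on the travel direction so
   overreach is positive for either approach.
5. **Intertarget path accuracy** (IPA, %): the fraction of travel-segment
   frames whose centroid lies inside the rectangular corridor spanning both
   targets with height equal to the target side. The *inside* fraction is
   reported (4 of 5 frames inside = 80%). Endpoint frames are excluded from
   the denominator: they lie inside a target square, hence inside the
   corridor by construction, and would only dilute the measure.

Per subtask, travel-segment values are averaged (5 segments), offsets over
available endpoints, IPA over pooled travel frames; `summarize_trial()`
emits one record per subtask.

## Reliability statistics

Each metric is reduced to a subjects x trials matrix by averaging the six
subtask means per trial (pre-averaging; a per-subtask stratified mode is
available). Subjects with a missing cell are dropped listwise for that
metric.

`anova_two_way_no_rep()` (via `stats::aov`) supplies the mean squares MSR
(subjects), MSC (trials), MSE (residual). The headline reliability is the
agreement ICC for the average of k = 2 trials,

    ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n),

with 95% intervals from the Shrout-Fleiss F-based procedure (single-measure
bounds stepped up by Spearman-Brown). The consistency form ICC(3,k) =
(MSR - MSE)/MSR is reported alongside, because the conventional labels for
"two-way fixed" and "ICC(2,k)" conflict in the literature and reporting
both removes the ambiguity. `lcc()` adds the Pearson correlation between
trials with the Fisher-z interval. Note that Pearson r estimates the
*single-measure* ICC(2,1) when there is no systematic trial shift, not the
average-measure ICC(2,k); `icc_2k()` exposes `icc_single` for that
comparison. Age trends are ordinary least squares on trial-averaged subject
values, significance at p < 0.05 with no multiplicity correction, matching
the analysis style this pipeline mirrors.

## The synthetic generator

`simulate_trial()` emulates the trial protocol exactly: initial rest,
initiation move, five movements per subtask (alternating direction,
starting rightward), return to rest, 10-s rests, six subtasks. Movements
follow a piecewise horizontal profile: a half-minimum-jerk ramp from the
reversal point that reaches the commanded speed exactly at the departure
square's edge, constant velocity across the corridor, and a
half-minimum-jerk deceleration beginning one frame-travel past the arrival
edge, stopping at target center + overshoot. Confining the ramps to the
squares is a deliberate departure from a whole-movement minimum-jerk
profile: every frame pair of a travel segment then lies in the
constant-velocity stretch, so the measured mean speed of every travel
segment equals `training_speed * speed_mult` to numerical precision and the
generator's ground truth is exact rather than approximate. Within the
squares the motion is still smooth (continuous velocity, zero velocity and
acceleration at reversals).

Noise knobs per subject (`subject_params`):

* `speed_mult` -- multiplier on the trained speed;
* `path_noise_sd` (mm) -- sd of a *smooth lateral bow*, one sinusoidal
  excursion with Gaussian amplitude per movement. A rough per-frame jitter
  of the mm scale needed to leave the corridor would add tens of mm/s of
  spurious lateral velocity and corrupt the speed and acceleration metrics;
  a single smooth excursion per movement leaves them intact while IPA still
  falls monotonically as the knob grows;
* `overshoot_mm` -- signed reversal offset from the target center;
* `accel_jitter_sd` (mm/s^2) -- additive x noise scaled by `1/(fps^2 *
  sqrt(6))` so the induced mean |acceleration| is approximately the knob
  value.

`simulate_cohort()` draws ages uniformly and the knobs linearly in age plus
between-subject and between-trial Gaussian components (`effect_model`). The
defaults encode the qualitative trends the task targets -- speed about twice
the trained pace at age 43 rising by ~1.1 mm/s per year, lateral control
and overreach worsening with age -- and are *illustrative*: no
trajectory-level distributions are published for the real cohort, so these
defaults are not calibrated to any table of estimates. Metric mode maps
knobs directly to metric values through their generative relations (fast,
exact expectations, used for estimator-recovery studies at n = 111);
trajectory mode runs the full frame-rate simulation (used end-to-end).
`simulate_metric_matrix()` generates subject x trial matrices with explicit
variance components, for which the theoretical agreement ICC is
`sb^2 / (sb^2 + (st^2 + se^2)/k)`.

All randomness flows from one integer seed through deterministic
sub-streams; no global RNG state is consumed or disturbed.

**What the generator does not emulate.** Tremor or pathology, vertical (Z)
motion, lens distortion, illumination drift, motion blur, correlated
detector dropouts, or learning effects within a trial. Passing tests
therefore validate the measurement chain and the statistics, not the
biology: with real video the detector faces artifacts and lighting this
generator does not produce.

## Numerical choices and degenerate inputs

* Threshold sweep over integer gray levels 0..254; binarization is
  `value > threshold`.
* Half-open `[start, end)` frame ranges, 0-based frame indices everywhere.
* Component perimeter is the closed boundary chain length (diagonal steps
  sqrt(2)); a digitized disc of the expected size then measures ~0.94
  circularity, comfortably above the 0.8 gate.
* Detection ties on circularity break by larger area.
* A subject-by-trial matrix whose row variance is at floating-point zero
  reports ICC 0 with a warning rather than 0/0.
* A travel segment needs >= 4 frames for an acceleration value; the
  generator refuses commanded speeds that would make that impossible, and
  the movement profile refuses reversal points that leave no room to
  decelerate inside the square.
* Zero-variance trial columns make the Pearson correlation an error, not an
  NA, so degenerate cohorts fail loudly.

Validation problem sizes: detector accuracy is assessed on 200 rendered
frames at random sub-pixel positions (a 320-px sensor crop at the reference
mm-per-px scale keeps rendering cheap without changing the geometry);
reliability recovery on 500 two-trial cohorts of 111 subjects per ICC
set-point; interval coverage on 1000 replicates at r = 0.85, n = 111;
age-trend null rates on 400 cohorts of 111.

## Known limitations

* ICC confidence intervals use the Shrout-Fleiss F approximation; exact
  intervals for unbalanced or heteroscedastic data are out of scope.
* The acceleration stencil (difference of consecutive two-frame speeds) is
  one reasonable reading of a four-frame scheme; alternatives (non-
  overlapping speed pairs) would scale segment values slightly but
  identically across subjects, leaving reliability and trends unchanged.
* The per-subtask IPA denominator uses travel frames only; including
  endpoint frames would compress the metric toward 100% uniformly.
* The effect-model defaults are plausible, not fitted; absolute synthetic
  reliability values should not be read as predictions for any real cohort.
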