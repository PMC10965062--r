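---
title: "Video-based gait analysis: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video-based gait analysis: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(videogait)
```

videogait turns single-camera video of a person walking — already processed
by a 25-keypoint human pose estimator into per-frame pixel coordinates —
into the quantities a clinical gait analysis reports: step times, step
lengths, gait speed, left/right (or paretic/non-paretic) asymmetries, trunk
inclination, and sagittal lower-limb joint kinematics. It supports two
camera arrangements that impose very different geometry: a *sagittal* view
(filming from the side) where distances in the image map to meters through
a single scale factor, and a *frontal* view (filming head-on) where the
walker moves along the optical axis and spatial parameters must be
recovered from *apparent size*.

This vignette explains the models behind each stage, the conventions and
defaults the package commits to, and where the genuinely open design
decisions were resolved.

## Depth from pixel size (frontal view)

A fixed pinhole camera with focal length $f$ maps a rigid body of physical
size $s$ at depth $d$ to an image of size $s_{px} = f\,s/d$. If the person
stands at a known reference depth $d_{ref}$ at the start of the trial, with
apparent torso size $s_{ref}$, then after walking to depth
$d_{ref} + \Delta d_i$ their apparent size $s_i$ satisfies

$$ s_{ratio,i} \;=\; \frac{s_i}{s_{ref}} \;=\; \frac{d_{ref}}{d_{ref} + \Delta d_i}
 \qquad\Longrightarrow\qquad
 \Delta d_i \;=\; \frac{d_{ref}}{s_{ratio,i}} - d_{ref}. $$

Both $f$ and $s$ cancel in the ratio, so the method needs neither camera
calibration nor the person's true size — only the reference depth, a tape
measure quantity. `depth_change()` implements the inversion; the package's
tests verify it is exact (to machine precision) for a rigid synthetic
subject over depth-changes of 0–20 m.

The torso is the tracked body because it barely rotates in the transverse
plane during gait, so its apparent size depends essentially only on depth.
Three size representations are available: torso *height* (neck to mid-hip,
the default), shoulder *width*, and *area* ($\sqrt{\text{height}\times
\text{width}}$, which preserves the linear size–inverse-depth scaling).
`evaluate_tracking_methods()` reproduces the grid search over size
representations and smoothing cutoffs for choosing among them on data with
a reference step table. Height is the default because in our synthetic
evaluations it is the least sensitive to left–right keypoint disturbances
(it uses unpaired keypoints only); all three remain selectable.

The size-ratio series is low-pass filtered at 0.4 Hz before inversion. The
stepping cycle modulates apparent size at the cadence (~2 Hz); 0.4 Hz
removes that oscillation while keeping the slow depth trend. The filtering
is applied to the *ratio*, not to the raw size, and the reference size is
the median over a window from the trial start until 0.3 s before the first
heel-strike (at least 5 frames) — the epoch when the person verifiably
stands at $d_{ref}$.

Step length in the frontal view is the torso's depth travel between
consecutive bilateral heel-strikes; step time their interval; speed the
ratio. Depth is read at the nearest frame to each event (sub-frame linear
interpolation is available behind `interpolate = TRUE` but off by default,
matching the discrete workflow).

## Sagittal workflow

Sagittal pixel distances are dimensionalized by one scale factor: a known
distance along the line of progression (tape marks on the walkway) divided
by its pixel length. Out-of-plane (perspective) error is deliberately not
corrected — a single scale factor is the method; the simulator can
quantify the resulting error by giving the walker a nonzero hip width.

Two step-length definitions are implemented, because only one of them is
available frontally:

* **ankle distance** — horizontal distance between the two ankle keypoints
  at the instant of the terminating heel-strike;
* **torso travel** — horizontal travel of the mid-hip keypoint between the
  bounding heel-strikes (the mid-hip is the torso landmark because it is
  the most stable keypoint of the trunk in the sagittal view).

In real gait, torso travel exceeds ankle distance systematically: during
terminal stance the trailing heel rises and its ankle keypoint drifts
forward before the opposite foot lands. The synthetic walker reproduces
this only when its `heel_rise_m` parameter is positive; by default it is
zero so that ankle-distance recovery can be validated against the commanded
step length exactly.

### Joint angles and trunk inclination

Angle conventions (chosen here; the keypoint triplets define the segments
but not the signs):

* **hip** — thigh segment (hip→knee) angle from the downward vertical,
  flexion (knee forward) positive;
* **knee** — angle between thigh and shank, zero at full extension,
  flexion positive;
* **ankle** — angle between shank and foot segment (ankle→hallux) minus
  90°, dorsiflexion positive.

All are invariant to translation and uniform scaling of the keypoints.
Trunk inclination is the forward lean of the mid-hip→neck segment from
vertical at each heel-strike, minus a fixed offset (default 12°) that
compensates for the systematic difference between the keypoint-defined
trunk and a marker-defined trunk on the back. The offset is configuration,
not anatomy: it was derived from a specific marker set, so it is a default,
not a constant.

## Gait events

All three detectors use the same principle: at heel-strike the foot is at
its most forward excursion relative to the body, at toe-off its most
backward.

* **sagittal / motion capture** — positive and negative peaks of each
  ankle's anterior-posterior position relative to the mid-hip (torso);
* **frontal** — extrema of the *vertical* pixel distance between the left
  and right ankle keypoints: under perspective the forward foot appears
  closer to the horizon, so walking away positive peaks of (left − right)
  mark left heel-strikes, and the mapping reverses walking toward the
  camera. Only heel-strikes are emitted frontally.

### Peak-picking design

The peak detector is scale-free by construction, because signal amplitudes
vary enormously (pixel units, any camera, and in the frontal view
perspective shrinks the signal several-fold along one trial):

* candidate peaks are located on a 3 Hz zero-lag smoothed copy of the
  signal (well above any stepping cadence, so peak times are preserved),
  then refined to the raw signal's local maximum within ±0.07 s;
* minimum peak separation is 0.4× the dominant period, with the dominant
  frequency estimated from median-crossings of the smoothed signal
  (crossing counts, unlike an FFT peak, are immune to the perspective
  amplitude envelope);
* minimum prominence is 20% of the interquartile range in a window of
  about two periods around the candidate — *local*, because a global
  threshold drops the far-range peaks of frontal trials — floored at four
  times the measurement-noise scale (the median absolute residual between
  the raw and smoothed signal), so that standing phases do not approve
  their own noise wiggles.

### Known timing bias of the frontal detector

The inter-ankle vertical-distance signal mixes two perspective terms: the
depth separation of the feet (maximal at heel-strike) and the swing foot's
vertical lift (maximal at mid-swing). Their ratio degrades with distance
from the camera, so frontal event timing is frame-accurate near the camera
but drifts by several frames beyond roughly 7 m, early when walking away
and late when walking toward — the same directional bias the workflow
exhibits on real recordings. Because event-timing error contaminates the
depth read-out, the pipelines accept externally supplied event times (e.g.
from motion capture, via `events =` or the CSV interchange format); this is
the configuration of record when spatial parameters must not inherit
detector timing. Cross-referencing (`cross_reference_events()`) greedily
matches same-side events of two systems within 0.25 s so that all compared
parameters derive from the same gait cycles.

## Preprocessing

* **Left–right label correction.** Pose estimators sporadically exchange
  left and right limb labels. For each frame the labeling (original or
  exchanged over the lower-limb pairs) minimizing summed displacement from
  the previous corrected frame is kept. Continuity cannot observe the
  *global* polarity — if the anchor frame itself is swapped, the whole
  trial comes out inverted — so a majority vote resolves it: when more than
  half the frames would need correction, the polarity is flipped instead.
  A frame-list override reproduces manual edits.
* **Gap filling.** Interior missing runs up to 0.12 s (inclusive) are
  linearly interpolated; longer and leading/trailing runs stay missing —
  nothing is extrapolated. The operation is idempotent and never alters
  observed samples.
* **Filtering.** Zero-lag 4th-order low-pass Butterworth, applied forward
  and backward (squared magnitude response, no phase shift). Defaults: 7 Hz
  for marker trajectories, 5 Hz for sagittal keypoint trajectories, 0.4 Hz
  for the frontal size ratio; frontal keypoint trajectories themselves are
  not filtered (the size ratio carries the frontal smoothing). Edges use
  odd-reflection padding of length 3× the filter order together with
  steady-state initial conditions, so constants pass through unchanged.

## Aggregation and statistics

Steps take the side of their terminating heel-strike (the paretic/left step
time runs from a non-paretic/right heel-strike to the next paretic/left
one). Asymmetry is (paretic/left − non-paretic/right) / (sum), computed per
trial and then averaged across trials by default (session values are
unweighted means of trial means, so every trial counts equally; pooled-step
aggregation is available via `pooled = TRUE`). Speed-related changes are
elementwise fast − preferred differences of session summaries.

`agreement()` implements the validation statistics for comparing two
measurement systems on paired values: mean ± SD of differences, mean ± SD
of absolute differences, 95% limits of agreement (mean ± 1.96 SD), and
Pearson correlation. `kinematic_mae()` compares joint-angle waveforms over
gait cycles time-normalized to 101 samples (0–100% of the cycle, linear
interpolation in phase; any resolution ≥ 101 gives the same answer to well
under a tenth of a degree).

## The synthetic walker

The generator is a *kinematic puppet*, not a locomotor model: it exists to
test measurement, so every quantity a pipeline might estimate is prescribed
and therefore exactly known. Its construction:

* heel-strikes follow the commanded per-side step times; footfall targets
  advance by the commanded per-side step lengths, so ankle-to-ankle
  distance at heel-strike equals the commanded step length exactly (when
  `heel_rise_m = 0`);
* the pelvis moves at constant mean speed between heel-strikes with a
  realistic intra-stride modulation (default 20% dip at double support,
  zero net position offset at the events) and a small vertical bob;
* swing feet follow a smooth lift-and-carry profile that touches down with
  a small residual forward speed (default 0.25 m/s). This matters: the
  event detectors fire where the foot's forward motion matches the pelvis
  speed, and a foot that lands with zero velocity pushes that instant a
  few frames before contact. The landing speed and double-support dip are
  gait-literature-scale values chosen once, and they place the
  position-peak within one frame of true contact;
* knees come from two-link inverse kinematics (hip height 0.86× leg length
  keeps them slightly flexed and the geometry feasible up to ~0.75 m
  steps; infeasible commands raise an error);
* gait initiation (first step from standstill) and termination (a low
  closing step that brings the trailing foot up beside the lead foot while
  the pelvis decelerates over the feet) are included and labeled, so
  analyses can trim transients;
* segment dimensions default to anthropometric fractions of stature;
  `hip_width_m = 0` collapses both legs onto the sagittal mid-plane — the
  "in-plane" walker used to validate calibrated sagittal distances without
  out-of-plane projection error.

Projection is an ideal pinhole with no lens distortion. Convenience
cameras mimic realistic recording setups: a portrait frontal tablet
(1080×1920, placed 1.5–7.3 m from the walker's start, behind for "away" or
ahead for "toward") and a landscape sagittal tablet (1920×1080 at 3.89 m).
`corrupt_track()` adds what real pose estimation adds: Gaussian pixel
noise, keypoint dropout (confidence 0), and left/right label swaps, all
seeded and logged.

**What the simulator does not emulate** — and hence what passing tests do
*not* show about real data: appearance-dependent keypoint bias (the
estimator tracking the shoe rather than the malleolus, or behaving
differently on the front and back of a person), confidence-correlated
error, occlusion by the contralateral limb or by assistive devices,
non-Gaussian outliers, rolling-shutter and lens distortion, soft-tissue
and clothing motion, and pathological gait beyond parametric asymmetry,
lean, and heel-rise. Validation on real clinical recordings remains a
separate exercise; the synthetic results bound only the *algorithmic* error
of the workflow.

## Problem sizes used by the tests and the acceptance script

Fixture trials are 3–6 s of walking at 25–30 Hz (roughly walkway length),
simulated fresh at run time; the frontal speed-recovery study uses 100
seeded walks at commanded speeds 0.6–1.4 m/s, noiseless and with 2 px
noise; the limits-of-agreement coverage check draws 10^5 normal
differences; the swap-correction study injects ~200 swaps over 20 seeded
trials. Event-timing checks use a commanded step time that is a whole
number of frames so true footfalls lie on the sampling grid, and exclude
the labeled initiation footfall.

## Known limitations

* Frontal event timing (and therefore unaided frontal step lengths)
  degrades with distance, as described above; frontal accuracy is best
  near the camera and with externally supplied events.
* The sagittal scale factor assumes motion parallel to the calibration
  plane; lateral drift biases lengths.
* Asymmetry from torso-travel step lengths is structurally insensitive:
  the torso advances at its mean speed, so per-side travel differences are
  much smaller than per-side ankle-distance differences. Use the sagittal
  ankle-distance method for asymmetry.
* The left-right corrector's majority vote assumes swaps affect a minority
  of frames; a track mislabeled for most of its duration will be resolved
  to the wrong polarity.
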