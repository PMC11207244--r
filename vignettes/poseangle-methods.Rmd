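---
title: "Models and methods behind poseangle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poseangle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(poseangle)
```

`poseangle` post-processes per-frame 3D joint coordinates from monocular
human pose estimators and converts them into anatomical joint-angle
trajectories. This vignette is the package's own account of the models it
implements, the conventions it had to fix, and what its tests do and do
not demonstrate.

## The humanoid model

The skeleton is a kinematic tree with 26 rotational degrees of freedom,
rooted at the pelvis centre (the midpoint of the two hip joints, which is
also the origin convention of the measured data). Rotations are named by
anatomical plane: sagittal (`theta`), coronal (`phi`), transverse (`psi`).
The coordinate frame is right-handed with +y up, +x toward the subject's
anatomical left, +z toward the camera.

* 3 body angles (`theta_bd`, `phi_bd`, `psi_bd`) orient the whole model
  relative to the camera, applied as `Ry(psi) Rz(phi) Rx(theta)` ahead of
  every chain.
* A 3-DoF waist (lumbar) joint separates upper-body motion from the
  pelvis. Multi-DoF joints compose sagittal, then coronal, then
  transverse as intrinsic rotations.
* Each leg: 2-DoF hip (sagittal, coronal) and 1-DoF knee. Each arm:
  3-DoF shoulder and 1-DoF elbow. Wrists and ankles are the endpoints of
  the lower-arm and shin segments; no hand or foot segments are modelled.
* Six further articulation points (sagittal/coronal neck, transverse
  hips, sagittal ankles) complete the 26-DoF joint table but are held at
  zero during fitting.

Of the 26, 17 joint angles are estimated from data; together with the 3
body angles and a global size factor `gamma` they form the 21-variable
pose vector, reported in a fixed printed order (see `pose_variables()`).
`gamma` multiplies every segment length, so the same model matches a
subject at any distance from the camera.

Segment lengths default to standard anthropometric fractions of stature
(thigh 0.245, shin 0.246, upper arm 0.186, lower arm 0.146, shoulder
width 0.259, hip width 0.191), overridable in `humanoid_spec()`.

**Placement of the waist joint.** The lumbar joint sits a sacral offset
(0.05 of stature) *above* the hip line rather than exactly at the
mid-hip origin. This is anatomically where the lumbosacral junction is,
and it is also what makes trunk pitch observable: with the waist exactly
on the hip line, a body-pitch change can be exactly cancelled by opposite
waist and hip sagittal rotations as far as the 12 measured joints are
concerned, so the angle decomposition would be unidentifiable. The offset
gives trunk pitch a lever arm through the shoulder positions.

**Polarity.** Positive sagittal angles flex limbs toward the camera
(hip/shoulder/elbow flexion forward, knee flexion backward), positive
waist/body pitch leans the trunk toward the camera, and positive coronal
angles tilt limbs toward the subject's left. These signs are a documented
package convention; mirror symmetry is exact under `mirror_pose()`
(left/right pairs swap; coronal and transverse components negate).

**Angle bounds.** Defaults are physiological ranges (knee and elbow
flexion `[0, 150]` degrees, shoulder sagittal `[-60, 180]`, hip sagittal
`[-30, 120]`, symmetric coronal/transverse ranges, `gamma` in
`[0.5, 2]`). They are configurable; symmetric coronal/transverse bounds
keep the mirrored version of any admissible pose admissible.

## The fitting cost and registration

For one frame, the cost is the mean per-joint position error (MPJPE):
the average over the 12 canonical joints of the Euclidean distance
between measured and model coordinates, both expressed in the
pelvis-centred frame. Measured frames are re-centred on their hip
midpoint before fitting; no pre-scaling is applied to metric input —
`gamma` absorbs scale. The cost is exactly zero when the model overlaps
the measurement.

## uDEAS, the optimizer

Every variable is encoded as a binary row. A row of `n` bits with integer
value `k` decodes to `lo + (hi - lo) * (k + 0.5) / 2^n` — the midpoint of
the `k`-th of `2^n` subdivisions, strictly inside the bounds and
strictly increasing in `k`. Attainable values at depth `d` form a uniform
grid of spacing `(hi - lo) / 2^d`.

A *local search* is a sequence of sessions. In a session each variable
receives one **bisectional search** (append a bit; evaluate both
children; keep the better, ties keeping the lower half) and one
**unidirectional search** (step the row's integer value in the direction
the winning child indicates, at fixed length, while the cost strictly
decreases, clamped at the range ends). The *global scheme* repeats the
local search from random initial matrices and keeps the best local
minimum. Identical seeds reproduce identical traces.

Per session, each variable's **cost sensitivity** is the average absolute
cost slope over its bisectional pair and its `M` accepted unidirectional
steps, divided by `M + 1`. With `ordering = "sensitivity"` (default) the
next session visits variables in descending sensitivity; the first
session is sequential.

Three implementation decisions matter and are deliberate:

* **Refinement at full depth.** Once a row reaches `max_bits`, sessions
  continue to give it a two-neighbour probe plus unidirectional search on
  the finest grid, until a whole session brings no improvement. Without
  this the search ends right after the last deepening session, which on
  the 21-variable pose problem left median angle errors near 5 degrees;
  with it the local search terminates at a genuine coordinate-wise
  minimum of the finest grid. Disable with
  `udeas_config(refine_at_max_depth = FALSE)`.
* **Warm-start encoding depth.** Warm starts (previous frame, geometric
  estimate) are encoded at `init_bits + 3` bits: coarse enough that
  bisection still refines them, fine enough to stay in the intended
  basin. Encoding at the full depth made the fixed-grid walks slow;
  at `init_bits` the basin was often lost.
* **Tie-breaks** always keep the lower ("0") child, making runs
  deterministic.

Defaults: `init_bits = 3`, `max_bits = 12` (0.04-degree resolution on a
180-degree range), 5 random restarts.

## Geometric initialisation

Coordinate-wise search on a 21-variable articulated model has deep
compensation minima: a smaller `gamma` with a pitched body can mimic a
crouch to within a few centimetres, and no single-variable move escapes.
`fit_frame()` therefore seeds one restart (of six) at a closed-form
estimate, `initial_pose_estimate()`:

* `gamma` from the rigid torso: measured shoulder-line plus pelvis-line
  width over the model's — these lengths are pose-invariant;
* body orientation from the pelvis line and the direction to the
  shoulder centre;
* the waist frame from the measured shoulder line, decomposed relative
  to the body frame;
* limb sagittal/coronal angles from each proximal segment's direction in
  its parent frame, knee/elbow flexion from the bend between segments,
  and the transverse shoulder angle from the forearm direction (skipped
  for a straight elbow, where it is unidentifiable).

This is the standard initialise-then-refine practice of inverse
kinematics; all 21 variables remain free and the random restarts remain
in place. In self-consistency experiments it improves the median
recovered MPJPE from about 0.018 m to 0.005 m.

## Outlier screening

Genuine motion changes link lengths in a pixel projection only slowly;
switches and misdetections change them abruptly. Ten links are monitored
(shoulder line, pelvis line, left/right upper arm, lower arm, thigh,
shin). For pixel-unit input, lengths are first converted to centimetres
by `stature_cm / subject_pixel_height`, with 175/160 cm male/female
population averages as the default stature and the tracked box height as
the pixel height.

The detector flags a frame when any link's per-frame length change
exceeds a threshold (default 10 cm/frame at 30 fps, rescaled by
`30 / fps`). Three operational details resolve what a threshold rule
alone leaves open:

* a super-threshold jump sits *between* two frames; the one whose length
  deviates more from that link's series median is the outlier;
* long events only jump at entry and exit, so two flag groups bracketing
  a plateau that stays more than the threshold away from the median on a
  common triggering link are merged across any gap;
* a segment triggered by at least 4 distinct links is classed as a
  left/right **switch** (whole-body events move many links at once) and
  repaired across *all* joints; otherwise it is a **misdetection** and
  the repair covers the triggering links' joints *plus all joints distal
  on the limb chain*. The distal closure matters: a consistent
  elbow-plus-wrist swap disturbs only the upper-arm link, so an
  endpoint-only repair would leave the wrist swapped.

Repair is mean interpolation — every coordinate in a flagged segment is
replaced by the average of the last clean frame before and the first
clean frame after (a single neighbour at sequence edges) — followed by a
running median of width 5 (odd, shrinking symmetrically at the edges).

Known blind spots, by construction: a full-body switch leaves every link
length unchanged (it is a pure relabelling) and is invisible to length
screening; it is also harmless to any left/right-symmetric analysis but
not to signed angle profiles. Switches of a perfectly symmetric pose are
undetectable by any coordinate-based method.

## Subject tracking

Boxes are half-open pixel rectangles, so shared edges are never counted
twice, and intersection-over-union is intersection area over the sum of
areas minus intersection (zero when the union is empty). Frame one keeps
the largest-area person box above the confidence threshold (0.5 default,
halved on failure down to a floor of 0.05); later frames keep the person
box maximising confidence plus IoU with the previous selection. Ties take
the first candidate. A frame with no person detection holds the previous
box for at most `max_gap` frames (default 5) before the track is declared
lost. Confidence and IoU are summed raw, without normalisation.

## The synthetic generator

`motion_script()` defines per-variable sinusoids
(`base + amplitude * sin(2 pi t / period + phase)`); three named scripts
emulate gym-style motions: `rowing` (symmetric trunk pitch, arm pulls and
knee drive), `back_chest` (trunk extension with arm abduction) and
`arm_leg` (contralateral arm/leg swings, deliberately asymmetric so that
partial switches produce detectable cross-body links). Coordinates come
from the package's own forward kinematics, so generated data are exactly
representable by the model — which is the point of self-consistency
testing. `corrupt_trajectory()` injects partial/full left/right switches,
fixed-offset joint teleports and isotropic Gaussian jitter (default
0.005 m), returning the exact ground-truth mask.

What passing these tests shows: the optimizer, model and screening logic
are correct and accurate on data the model can represent. What they do
not show: robustness to systematic estimator bias, soft-tissue and
clothing artefacts, camera distortion, or anthropometry that deviates
from the default proportions — real-data validation against a
marker-based reference is out of scope here.

## Problem sizes and numerical choices

The test suite fits 20 uniform-random in-bounds poses (gamma in
[0.8, 1.2]) at the default optimizer settings, screens a 150-frame
corrupted motion, and checks tracking over 40 frames — sizes chosen so
the whole suite runs in a few minutes while medians remain stable.
Tolerances: forward kinematics is checked to 1e-9 relative; optimizer
traces to exact equality; recovery to the method's own targets (median
MPJPE at most 0.01 m, median absolute angle error at most 3 degrees,
comfortably met at 0.005 m / 1.5 degrees). Degenerate inputs are
errors with named variables (out-of-bounds pose, even median window,
non-positive pixel height, empty angle tables); degenerate geometry
(zero-area boxes, straight elbows, gimbal-adjacent body rolls) takes
documented conventions rather than errors.

## Limitations

* The sagittal body/waist/hip decomposition is only weakly identifiable
  from 12 joints (the lumbar lever is short); expect a few degrees of
  trade-off between `theta_bd`, `theta_ws` and the hip angles even at
  near-zero MPJPE.
* The transverse shoulder angle is unidentifiable when the elbow is
  straight.
* Link-length screening cannot see full-body switches (relabelling
  invariance) — a model-based or temporal-continuity prior would be
  needed.
* Per-frame fitting with warm starts is accurate but not real-time in
  pure R (roughly 2-5 s per frame at default settings).
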