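---
title: "Marker registration and constrained inverse kinematics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker registration and constrained inverse kinematics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Constrained inverse kinematics (IK) estimates the generalized coordinates
$q$ of a rigid-body model from optical marker trajectories by minimizing

$$ f(q) \;=\; \sum_i w_i \,\lVert x_i^{\mathrm{obs}} - x_i(q) \rVert^2 , $$

where $x_i(q)$ is the forward-kinematics position of model marker $i$ and
$w_i \ge 0$ its weight.  For the estimates to mean anything, the model
markers must sit on the model where the experimental markers sit on the
subject — *marker registration*.  The subtlety this package is built to
demonstrate is that registration error is invisible to the usual quality
check: every registration method ends by repositioning model markers to
coincide with the experimental markers at the static calibration pose, so
the static marker residual is numerically zero whether the underlying pose
was right or badly biased.  Small marker RMSE therefore does not imply
accurate joint angles.

Three registration strategies are implemented and compared on a synthetic
humanoid robot whose true joint angles are known:

* **Encoder registration** — the idealized reference: the model is posed
  with the robot's ground-truth joint angles; only the six pelvis-to-ground
  root coordinates are estimated, by a least-squares fit of the pelvis
  markers with the joint angles frozen (encoders cannot observe the root;
  this minimal completion is our choice).
* **Orientation registration** — the method of interest: anatomical
  reference frames for pelvis, thighs, shanks, and feet are constructed
  from the experimental markers alone; the model is posed so that its own
  anatomical frames (fixed, specification-derived transforms in each
  segment) best match the measured frames; markers are then registered at
  that pose.
* **User registration** — a stochastic surrogate for a person placing
  markers by eye in a GUI: each marker's local offset is perturbed by an
  independent isotropic Gaussian (default $\sigma = 10$ mm per axis, five
  seeded "users"), the pose is solved by full-marker IK with those wrong
  offsets, and markers are then registered at that (biased) pose.

## The rigid-body model

A model is a tree of rigid segments connected by joints, rooted at the
ground through a 6-DOF free joint (three translations, then intrinsic
Z–X–Y rotations).  Frames are right-handed with **Y up, X forward, Z to the
subject's right**; lengths are meters and angles radians everywhere inside
the package — degrees appear only in MOT files and reports.  Joint motion
composes intrinsic successive rotations about declared unit axes, matching
a serial-hinge robot.

The bundled fixture (`robot_fixture()`, also shipped as
`inst/extdata/robot.model.json`) is a child-sized biped: twelve
lower-extremity degrees of freedom (hip flexion/adduction/rotation, knee
flexion, ankle flexion/inversion, per leg), trunk and head welded to the
pelvis, 18 generalized coordinates in total, and 35 markers distributed as
three per foot/shank/thigh, two on each knee and ankle flexion axis, four
on the pelvis, two on the trunk, three on the head.  The published
description of the robot does not include link lengths or inertial values,
so the fixture's geometry (thigh 0.26 m, shank 0.25 m, ankle height
0.04 m, hip spacing 0.16 m, total mass 12 kg) is a documented stand-in
with child-like proportions, sized so 0.33 m steps are within reach; all
numbers live in `robot_geometry()` and are not reproductions of the real
robot.  Knee flexion is negative in our sign convention (positive rotation
about +Z is flexion of the hip).

## Anatomical frames

Frames are built Gram–Schmidt style: the primary direction is kept exact,
the secondary is orthogonalized against it, and the third axis is the
cross product completing a right-handed triad.  The bundled definitions
follow the common lateral-marker conventions: the pelvis from the
ASIS/PSIS markers; thigh and shank mediolateral axes from the knee- and
ankle-flexion-axis markers (these markers sit on the axes, so the
constructions are exact on the fixture); thigh longitudinal axis toward
the hip joint center, which is derived from the pelvis frame plus the
model's known hip-center offset (no functional estimation); foot frames
from heel, toe, and fifth-metatarsal markers with the plane normal as the
vertical.  Degenerate constructions (defining directions closer than 1°)
are errors, not warnings.

Orientation registration needs model-side counterparts of the measured
frames.  Each framed segment stores a constant anatomical-to-segment
transform, computed once from the fixture's nominal marker offsets; this
encodes "the model was built to the robot's specifications".  Orientation
tracking is realized through *virtual frame points*: the frame origin plus
points 0.1 m along each axis become four unit-weight targets for the same
least-squares marker solver (a deliberately swappable strategy — a
dedicated rotation-residual solver would be a drop-in alternative).

## The IK solver

A damped Gauss–Newton (Levenberg–Marquardt) iteration with the analytic
geometric Jacobian (rotational columns $a_k \times (x - p_k)$,
translational columns $a_k$).  Tolerances: gradient infinity-norm
$<10^{-10}$, step norm $<10^{-12}$, at most 100 iterations; accepted steps
never increase the objective, and hitting the iteration cap flags the
result as non-converged rather than returning silently.  Markers with
non-finite coordinates are excluded per frame; fewer than three
non-collinear targets is an error.  Trajectories are solved frame by
frame, warm-started from the previous solution (the first frame from the
static pose).  Default weights are 1; weight doubling provably leaves the
minimizer unchanged, and the test suite checks it.  Root orientation uses
intrinsic Z–X–Y angles; gait keeps the pitch far from the ±90° gimbal
region, and warm starts keep successive solutions on the same branch.

## Inverse dynamics

A recursive Newton–Euler pass over the tree.  Outward: world angular
velocity and acceleration propagate through each joint's axes
($\alpha \mathrel{+}= \ddot q_k a_k + \omega \times \dot q_k a_k$, applied
in axis order), giving exact segment accelerations for given
$(q, \dot q, \ddot q)$.  Inward: subtree forces and moments accumulate,
external wrenches enter at their center of pressure, and the generalized
moment of a rotational coordinate is the axis projection of the subtree
moment about the joint point; the root translational entries are the
residual forces.  When derivatives are not supplied they come from finite
differences of $q(t)$: 5-point 4th-order central stencils in the interior,
3rd-order shifted stencils one sample from each end, 2nd-order one-sided
at the ends — applied after any filtering.  Moments are reported about the
joint coordinate axes in N·m, unnormalized, and compared over the right
single-support window only (the synthetic gait mirrors the study design in
which stride length did not allow clean successive force-plate strikes for
both feet).

## Signal processing and evaluation

Filtering is a 4th-order low-pass Butterworth with an 8 Hz cutoff (the
defaults), applied forward and backward for zero phase — the biomechanics
norm, chosen because event timing must not lag; the effective order is
therefore 8.  Each pass is seeded with steady-state initial conditions
anchored at the first sample and the signal is reflection-padded, which
keeps DC exact and suppresses edge transients; edges of a filtered record
are still the least trustworthy part, so analysis windows sit inside the
trial.  Gait events come from the vertical ground reaction force crossing
5% of body weight, debounced by a 50 ms minimum phase duration, with
crossing times linearly interpolated between samples.  Kinematics are
compared on a 101-point percent-gait-cycle grid (linear interpolation) in
degrees; marker error is the per-frame RMS of model-to-experimental marker
distances, reported as mean ± SD over the analyzed cycle in mm; moment
RMSE is computed at native sampling inside the single-support window
against the encoder-registered model's moments (there is no moment ground
truth, so the encoder model serves as reference, as in the study design).

## The synthetic experiment

`make_dataset()` generates everything the pipeline consumes: a 1 s static
standing trial, a walking trial, exact encoder channels, and ground
reactions.  The gait is procedural, not a controller simulation: the
pelvis advances at a constant 0.4 m/s, each stance ankle is pinned to the
ground while the hip passes over it, swing ankles follow a C²-smooth
quintic carry with a $\sin^3$ lift (0.03 m), and sagittal hip/knee/ankle
angles come from exact planar two-link geometry with the foot held flat;
small 2° sinusoids add hip adduction/rotation and ankle inversion.
Defaults are the study conditions: 0.4 m/s, 0.33 m steps, 200 Hz, duty
factor 0.62 (our choice of a typical slow-walking value), three cycles so
that one full cycle is bounded by detected foot strikes away from filter
edges.  Because every waveform is exactly periodic and the pelvis advances
one stride per cycle, consecutive ipsilateral footfalls are spaced exactly
0.66 m by construction, and the robot walks with visibly bent knees
(roughly 25–70° of knee flexion) — a consequence of keeping the swing leg
within reach at this step length, and typical of small humanoids.

Ground reactions are synthesized from the model's own dynamics: the total
Newton–Euler wrench of the body is assigned to the stance foot during
single support; during double support it is split by a smooth cosine
transition weight; the center of pressure is solved so the horizontal
moment balance on the ground plane is exact and the vertical free moment
carries the remainder.  Running inverse dynamics on (truth kinematics,
synthesized GRF) therefore closes the loop with root residuals at
numerical precision — this closure is the reason the GRF is synthesized
from dynamics rather than drawn from a template.

Marker measurement error is independent isotropic Gaussian noise (default
0.5 mm per axis), and manual placement error is independent isotropic
Gaussian on the local offsets (default 10 mm per axis, five users).  All
randomness flows from one explicit seed.

**What the generator does not emulate**: soft-tissue artifact (absent on a
robot by design — that is the point of the robot paradigm), marker
occlusion and relabeling, force-plate noise and drift, double-support
force attribution fidelity, and any servo dynamics of the real machine.
Passing tests on this data therefore demonstrate the correctness and the
error-propagation structure of the algorithms, not field performance on
human data.  In particular the orientation method is exact here up to
measurement noise because the model-side anatomical frames are known
perfectly; on a real subject, frame-convention mismatch contributes
additional offset that this synthetic world cannot show, and the published
robot experiment's RMSE magnitudes are not reproducible without the
deposited dataset — only the direction and structure of the comparison
are.

## Numerical choices

* IK damping: multiplicative Levenberg–Marquardt on the normal equations
  with a $10^{-12}$-scaled ridge so unobservable directions stay put.
* Differentiation stencils as above; the 4th-order interior keeps the
  acceleration error of a 1 Hz signal sampled at 200 Hz below
  $10^{-3}\,s^{-2}$.
* COP solve: $p_x = N_z / F_y$, $p_z = -N_x / F_y$ on the $y=0$ plane;
  below 1 µN of vertical force the wrench is zeroed and the COP parked
  under the ankle.
* Static-trial markers are time-averaged before frame construction
  (noise shrinks as $1/\sqrt{T}$).
* Ties and degeneracies error out loudly: under-determined IK, degenerate
  frames, non-tree models, misaligned GRF time bases.

## Study-size choices

The test suite and the acceptance script run the full design at sizes a
laptop handles in minutes: IK evaluations run on every 4th frame (50 Hz)
of a three-cycle trial while events and moments stay at 200 Hz; the
directional comparison uses 10 ensemble repetitions × 5 users; the
end-to-end identity check runs two cycles at the full 200 Hz.  These sizes
are stated here as the package's chosen experiment scale; all of them are
arguments, not constants.

## Known limitations

* The simulated user is an assumption: real users' placement errors are
  neither isotropic nor independent across markers (they correlate along
  visible bone lines), and the published study reports only aggregate
  user variability, not a distribution.
* Orientation registration inherits any error in the model-side
  anatomical transforms; here they are exact by construction.
* The root pose completion for encoder registration (pelvis-marker fit)
  is our design; a different completion shifts absolute root coordinates
  but not the method comparison.
* Single-support-only moments: double-support attribution is split by a
  smooth weight for synthesis but never analyzed.
* No joint limits, no closed loops, no muscle or contact modeling.
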