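# gaitreg

Marker registration and constrained inverse kinematics for rigid-body gait
analysis.

## The problem

Joint angles computed by constrained inverse kinematics (IK) — posing a
jointed rigid-body model to minimize the weighted least-squares distance
between model and experimental markers,

```
f(q) = Σᵢ wᵢ ‖ xᵢ_obs − xᵢ(q) ‖²
```

— are only as good as the *marker registration*: the placement of model
markers where the experimental markers actually sit on the subject.  Every
common registration workflow ends by snapping model markers onto the
experimental markers at the static calibration pose, which drives the
static marker residual to zero **whether or not the underlying pose was
right**.  Small marker error therefore cannot certify accurate joint
angles, and manual (GUI) registration silently injects user-dependent bias
into every downstream angle and moment.

`gaitreg` is a self-contained toolkit for studying exactly this effect.  It
provides:

* a rigid-body kinematic-chain model (JSON schema) with a canonical
  child-sized humanoid-robot fixture — 12 lower-extremity degrees of
  freedom, 6-DOF pelvis-to-ground root, 35 optical markers;
* forward kinematics with analytic geometric Jacobians, and a damped
  Gauss–Newton weighted least-squares IK solver (per-frame and
  warm-started trajectory solves, missing-marker handling);
* anatomical reference frames (pelvis, thighs, shanks, feet) built from
  marker subsets by exact-primary Gram–Schmidt construction;
* three registration methods: **encoder** (ground-truth joint angles),
  **orientation** (pose matched to marker-derived anatomical frames — the
  method whose benefit the package demonstrates), and simulated **user**
  registration (seeded Gaussian manual-placement error);
* recursive Newton–Euler inverse dynamics with external ground-reaction
  wrenches, reported as generalized moments per coordinate;
* the evaluation protocol: zero-phase 4th-order 8 Hz Butterworth
  filtering, threshold gait events, 101-point percent-gait-cycle
  normalization, per-DOF RMSE tables;
* a synthetic experiment generator: periodic robot gait (0.4 m/s, 0.33 m
  steps, 200 Hz) with known joint angles, exact encoder channels, and
  dynamically consistent single-support ground reactions;
* TRC and MOT/STO readers/writers and a CLI
  (`synth / register / ik / id / evaluate / replicate`).

Who it is for: biomechanists and roboticists who want a transparent,
dependency-light testbed for registration and IK error propagation, with
every algorithmic step open and unit-tested against independent oracles.

## Worked example

Replicate the full study design on a synthetic trial: one encoder
registration, one orientation registration, five simulated users with
10 mm placement error, 0.5 mm marker noise, IK on every 4th frame of a
three-cycle 200 Hz walk:

```r
library(gaitreg)
rep <- replicate_study(seed = 1)
print(rep)
```

```
<replicate_report> seed 1, 5 users, sigma_user 10 mm
                  encoder_angle_deg orientation_angle_deg user_angle_mean_deg
Hip flexion                    0.06                  0.06                1.27
Hip adduction                  0.03                  0.02                1.72
Hip rotation                   0.05                  0.05                1.21
Knee flexion                   0.10                  0.09                1.86
Ankle flexion                  0.09                  0.08                3.08
Ankle inversion                0.15                  0.16               10.20
Marker error (mm)              0.22                  0.22                1.02
...
orientation better than user mean in 6/6 right-leg DOFs
```

Reading the table: each row is a right-leg degree of freedom (plus the
pooled marker-error row); entries are RMSE over one normalized gait cycle
against the known encoder angles, in degrees (moment columns, not shown
above, are N·m over the single-support window, compared against the
encoder-registered model's moments).  Orientation registration tracks the
encoder reference closely, while user registration is degrees off —
*despite every method having near-zero static marker residual* (check
`registration_result$static_marker_rmse`: it is below 1e-9 m for all
three).  The user columns carry the inter-user SD; the algorithmic methods
have none.

The same pipeline is scriptable from a shell:

```sh
Rscript exec/gaitreg synth --seed 1 --out data/
Rscript exec/gaitreg register --method orientation --dataset data/ --out reg.json
Rscript exec/gaitreg replicate --seed 1 --out report/
```

## Conventions

Right-handed frames, **Y up, X forward, Z to the subject's right**; meters
and radians internally (TRC files are mm, MOT angle columns degrees);
positive rotation about +Z is flexion, so knee flexion is negative; all
randomness flows from explicit integer seeds.  See the methods vignette
(`vignettes/marker-registration.Rmd`) for the model, the numerical
choices, and the limits of what the synthetic experiment can show.
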