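---
title: "Estimating lower-extremity kinematics from IMUs: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lower-extremity kinematics from IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imukin)
```

## The problem

Body-worn inertial measurement units (IMUs) — triaxial gyroscope,
accelerometer and magnetometer in one package — promise joint-angle
measurement outside the laboratory and over long durations. The obstacle is
drift: integrating angular velocity accumulates error without bound, and the
reference signals that can correct it (gravity from the accelerometer,
magnetic north from the magnetometer) are corrupted by motion and by
ferromagnetic disturbance respectively. `imukin` implements a complete
workflow that mitigates drift with two ingredients: complementary-filter
sensor fusion per sensor, and inverse kinematics (IK) on a constrained
skeletal model, so that each joint angle is informed by every sensor through
the kinematic chain rather than by a single sensor pair.

The pipeline is: **fuse** raw signals into per-sensor orientations →
**calibrate** fixed sensor-to-segment rotational offsets from a standing pose
→ **pre-screen** sensors whose early-trial behaviour is physiologically
unrealistic → **solve IK** per frame → **evaluate** agreement and drift
against a reference.

## Orientation algebra

Orientations are unit quaternions (scalar-first, `(w, x, y, z)`) or 3×3
rotation matrices, interconverted exactly (Shepperd branch selection, `w ≥ 0`
canonicalisation for the double cover). The scalar distance between two
orientations is the angle of the axis-angle representation of their relative
rotation,

$$\theta = \cos^{-1}\!\frac{\operatorname{tr}(R) - 1}{2}, \qquad
R = R_a^{\mathsf T} R_b,$$

with the arccos argument clamped to $[-1, 1]$. Internally the equivalent
quaternion `atan2` form is used because it is numerically stable near
$\theta = 0$ — the regime where equivalence tests at $10^{-9}$ rad operate,
and where a plain arccos of a dot product bottoms out near $10^{-8}$. All
angles are radians inside the package and degrees at every file and report
boundary.

## Sensor fusion

Three estimators share one integration core (per-sample timesteps from the
timestamps, midpoint-averaged gyro samples, quaternion-derivative
integration with renormalisation):

* **gyro_only** — pure strap-down integration, the drift baseline;
* **madgwick** — gyro integration corrected by a normalised gradient-descent
  step on the accelerometer (and magnetometer) objective, scaled by the gain
  `beta` (dimensionless). The corrective step is evaluated at the
  gyro-predicted state so that the measurement and the state refer to the
  same instant; at 100 Hz and gait-speed angular rates the half-sample lag of
  the classic ordering is worth ≈ 0.5°, which this predictor–corrector
  arrangement removes. A vanishing objective gradient skips the correction
  (normalising a round-off-level gradient would otherwise inject a full-size
  step in an arbitrary direction).
* **mahony** — proportional–integral feedback on the cross-product error
  between measured and predicted gravity/field directions; the integral term
  (`ki`) estimates the gyro bias.

Conventions, stated once because sign errors are the dominant failure mode:
the accelerometer measures **specific force** (a static, level sensor reads
`(0, 0, +9.81)` m/s²); the earth frame is right-handed with Z up and X the
horizontal projection of the magnetic field at initialisation; quaternions
are sensor-to-earth.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `beta` (Madgwick) | 0.1 at 100 Hz | the gain used with 100-Hz gait data; at 40 Hz it overcorrects and 0.025 is adopted instead, unchanged rather than re-derived |
| `kp`, `ki` (Mahony) | 0.5, 0 | conservative proportional gain, bias estimation off; no published tuning exists for this protocol, so the defaults stay configurable |
| `init_window_s` | 5 s | the length of the standing calibration pose; the mean accelerometer and magnetometer vectors over the window feed a TRIAD construction for the initial orientation |
| `mag_divisor` | 1 | incorporating the magnetometer only every m-th update limits the damage a magnetically disturbed sensor (typically a foot, near the floor) can do, at the price of slower heading correction; configured per sensor |

## The kinematic model

The default chain has 8 segments and 19 coordinates: a 6-dof pelvis root
(tilt/list/rotation + three translations, translations frozen during IK
because orientations carry no translation information), a 3-dof ball joint to
the torso, and per leg a 3-dof ball hip (flexion/adduction/rotation), a 1-dof
pin knee and a 1-dof pin ankle (plantarflexion–dorsiflexion, with the distal
foot joints welded). Eight virtual IMU frames sit on upper back, lower back
and bilateral thigh/shank/foot.

Ball joints use intrinsic Z–X–Y Euler angles mapped to (flexion, adduction,
axial rotation); segment frames at the neutral pose are X forward, Y up, Z to
the subject's right, and the root's fixed offset aligns this convention with
the ground frame. The rotation order is a convention choice — the named gait
angles do not determine it — and the Z–X–Y order puts the largest (sagittal)
rotation first, keeping the frontal-plane coordinate far from its gimbal
singularity at ±90°, which is outside the physiologic range. The knee is a
pure pin: coupled knee translations affect marker-based analyses but not
orientation-only tracking, so only the rotational dof is kept; this is an
approximation, documented rather than hidden. Coordinate bounds default to
±120° hip flexion, 0–140° knee flexion, ±60° ankle, ±60° for the remaining
hip dofs. The back joint carries 3 dofs (ball), a modelling assumption the
config format lets you change.

The all-zero pose is the instructed neutral standing posture, and
`forward_kinematics()` composes fixed offsets and joint rotations root-first.
Models round-trip through a YAML schema (`save_model()` / `load_model()`;
an example ships in `inst/extdata/default_model.yaml`).

## Sensor-to-segment calibration

With the model posed at the calibration pose $q_{cal}$ (default: all zeros),
each sensor's fixed rotational offset is

$$R^{off}_i = \bigl(R^{seg}_i(q_{cal})\bigr)^{\mathsf T} R^{meas}_i,$$

where $R^{meas}_i$ is the fused orientation averaged over the calibration
window (sign-aligned normalised quaternion mean; the window's angular
dispersion is reported and a dispersion above 10° warns). Averaging the 5-s
window, rather than picking one frame, is a choice: it suppresses
initialisation noise at no cost. A `q_cal` override accepts an externally
measured calibration posture for protocols that record one.

Because subjects do not hit the instructed pose exactly, and because
magnetometer disturbance corrupts per-sensor headings, zero-pose calibration
can inject constant axial-rotation biases. `heading_align()` optionally
removes per-sensor heading disagreement relative to a trusted reference
sensor by rotating offsets about earth Z only (swing–twist decomposition);
inclination disagreement is deliberately untouched. It is **off** by default:
it is a mitigation, not part of the core protocol.

## Inverse kinematics

Per frame, the tracker solves

$$\min_q \sum_{i \in \text{IMUs}} w_i\, \theta_i(q)^2, \qquad
\theta_i = \text{angle between } R^{meas}_i \text{ and }
R^{seg}_i(q)\,R^{off}_i,$$

with $\theta$ in radians inside the objective and degrees in every report.
Rather than treating the scalar $\theta_i$ as the residual, the solver stacks
the rotation-vector (matrix logarithm) of each sensor's discrepancy,
$r_i = \sqrt{w_i}\,\log(R^{meas\,\mathsf T}_i R^{vir}_i) \in \mathbb R^3$,
whose squared norm reproduces $w_i \theta_i^2$ exactly while giving a
determined least-squares system (24 residuals vs 16 free coordinates for the
default model). Each frame is solved by Levenberg–Marquardt with a
forward-difference Jacobian (step $10^{-7}$ rad), warm-started from the
previous frame; coordinates are clamped to bounds, with an active-set
reduction (coordinates pinned at a bound whose gradient points outward are
frozen for the iteration) so constrained frames converge instead of
grinding. Convergence: relative cost decrease below $10^{-9}$, projected
gradient below $10^{-10}$, or 200 iterations, whichever first; warm-started
gait frames typically converge in 2–4 iterations. Determinism: identical
inputs give identical outputs; there is no randomness in the solver.

Default weights downweight distal sensors — 1.0 for torso, pelvis and
thighs, 0.5 for shanks, 0.25 for feet — because sensors near the floor are
most exposed to ferromagnetic disturbance. The specific values are a
package default (config-overridable), chosen as a monotone distal reduction;
no published value set exists for this protocol. Known limitation:
hip internal/external rotation under heading-corrupted sensors is a
multimodal problem; the solver relies on warm starting only and performs no
global search. Missing samples drop that sensor's term for the frame rather
than interpolating, keeping the estimator honest about what was measured.

`ik_trajectory()` returns a classed fit (`imu_ik`) with `coef()` (joint
angles, degrees), `residuals()` (the per-sensor $\theta_i$, degrees — the
*IK orientation differences* used for screening and drift monitoring),
`summary()`, `plot()` and `as.data.frame()`.

## Pre-screening

Sensors whose early-trial IK orientation differences are unrealistic are
excluded before the definitive run, using the first 10 s of the trial:

1. **absolute rule** — any $\theta_i$ sample exceeds 45°;
2. **range rule** — the mean range of $\theta_i$ over 60-ms bins exceeds 30°.

Readings exactly at a threshold are included (strict inequalities). The
absolute rule uses the window maximum: the rule targets tracking failures,
and the maximum is the stricter, simpler reading of "exceeds a threshold"
(a mean variant is available). Bins are `round(bin_ms · rate / 1000)`
samples (6 at 100 Hz), floored at 2 samples with a warning at very low
rates; a trailing partial bin is dropped. Screening needs an IK pass that
still includes the possibly-bad sensors; a single all-sensor pass over the
first 10 s is used, then excluded sensors are dropped (weight 0) for the
full-trial fit — the minimal self-consistent reading of a screening rule
defined in terms of IK residuals.

## Evaluation statistics

Agreement and drift are quantified the way the field reports them:
per-minute RMS differences (angle differences wrapped to (−180°, 180°]
before squaring — a safety net, as gait angles live far from the wrap),
Pearson correlations per coordinate with the first-vs-last-minute change, an
ordinary least-squares line through the per-minute RMS values whose slope
(deg/min) is the drift measure, median/IQR summaries with 1.5·IQR outlier
flagging (type-7 quantiles, fixed so outlier counts are reproducible), and
integer-lag cross-correlation synchronisation (ties toward zero lag,
boundary hits flagged). Bilateral coordinates are pooled by default, and
pooling is over all window-values rather than medians-of-medians. $R^2$ is
reported as $1 - SS_{res}/SS_{tot}$ from the with-intercept fit and is
therefore non-negative; out-of-sample conventions that can go negative are
not replicated.

## The synthetic-trial generator

Closed-loop validation needs ground truth, so the package generates it.
`generate_trajectory()` produces joint-angle trajectories that emulate the
structure of a long-duration validation protocol: a 5-s all-zero standing
calibration segment, then walking (smooth sinusoidal profiles at a set
cadence; stride period = 120/cadence s), walking with alternating 180°
heading turns, or a repeated cycle of sitting, standing, stair-like
movement, side-stepping, walking and running. Transitions are 1-s
cross-fades, so implied angular velocities are finite, and a configuration
whose amplitudes exceed the model bounds is an error. `synthesize_imu()`
then realises the signals the filters invert: true sensor orientations
$R^{seg}(q(t)) R^{off}_i$ with planted offsets; gyro from central-difference
orientation differencing (so the generator stays consistent under any model
change); accelerometer specific force; magnetometer from a (optionally
disturbed) earth field.

Noise defaults are order-of-magnitude consumer-MEMS values: gyro white noise
0.005 rad/s/√Hz (scaled by √(rate/2) per sample), constant gyro bias 0.002
rad/s per axis (fixed magnitude, random direction per sensor), accelerometer
0.05 m/s², magnetometer 1% of field magnitude; bias random walk off. All
randomness is seeded explicitly — same seed, bit-identical trial.

Two deliberate simplifications, and what they imply about the tests:

* **Gravity-only accelerometer by default.** The accelerometer model omits
  linear acceleration unless `gravity_only = FALSE`; the default isolates
  filter and IK behaviour from the accelerometer-disturbance rejection
  problem. Passing round-trip tests therefore demonstrate correctness of
  the chain, not robustness to high-acceleration movement.
* **Sinusoidal gait.** Profiles are smooth parametric mixtures, not
  biomechanically exact waveforms; they exercise every code path (including
  bound contact at full knee extension) but say nothing about soft-tissue
  artifact, impact transients, or real magnetic environments.

The study-shaped fixture (`make_study_fixture()`) adds foot-sensor magnetic
disturbances beginning after the screening window and a corrupted variant in
which the right-foot sensor slips 60° on its mount just after calibration —
the failure mode the screening rules are designed to catch.

## Problem sizes

The shipped tests validate the full chain at the sizes the workflow targets:
a 60-s, 100-Hz, zero-noise walking trial must round-trip through
fuse → calibrate → IK to below 0.5° RMS per coordinate (observed ≈ 0.05°);
a 10-min, 100-Hz noisy trial must show per-minute-RMS drift slopes within
±0.2 deg/min under the complementary filter while gyro-only integration
exceeds that by two orders of magnitude; unit tests run at 8–30 s. The
`scripts/acceptance.R` driver recomputes these end-to-end quantities from
scratch at the same sizes.

## Known limitations

* Orientation-only tracking: pelvis translations are frozen; no position or
  velocity estimates.
* Static calibration only; functional and anatomical calibration methods are
  out of scope, as is magnetometer hard/soft-iron calibration.
* The Madgwick normalised-gradient correction chatters at amplitude
  ≈ `beta`·dt (0.06° at the defaults) — negligible against gait-scale
  signals, visible in noiseless synthetic runs.
* Per-frame local optimisation: no global search, no temporal smoothing
  beyond warm starts.
* The generator's realism limits (above) bound what synthetic validation can
  claim about real recordings.
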