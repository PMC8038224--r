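---
title: "Estimating L5/S1 net moments from wearable EMG and inertial sensors: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating L5/S1 net moments from wearable EMG and inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumbarload)
```

## The estimation problem

Mechanical load on the lower back is conventionally summarized by the net
moment about the L5/S1 intervertebral joint centre. Under known loading it
can be computed by inverse dynamics, but that requires either force plates
or fully known handheld loads — neither of which exists during real work.
`lumbarload` implements an ambulatory two-stage alternative:

1. During a short in-session calibration block with *known* handheld loads
   (0, 6 and 10 kg), a top-down linked segment model (LSM) driven by six
   body-worn inertial sensors produces reference net moments.
2. A small feed-forward neural network is trained, per subject and session,
   to map *wearable-only* signals — four trunk surface-EMG envelopes plus
   angular velocity and linear acceleration from just the sternum and
   sacrum sensors — onto those reference moments. The trained network then
   estimates lumbar load during unconstrained work tasks, where no load
   information exists.

The package covers the complete chain (sensor-to-segment calibration,
stream synchronization, EMG amplitude estimation, LSM targets, network
training and prediction, discriminant-validity statistics) plus a forward
simulator that generates full synthetic sessions with ground truth, so the
chain is testable end to end without recorded human data.

## Frames and sign conventions

All frames are right-handed with **x anterior, y to the subject's right, z
caudal (down)**; gravity is $+9.81\,\mathrm{m/s^2}$ along $z$. Orientation
quaternions map body-frame to global coordinates; angular velocity and
linear acceleration (specific force, IMU convention) are body-frame.

The net moment is the *reaction* moment exerted on the upper body across
L5/S1,

$$\mathbf{M} \;=\; \sum_i \mathbf{r}_i \times m_i(\mathbf{a}_i -
\mathbf{g}) \;+\; \sum_i \frac{d}{dt}\!\left(R_i I_i R_i^\top
\boldsymbol\omega_i\right),$$

summed over trunk (incl. head+neck), both upper arms, both forearm+hand
segments and the handheld load, with $\mathbf{r}_i$ the COM position
relative to the L5/S1 centre. In the frame above this yields the standard
reporting convention: $M_y > 0$ in forward flexion, $M_x > 0$ in
lateroflexion to the left, $M_z > 0$ in rotation to the left. Moments are
expressed in the trunk anatomical frame; this is a package convention (the
norm $\lVert\mathbf{M}\rVert$ is frame-invariant either way).

## The linked segment model

The top-down formulation deliberately avoids ground reaction forces: only
upper-body segments are modeled, so the method stays valid when the subject
leans on a workbench or stands on unknown support. Anthropometry follows a
standard adult fraction table (`anthropometric_table()`): segment masses as
fractions of body mass (trunk 0.497, head+neck 0.081, upper arms 0.028
each, forearm+hand 0.022 each — 0.678 of body mass in total), lengths as
fractions of stature, COM positions and transverse radii of gyration as
fractions of segment length. Head+neck is rigidly attached to the trunk
because the sensor layout has no head sensor. All fractions are plain
constants and overridable.

Numerical choices:

* COM accelerations come from double central differences of the
  reconstructed COM trajectories after a zero-phase 2nd-order Butterworth
  low-pass at 3 Hz (the same smoother used for EMG envelopes), which
  suppresses differentiation noise without phase distortion. In the exact
  static limit the filtered derivative vanishes and the model reduces to
  the closed-form gravitational sum $\sum m_i g d_i$ — the unit tests hold
  it to $10^{-6}$ Nm against an independently coded point-mass oracle.
* The pelvis-sensor specific force supplies the root (L5/S1) translation
  acceleration when `use_linacc = TRUE` (default; meant for controlled
  environments). Disabling it drops only the root-translation term.
* The handheld load is a point mass at the mid-hands point (from the
  forearm chain) plus a configurable offset; its moment contribution is
  exactly linear in load mass, a property the tests exploit.

## Sensor-to-segment calibration

Sensors are strapped over clothing, so the casing axes are rotated relative
to the anatomical segment axes by an unknown fixed rotation (the simulator
draws up to 10° by default). The calibration uses two functional cues:

* **Gravity**: during quiet neutral stance the mean accelerometer direction
  is segment-"up"; this fixes the longitudinal axis exactly. Samples are
  kept only if the specific-force norm is within 1 m/s² of $g$ and the
  rotation rate below 0.1 rad/s, which rejects transients (including the
  synchronization tap).
* **Sagittal rotation axis**: during trunk bending (sternum, sacrum) or
  shoulder flexion (arm sensors) the first principal direction of the
  gyroscope samples above 0.3 rad/s estimates the mediolateral axis, pooled
  over all five repetitions. Its sign is fixed by the rotation direction at
  movement onset (flexion is a rotation about the negative mediolateral
  axis in this frame).

Gram–Schmidt orthogonalization keeps the gravity axis exact; the anterior
axis completes the right-handed triad. If the principal rotation axis lies
within 15° of gravity the geometry is degenerate (e.g. a pure twist offered
as a bending trial) and calibration fails loudly. Under default simulator
noise, mountings up to 20° are recovered to well under 2° (typically
< 0.2°).

## EMG amplitude and synchronization

Envelopes are full-wave rectification followed by a zero-phase 2nd-order
Butterworth low-pass and linear interpolation onto the 50 Hz session grid.
The cutoff is a tunable with default **3 Hz**, a conventional envelope
bandwidth for trunk-load estimation; nothing downstream depends on its
exact value because the network standardizes its inputs.

EMG hardware and inertial sensors run on separate clocks. A pre-measurement
tap on two electrodes and one inertial sensor leaves a sharp transient in
both streams; `detect_tap_marker()` finds the highest-prominence transient
in the pre-trial window fully automatically (the cursor-assisted step of
interactive tools is replaced by a prominence ratio that must exceed 1,
with a 5-MAD noise gate). The clock offset is the difference of marker
times, median across EMG channels; all EMG streams are then shifted onto
the sacrum (master) clock and envelopes re-gridded. Injected offsets up to
±2 s are recovered with errors far below the 0.05 s tolerance used for
such tap procedures.

## The network estimator

Architecture is fixed at **16 inputs → 31 sigmoid hidden units → 3 linear
outputs**: four EMG envelopes plus 3D angular velocity and 3D specific
force from sternum and sacrum. Orientation quaternions are deliberately
excluded — inclination is already encoded in the accelerometer channels,
and magnetometer-derived headings are unreliable indoors. Training
minimizes the mean squared error of the three moment components on
standardized inputs and targets with full-batch L-BFGS from a small seeded
random initialization, and stops as soon as the summed per-axis training
RMSE drops below **10 Nm** (the fixed criterion; evaluated on the training
set — the method trains to a fit criterion, not with a validation split).
Up to three seeded restarts guard against poor initializations; if none
converges the best model is returned flagged `converged = FALSE` with a
warning. Everything is deterministic given the seed.

Two training configurations mirror the session protocol: the phase-2
evaluation trains on the 0 and 10 kg trials and holds out the 6 kg trials;
phase-3 work-task estimation trains a fresh network on all nine known-load
trials. With ~6 750 training samples against 623 weights the fit is well
constrained; a warning is raised below 10 samples per weight.

## The simulator: what it emulates, and what it does not

`simulate_session()` generates the full three-phase protocol: phase 1
segment-calibration movements (neutral stance; 90° bending, 45°
lateroflexion, 45° rotation, 45° shoulder flexion, 90° shoulder abduction;
five repetitions each followed by 3 s neutral standing), phase 2
bending/lateroflexion/rotation crossed with 0/6/10 kg, and phase 3 work
tasks — a light task (rank 1), a static task holding a working posture for
8 s (rank 3–4) and a combined heavy+dynamic lifting task (rank 5), with
Borg CR-10 scores drawn from truncated normals with means (SDs) 0.9 (0.8),
3.8 (1.6) and 6.0 (2.0).

Design choices, chosen once as plausible field conditions:

* Angle profiles are raised cosines (4 s per repetition), so velocity is
  continuous and acceleration bounded — no human movement has velocity
  jumps. Pelvis motion follows the trunk at a fixed lumbopelvic ratio of
  0.4; arms hang vertically during trunk movements, follow the trunk during
  axial rotation, and articulate at the shoulders during the shoulder
  calibration movements.
* Sensor imperfections: white gyro noise 0.01 rad/s, accelerometer noise
  0.05 m/s², random mounting misalignment up to 10°, accelerometers output
  specific force (gravity included) per IMU convention.
* The EMG forward model is linear in the moment with half-wave
  rectification and bilateral asymmetry: each channel's noise-free
  envelope is $\mathrm{gain}\cdot\max(0,\; a M_y + b\lvert M_x\rvert +
  c\lvert M_z\rvert)$ with side-dependent $(a, b, c)$, plus a small tonic
  floor; the raw signal is that envelope modulating a zero-mean white
  carrier at 1 000 Hz, plus additive noise (amplitude SNR ≈ 10) and 5%
  bilateral cross-talk. This is the *minimal* structure under which an
  EMG-driven estimator can demonstrably recover moments; it contains no
  activation dynamics, force–length/velocity relations, fatigue, ECG
  contamination or motion artifact.

Consequently, passing tests show that the estimation chain is correct and
well conditioned under physiological signal structure — they do not show
field accuracy on real tissue-borne signals, where EMG–moment relations
are nonlinear and nonstationary. One visible consequence of the symmetric
simulator postures (shared with real quasi-symmetric tasks): axial net
moments are small, since gravity contributes no moment about the
longitudinal axis, so rotation-axis correlations land in the moderate band
(r ≈ 0.5–0.6) — matching the moderate rotation-axis agreement reported for
this class of method, while bending and lateroflexion axes reach r > 0.99.

## Statistics

* Curve agreement: per-axis RMSE and Pearson r (r²), with r banded at the
  0.1 / 0.5 / 0.7 / 0.9 cutpoints (weak / moderate / good / very good). A
  zero-variance channel has an undefined r and is reported `NA`, never 0.
* Task descriptives: mean, peak (max) and "variance" — the within-trial
  standard deviation, sample (n − 1) denominator — of
  $\lVert\mathbf{M}\rVert$.
* Direction splits partition samples by the sign of an axis component;
  exact zeros belong to neither segment, and descriptives within a segment
  use magnitudes. The nonnegative norm channel is split by the sign of the
  per-sample dominant component — an interpretation, flagged as such, since
  a norm has no sign of its own.
* Paired comparisons gate on a Shapiro–Wilk test of the paired differences
  using the conventional reading (normal if p > 0.05), recording the gate
  p-value so the opposite reading can be audited; the t-based 95% CI of
  the mean difference is always reported. Relative differences are emitted
  two ways — mean of per-pair percentage differences, and 100·MD divided by
  the reference-group mean — because published summaries are ambiguous
  between the two.
* Task selection: light/heavy by lowest/highest checklist rank (ties broken
  by Borg, then trial order); static requires the lumbar posture (trunk
  relative to pelvis) to stay within 3° of a held working posture for at
  least 4 s, measured as rotation relative to the window start so constant
  mounting offsets cancel; dynamic is the non-static task with the most
  varying posture. The heavy and dynamic roles may select the same trial —
  the simulator emits a combined heavy+dynamic task by default, mirroring
  how such tasks co-occur in real job inventories.

## Problem sizes used in validation

The shipped validation suite runs entirely at desk scale, chosen to
exercise every code path with comfortable statistical margins: full
simulated sessions of ~18 trials (about 7 minutes of 50 Hz data, EMG at
1 kHz), 20 seeds for training-convergence and hold-out-agreement checks, 50
seeds for synchronization recovery, and 20 seeds for calibration parameter
recovery. `scripts/acceptance.R` recomputes the headline quantities from
scratch on the same scales.

## Known limitations

* The anthropometric table is a population average; no subject-specific
  segment calibration beyond global height/mass scaling.
* The trunk above L5/S1 is treated as one rigid segment oriented by the
  sternum sensor; spinal curvature changes are not modeled.
* The LSM ignores the moving-point correction when the root accelerates
  (standard practice in top-down ambulatory formulations; exact when the
  pelvis is quasi-stationary).
* Per-session training does not transfer across subjects or days; that is
  inherent to the method, not an implementation limit.
* The simulator's EMG model is linear by design; estimator performance on
  real nonlinear EMG will be worse and must be established on recorded
  data.
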