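---
title: "Real-time musculoskeletal analysis: models, filters and forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time musculoskeletal analysis: models, filters and forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtmsk)
```

# Overview

`rtmsk` implements a streaming analysis chain for human-movement data:
observed marker positions and/or IMU orientations are turned, frame by
frame, into generalized coordinates (inverse kinematics), differentiated
under noise (causal filtering), and propagated through rigid-body
mechanics to joint moments (inverse dynamics), predicted ground reaction
wrenches, muscle tensions (static optimization) and joint reaction
loads. Every stage is exercised on bundled synthetic fixtures — a
pendulum, a double pendulum and a 9-DoF planar walker — whose mechanics
have closed forms, so the whole chain is testable without laboratory
data.

This vignette records the models, the tunable parameters, and the
design choices made where the problem statement was genuinely open.

# Rigid-body model

A model is a tree of rigid segments connected by joints (`revolute`,
`free_planar` with 3 DoF, `free_spatial` with 6 DoF), rooted at the
ground. The ground frame is y-up, x along the walking direction, z
lateral; angles are radians and lengths meters internally. Coordinates
are ordered depth-first with the base joint first, so the floating-base
block — where non-physical *residual forces* absorb model/data
inconsistency — is always the leading block of every generalized-force
vector.

Internally each joint is expanded into elementary one-DoF prismatic and
revolute elements plus a fixed child-frame element. The velocity and
acceleration recursion then needs only two primitives, and generalized
forces are exact axis projections of subtree wrenches. This is the same
computation as a classical recursive Newton–Euler pass, organized for
transparency over raw speed; on the bundled fixtures it agrees with an
independently derived Lagrangian closed form to ~1e-12 relative.

Orientation data are carried as unit quaternions (scalar-first); the
kinematic recursion itself runs in rotation-matrix form and converts at
the boundary, normalizing on conversion.

Rather than parsing a full musculoskeletal model format, models load
from a small declarative YAML schema (`segments`, `joints`, `markers`,
`imus`, `muscles`) that carries exactly the fields the pipeline needs.

# Inverse kinematics

Each frame solves a weighted nonlinear least-squares problem over the
coordinates `q`: squared marker position errors plus squared
orientation errors, each with per-target weights (default 1). The
orientation residual is the geodesic angle (the norm of the rotation
log of the relative rotation) represented as its 3-vector log, which
makes the problem a standard stacked-residual least squares. Tree
models have no holonomic loop constraints, so the constraint-penalty
term is identically zero; the argument exists for models with loop
closures, and we chose a penalty (not a hard constraint) formulation
for that case because it keeps the per-frame solver unconstrained.

The solver is damped Gauss–Newton (Levenberg–Marquardt) with a numeric
Jacobian, warm-started from the previous frame. The stopping rule is a
step-norm below 1e-10 or a vanishing gradient, capped at 100
iterations; a non-converged frame returns the best iterate, flagged.
Descent is guaranteed because steps are only accepted when the
objective does not increase.

**IMU calibration.** A static trial in the model's default pose gives
each sensor's mean orientation (averaged by the dominant eigenvector of
the outer-product sum of quaternions). The constant offset applied to
every stream for the rest of the session composes an Earth-to-model
frame change with a heading rotation about the vertical that aligns the
horizontal projection of the base sensor's anterior axis with the
model's +x. Using only the horizontal projection means pitch/roll tilt
of the base sensor cannot corrupt yaw alignment.

**Marker completion.** A missing marker on a segment with at least
three visible markers is reconstructed by the rigid (orthogonal
Procrustes/Kabsch) transform fitted from the visible markers'
model-frame to world positions; otherwise its last known position is
held and the frame flagged. The completion step never hard-fails.

# Real-time filtering and differentiation

Inverse dynamics multiplies accelerations by inertia, so raw
double-differentiation of noisy coordinates is useless; the filter is
the pipeline's accuracy bottleneck. Four hyper-parameters: buffer
memory `M` (samples), FIR cutoff `fc` (Hz), spline order `Ns`, and
evaluation lag `D` (samples), with sampling rate `fs`.

Each step, the newest sample enters a circular buffer of `M` samples
per channel. The window is low-pass filtered with a length-`M`
windowed-sinc FIR (Hamming window, coefficients normalized to unit DC
gain), a cubic smoothing spline is fitted to the filtered window with
its smoothing level chosen by generalized cross-validation (GCV), and
the spline and its first two derivatives are evaluated at the delayed
time `t_d = t - D/fs`. Evaluating behind the newest sample is the core
trade: a deliberate lag of `D` samples buys near-non-causal accuracy.

Numerical choices worth recording:

- *Window edge handling.* A length-`M` kernel applied to a length-`M`
  window has full support at only one sample, so some boundary rule is
  unavoidable. We convolve zero-phase ("same" alignment, which for a
  symmetric kernel introduces no group delay) after extending the
  window by odd (point) reflection about its endpoints. Point
  reflection preserves value and slope at the ends; the residual edge
  bias is quadratic in signal curvature and decays toward the window
  interior — which is exactly where `t_d` sits for sensible `D`. A
  strict "fully-overlapped positions only" rule would leave a single
  usable sample and no support for a spline.
- *GCV each step.* The smoothing level is re-estimated on every window
  rather than frozen; this keeps the filter parameter-free beyond the
  four hyper-parameters, at the cost of some step-to-step variance of
  the effective smoothing. Windows with (near-)zero variance short-cut
  to an exact constant with zero derivatives, and degenerate GCV fits
  fall back to an exact cubic polynomial fit.
- *Spline order.* Only `Ns = 3` (cubic) is implemented — a reasonable
  order that avoids over-fitting when second derivatives are the
  target, and the only order the underlying GCV spline supports.
- Channels (generalized coordinates) are filtered independently.

Defaults for gait at 100 Hz: `fc = 6` Hz, `M = 35`, `D = 14`,
`Ns = 3`. With these, the reported evaluation lag is exactly
`D/fs = 0.14 s`; output timestamps carry `t_d` explicitly rather than
silently shifting the series.

**Hyper-parameter selection.** `tune_hyperparameters()` scans an
`(M, D)` grid at fixed `fc` and `Ns`, scoring coordinate, speed and
acceleration RMSE against a comparator — either analytic truth
(synthetic data) or `offline_reference()`, the non-causal whole-trial
counterpart (zero-phase low-pass, then one GCV spline over the full
record). The selected point minimizes *acceleration* RMSE, the error
that dominates downstream dynamics; ties break toward smaller `M`
(less latency and memory), then smaller `D` (less lag).

A note on a property one might expect: an ideal cubic spline
reproduces cubic polynomials and their derivatives essentially exactly.
Through the full offline path the FIR's passband bias (the kernel's
nonzero second moment) perturbs cubic first derivatives at the ~1e-4
level for unit-scale signals; the tests assert exact linear
reproduction and bound the cubic case accordingly.

# Inverse dynamics and residuals

Given a full state `(q, u, a)` and external wrenches (point + force +
moment in the ground frame), generalized forces are computed by
projecting each coordinate's subtree wrench — inertial terms
`m(a - g)` and `I w' + w x (I w)` minus applied loads — onto the joint
axis. Gravity is `(0, -9.80665, 0)` m/s². The floating-base block of
the result is reported as the residual force/moment diagnostic; with
dynamically consistent inputs it vanishes to machine precision, and
`residual_report()` tracks its running RMS. A fixed-step RK4
forward integrator exists purely as test support to close
torque–motion–torque round trips.

# Ground reaction prediction

Assuming ground reactions are the only external loads, the total
reaction wrench follows from whole-body Newton–Euler sums:
`f_total = sum m_i (a_i - g)` and, about the ground origin,
`tau_total = sum [I_i w_i' + w_i x (I_i w_i)] + sum c_i x m_i (a_i - g)`.
The per-endpoint moment formulation is algebraically absorbed into
these resolved sums, since the per-foot wrenches are the unknowns being
solved for.

**Phase machine.** Per-leg raw detections compare a generic measure
`u(t)` with a threshold `v_th`; the committed phase flips only after
`k` consecutive opposite detections, and events are time-stamped at the
first sample of the committing run. The default measure is the negated
heel-endpoint clearance with `v_th = -0.02` m (i.e. "heel within 2 cm
of the ground") and `k = 3`; any external signal (insole pressure,
acceleration) can be supplied instead, and precomputed event streams
can bypass detection entirely. Double- and single-support durations are
estimated online from heel-strike-to-toe-off and
toe-off-to-heel-strike intervals, or supplied when known.

**Distribution.** In single support the stance leg carries the whole
wrench. In double support the indeterminacy is resolved by the smooth
transition assumption: in the walking frame (yaw from the circular mean
of the pelvis anterior axis's horizontal projection), the trailing
leg's wrench is the total wrench *frozen at the leading leg's
heel-strike*, scaled element-wise by a monotone transition function
with `f_t(0) = 1` and `f_t(T_ds) = 0`; the leading leg takes the
remainder. The frozen value is held for the entire double support. The
default shape is the cubic smoothstep `1 - (3 s^2 - 2 s^3)`, identical
for all six components; the shape is injectable (including tabulated
per-component curves) since published per-component forms vary.
Conservation — leading plus trailing equals the total, element-wise —
holds to machine precision by construction.

**Center of pressure.** During single support the CoP travels from the
heel to the metatarsophalangeal (MTP) projection along
`sigma(t) = -(2/(3 pi)) (sin wt - sin(2wt)/8 - (3/4) wt)`,
`w = 2 pi / T_ss`: monotone from 0 to 1 with zero slope at both ends
and `sigma = 1/2` at mid-stance. During double support the trailing
foot's CoP is pinned at its MTP projection and the leading foot's at
its heel projection, which makes the trajectory continuous at both
transitions; the scaling law governs single support only. Per-leg
moments are re-expressed about the assigned CoP before output.

# Muscle redundancy

With more muscles than actuated coordinates, tensions are resolved per
frame by minimizing `(1/p) sum_i (f_i / fmax_i)^p` subject to the
moment balance `tau = R(q) f` on the actuated coordinates only and
`f >= 0` (muscles only pull; no upper bound, so no reserve actuators
are needed). Excluding the floating base removes exactly six equality
constraints for a spatial base (three for the planar walker) and keeps
non-physical pelvis forces out of the optimization.

Moment arms are `-d(path length)/dq`, computed from straight-line
paths by central differences (step 1e-6) and approximated, for speed,
by per-muscle multivariate polynomials (total degree 4 by default) in
the coordinates that muscle actually spans (spanning detected by
sweeping each coordinate and thresholding at 1e-6 m). Sampling uses 9
points per spanned coordinate over its range, full tensor per muscle —
spanned sets are small, so the tensor stays tiny.

`p = 2` is the default: the problem is then a strictly convex QP with
a unique optimum, solved exactly by a primal active-set method on the
KKT system (bounded by 200 iterations, warm-started from the previous
frame's active set). `p = 3` is solved by an augmented-Lagrangian outer
loop around a bounded quasi-Newton inner solver, warm-started from the
`p = 2` solution. The balance residual is reported; when the demanded
moment lies outside the cone of nonnegative muscle forces the result is
flagged `infeasible` and a nonnegative least-squares fallback is
returned with its residual.

# Joint reaction loads

Solved tensions are applied as point forces along each muscle's path
(equal and opposite at the ends of every path segment, as for an ideal
string); the net generalized force of these point loads reproduces
`R(q) f` — a built-in consistency check between the path geometry and
the moment-arm model. Each joint's reaction is then the distal
subtree's inertial wrench minus all gravity, muscle and external loads
applied to it, resolved at the joint center, expressed in the ground
frame, acting on the child segment (the convention used by standard
joint-reaction analyses; the frame of expression is a choice we made
explicit since comparisons are frame-sensitive). Dynamic inconsistency
is not redistributed — it surfaces in the base joint's reaction,
mirroring the residual diagnostic.

# Synthetic data: what it does and does not show

The walker's gait is a band-limited surrogate: each coordinate is
`offset + sum_k amp_k sin(2 pi k t/T + phase_k)` with analytic first
and second derivatives, a 1.2 s cycle, 15% double-support fraction per
transfer and 1.2 m/s progression; waveform amplitudes are in the range
of slow walking but are not validated gait curves. Markers add iid
Gaussian noise and Bernoulli occlusions; IMUs add small-angle noise and
a linear yaw drift. All synthesis is seeded and bit-reproducible.

Ground-truth per-leg wrenches are *defined* by the same transition
rules the predictor implements, driven by the closed-form gait schedule
instead of the streaming detector. Round-trip agreement therefore
verifies the implementation — phase bookkeeping, frame changes,
distribution algebra, CoP assignment, and consistency between the
total-wrench summation and the independent recursive-dynamics path
(near-zero base residuals) — not the biological fidelity of the smooth
transition assumption, which can only be judged against force plates.
In the round-trip tests the predictor receives the generator's event
stream (as if from instrumented timing) and known support durations;
its online detector and duration estimator are tested separately.
Because the streaming predictor needs one gait cycle to acquire its
phase state, round-trip comparisons start after the first cycle.

Problem sizes used by the test-suite and verification runs: 2.4–10 s
trials at 100 Hz on the 9-DoF walker, 100-state oracle sweeps on the
double pendulum, and a 10^6-point brute-force grid for the `p = 3`
muscle objective — sizes chosen so every check has a meaningful, fully
recomputed oracle.

# Known limitations

- Straight-line muscle paths with via points; no wrapping surfaces.
- No subject scaling/calibration from static trials; fixtures are
  parameterized directly.
- The gait schedule assumes alternating, periodic walking; running
  (flight phases) and stairs are out of scope.
- R is single-threaded, so the two-thread acquisition/processing
  architecture is emulated by an interleaved event loop through the
  same bounded buffer; replay mode is bit-identical by construction
  and the buffer's ordering/overflow semantics are what the tests pin
  down.
- Orientation estimation from raw gyro/accel/mag is out of scope; the
  package consumes orientation streams.
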