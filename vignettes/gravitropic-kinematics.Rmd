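---
title: "Gravitropic kinematics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gravitropic kinematics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coleokin)
```

This vignette is the package's own account of the science it
implements: the posture-control model, the kinematic estimators, the
synthetic-data generator, and the numerical and design decisions behind
them. Everything quantitative stated here is computed by the test suite
or the `analysis/` scripts; nothing is quoted from elsewhere.

## Geometry and conventions

An elongating plant axis (the motivating system is the wheat
coleoptile, a dark-grown grass sheath 10–20 mm long) is described by its
planar midline. Arc length `s` runs **from the apex**: `s = 0` at the
tip, `s = L(t)` at the base. The local orientation `A(s, t)` is the
zenith angle of the axis in radians — 0 when the element points
vertically up, `+pi/2` when horizontal, clockwise positive — and the
curvature is its arc-length derivative `C = dA/ds`. Times are in hours,
lengths in mm. Many kymograph tools put the origin at the base; here
every field, including the advection integral below, is apex-origin, so
base-origin data must be reversed on input.

Growth is quantified by the relative elongation growth rate (REGR)
`E(s, t)` in h^-1. Because arc length is measured from the apex, a
material element's distance from the tip grows at
`v(s, t) = Int_0^s E(s', t) ds'`, and the curvature change experienced
by the moving tissue is the material derivative

```
DC/Dt = dC/dt + v(s, t) * dC/ds .
```

Its sign convention: positive means the co-moving element is becoming
more curved (in the clockwise-positive sense of `A`).

## The posture-control model

The dynamics couple two sensory drives inside the apical growth zone of
length `L_gz` (tissue outside the zone is frozen and merely advected):

```
DC/Dt = -beta * g(A) - gamma * C        (inside the zone)
```

with graviceptive gain `beta` (mm^-1 h^-1), proprioceptive gain `gamma`
(h^-1), and `g` either `sin` or its small-deflection linearization
`g(A) = A`. The base is clamped at the tilt angle and `A` follows by
integrating `C` from the base. The fixed point satisfies
`gamma * C = beta * sin A`: a basal curved region whose extent is set by
the decay length `L_eff / B`, where `B = beta * L_eff / gamma` is the
dimensionless balance number and `L_eff = min(L0, L_gz)`.

`simulate_ac()` integrates this law by explicit Euler on a base-anchored
grid (trapezoid integration of `C` into `A`; first-order upwind
advection when growth is on; stability requires `dt * gamma < 0.5`, the
default is `0.002 / gamma`). The emitted kymographs are re-expressed in
the apex-origin convention so that the curvature field is exactly the
arc-length derivative of the orientation field.

**Overshoot and the critical balance number.** A tilted organ with small
`B` relaxes to vertical monotonically; a large-`B` organ swings past
vertical. `overshoot_predicate()` flags a series whose tip angle passes
below `-delta` (default dead band 0.02 rad, rejecting numerical
ripple). `critical_balance_number()` pre-scans `B` on a coarse grid,
asserts the indicator is monotone, and bisects. The transition depends
on the response form: with the linearized response it sits near 2.9 (at
the 0.02 rad dead band; 2.79 for a bare sign change), consistent with
the conventional threshold of 2.8 used for morphometric overshoot
prediction, while the full `sin` response places it near 3.3. Both
switches are exposed; the linear form is the default for the threshold
computation precisely because it is the formulation under which the 2.8
classification threshold is self-consistent, and `analysis/01` reports
both values side by side.

## Kinematic estimators

**Orientation and curvature.** Midlines are resampled to uniform arc
length (default 0.1 mm for geometry, 0.25 mm in the pipeline), tangents
are taken by centered differences with second-order one-sided stencils
at the ends (a first-order stencil carries a half-step angle bias that
corrupts edge curvature), angles are unwrapped along `s`, and curvature
is the Savitzky–Golay-smoothed derivative. Default smoothing: local
quadratic over 1.5 mm in `s` and 3 frames in `t`, applied within
contiguous supported runs only so values never bleed across the organ
boundary. On exactly sampled circular arcs of radius 5–100 mm the
recovered curvature is accurate to well under 1%.

**REGR by 1-D image correlation.** Marker intensity profiles (orange
fluorescent dust in the motivating experiments) are compared between
frames by windowed normalized cross-correlation: window 2 mm, 75%
overlap, search ±1 mm per interval (sized to cap implied growth at
4 mm/h), Gaussian (log-parabola) sub-sample peak interpolation. Three
details matter at realistic marker densities:

* the correlation peak measures the displacement of the window's marker
  *texture*, i.e. at its intensity-squared centroid rather than the
  geometric center — estimates are placed at the centroid and resampled
  to a regular grid, removing the first-order bias under strain;
* the apex is an exact anchor (`v(0) = 0` because arc length is
  measured from the apex in every frame), which stabilizes the apical
  boundary of the velocity profile;
* strain is obtained from the velocity profile by a Savitzky–Golay
  first-derivative filter over a 3 mm baseline (one-sided fits at run
  ends).

The per-window error of the correlation peak (~1–3 µm) is set by the
texture, not the displacement, so correlating frames further apart
improves the strain signal-to-noise proportionally; the pipeline
default is `frame_step = 2` (a 30-minute interval at the 15-minute
cadence), and each REGR row is time-stamped at the midpoint of its
interval — the average strain rate over an interval estimates the rate
at its center, and labelling it at the earlier frame would shift the
phase of any oscillation. Windows with flat texture, a peak on the
search bound, or a peak correlation below 0.6 are masked (a displacement
outside the search range can still alias onto a similar-looking marker
within range — the search range must be sized generously). Uniform
strain rates in 0.005–0.05 h^-1 are recovered within 5%.

**Material derivative.** `material_curvature_derivative()` combines the
partials (SG derivative filters; the time window is 5 frames in the
pipeline to tame frame-to-frame tracking noise, 3 = plain centered
differences at the function level) with the advection integral taken
from the apex, interpolating the curvature partials at the REGR rows'
midpoint time stamps. On smooth analytic fields it agrees with explicit
co-moving point tracking to better than 10^-3 mm^-1 h^-1 and
annihilates a co-moving wave.

**Oscillations.** Pulses are characterized exactly as a peak-based
procedure: thresholded local maxima along time at each station (default
threshold: the 0.7 quantile of supported values; a 1 h minimum
separation suppresses noise doublets), greedy nearest-neighbour linking
into tracks (gap ≤ 0.75 h, jump ≤ 8 mm; ties broken by smallest jump,
then earliest track), and a least-squares line through each crest locus
`s = vp (t - t0)`. Three accuracy measures proved necessary at a
15-minute cadence:

* peak times are refined to sub-frame precision by a local quadratic
  fit over ±2 frames — frame-quantized peak times otherwise attenuate
  the fitted velocity;
* the per-track line is fitted as `t` on `s` and inverted (the
  quantized coordinate belongs in the response), and the per-organ
  velocity is a pooled common-slope fit across all tracks, since every
  pulse of one organ travels at the same speed;
* the period is the span-over-intervals estimate at each of the five
  most strongly oscillating, mutually separated stations, with the
  interval count inferred from the median inter-peak spacing (a missed
  mid-train peak would otherwise inflate the estimate by one part in
  `n`), and the median across stations is reported.
  `period_estimate()` retains the bare span/`n` arithmetic.

Stations within 2 mm of the apex or beyond the growth zone are excluded
from tracking: the former sit inside the derivative baseline (flattened
pulse phase), the latter carry no growth signal. On 20 synthetic plants
with periods drawn from 2.5–3.5 h and speeds from 8–17 mm/h the median
relative recovery error is a few tenths of a percent for the period and
3–4% for the velocity.

## Morphometrics

`effective_length()` takes the apical contiguous extent where the
time-averaged REGR exceeds a threshold (default 20% of peak), capped by
the initial organ length. `curved_zone_length()` measures, once the
curvature variation has settled (mean |DC/Dt| in the final 2 h below 5%
of its peak, with a floor at 1.3× the measurement-noise level estimated
from the sub-zone region where DC/Dt is structurally zero), the final
arc-length extent where |C| exceeds `exp(-1)` of its peak. Two choices
here deserve emphasis, both forced by the mathematics of the fixed
point:

* the `exp(-1)` threshold makes `L_c` equal the decay length of an
  exponentially relaxing curvature profile, so the morphometric ratio
  `B = L_eff / L_c` estimates the dynamic `beta * L_eff / gamma`
  directly (a 10% threshold would measure 2.3 decay lengths and bias
  `B` low by the same factor);
* `L_c` is measured within the growth zone. In an elongating organ,
  tissue leaving the apical zone freezes mid-bend, so the whole-organ
  curved extent grows indefinitely with time and no longer reflects the
  sensory balance.

With both, the morphometric `B` of simulated pulse-free organs tracks
the true dynamic `B` within ~20% over `B` in 1–4 and the predicted
overshoot flags (`B > 2.8`) match the simulated outcomes.
`classify_plant()` refuses a balance number for upright-control plants
— it is a gravitropic quantity — while still reporting the observed
flag.

## The synthetic-data generator

`generate_coleoptile_series()` emulates a darkroom tilting assay:
15-minute frames over 24 h; initial length 10–20 mm; apical growth zone
(default 12 mm) with baseline REGR 0.036 h^-1 (≈ 1e-5 s^-1) decaying
smoothly at its basal edge (logistic taper, 0.75 mm — real REGR
profiles fall off gradually, and a razor edge is unresolvable by
windowed correlation anyway); propagating pulses
`sin(2*pi*(t/Tp - s/(vp*Tp)))` modulating the REGR (relative amplitude
0.4) and the differential-growth fraction `Delta` (amplitude 0.4,
radius 0.5 mm) whose curvature production `E * Delta / R` is added to
the posture law; and a controllable phase `delta_phase` between the two
waves — `pi` for the tilted treatment, 0 for the upright control —
which fixes the sign of the correlation between the two kymographs.
(The same wave evaluated with the literal alternative form from the
idealized-wave illustration is available behind `literal_form = TRUE`;
that form has temporal period `2*pi*Tp` and apex-ward crests, so the
default generator uses the corrected form.)

Observation noise: midline coordinates receive spatially correlated
Gaussian noise (sd 1 µm, correlation length 0.5 mm). Contour-derived
midlines average hundreds of pixels, so their residual error is small
and smooth along the organ — iid per-point noise of any visible
magnitude is the wrong model and overwhelms any curvature-rate
measurement. Marker profiles are Gaussian bumps (σ = 0.15 mm, 8 per mm,
amplitudes 0.5–1) advected materially, with additive intensity noise
(sd 0.01). All randomness derives from one seed; a fixed seed
reproduces every file byte for byte.

What the generator does *not* emulate: photorealistic images, contour
extraction, leaf piercing, nutation, phototropism, or elasticity. A
passing pipeline therefore demonstrates correctness of the kinematic
chain downstream of midline extraction, not robustness to segmentation
errors in real photographs.

**Pipeline closure.** Running the full measurement chain on generated
observables recovers the ground-truth REGR kymograph with a relative
RMS error of 15–22% and the DC/Dt kymograph within ~25–32% at the
default noise (the generator property test asserts these levels).
Tighter closure is not attainable by this chain: DC/Dt is a double
spatial plus single temporal differentiation of tracked coordinates,
and the smoothing needed against noise attenuates the sharp early
gravitropic transient, which dominates the field's variance — the
noise-free floor is already near 10%. Estimates of *derived* quantities
(periods, velocities, coupling sign, balance numbers) are far more
accurate than the pointwise fields, which is why the pipeline's
summaries, not its raw kymographs, carry the statistics.

## Statistics

`fisher_exact()` computes exact hypergeometric tail probabilities for a
2×2 table; the two-sided p sums all tables (given both margins) whose
point probability does not exceed the observed one. The odds ratio
reported is the sample cross-product ratio — the quantity
conventionally printed alongside this test — with a Wald 95% interval
and the caveat that interval constructions differ. For the
predicted-vs-observed overshoot comparison of a 54-plant tilted cohort
(16 predicted, 5 observed), the right-tailed reading reproduces the
printed p = 0.0069 with odds ratio 784/190 ≈ 4.13; the two-sided value
is ≈ 0.0137. Both tails are always reported.

`mann_whitney_u()` computes the rank-sum U with midranks; the exact
two-sided p enumerates the full permutation null for pooled sizes up to
20, otherwise a tie-corrected normal approximation with continuity
correction. `kymograph_correlation()` is the Pearson correlation over
jointly supported cells, optionally restricted to the growth zone — the
pipeline restricts, because below the zone both fields are structurally
zero and only dilute the coupling. No multiple-testing correction is
applied anywhere; every comparison is reported raw.

## Problem sizes and runtimes

The simulations behind the test suite and analyses were sized for
precision at interactive runtimes: the overshoot bisection runs the
nondimensional model on 101 spatial points with `dt = 0.002` for 40
time units (transition located to ±0.025); recovery and coupling
experiments use cohorts of 20 plants per condition at the full 24 h /
15-min study cadence; the analysis scripts use a 12 + 12 cohort. The
classification analysis uses pulse-free plants because the curved-zone
measurement presupposes that curvature variation ceases, which
sustained differential-growth forcing prevents by construction.

## Known limitations

* The coupling correlation of measured kymographs is diluted toward
  zero by measurement noise and the early transient; its sign and group
  contrast are robust, its magnitude is conservative.
* Curvature-variation pulse velocities measured on DC/Dt kymographs of
  tilted plants are biased low by the superposed gravitropic transient;
  REGR-based estimates are the accurate ones and carry the recovery
  guarantees.
* DIC displacement beyond the search range can alias onto a
  similar-looking marker within range; the search range must be chosen
  to cover plausible growth rates.
* The balance-number correspondence (dynamic vs morphometric) degrades
  for organs much longer than their growth zone observed over long
  times, because exited tissue keeps its curvature; the zone-restricted
  `L_c` mitigates but cannot remove this for very small `B`.
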