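---
title: "Methods: time-based and path-based analysis of upper-limb use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-based and path-based analysis of upper-limb use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbuse)
```

## The measurement problem

Clinically useful monitoring of upper-limb use at home has to answer two
questions from wearable data alone: *how much* is each arm used, and *how*
— unimanually or bimanually. `limbuse` answers the first with time-based
segmentation (fixed 0.25 s quants scored by accelerometer activity counts
and EMG muscle counts) and the second with path-based segmentation
(completed movements scored by four coordination criteria combined into the
bimanual movement parameter, BMP).

The input model is deliberately minimal: hand position and hand
acceleration expressed in a trunk-fixed frame on a shared 80 Hz clock, trunk
acceleration, a gravity vector (constant or per-sample), and optionally
8-channel normalized forearm EMG at 200 Hz per limb. The limbs are labelled
`uaf` (unaffected, or dominant for healthy subjects) and `af` (affected /
non-dominant); every ratio statistic puts `uaf` in the numerator, so
positive log-ratios mean the unaffected limb did more.

## Time-based track

Activity counts per quant are the time-average of the norm of the
band-passed hand acceleration. The band (0.25–2.5 Hz) brackets the
frequency content of voluntary arm movement; it is applied per component
with a fourth-order zero-phase Butterworth filter (two poles per edge,
forward–backward), so quant boundaries are not shifted by group delay.
Three correction modes exist because a band-pass alone does not remove
gravity when the trunk tilts: `raw` uses the acceleration as measured,
`minus_gravity` subtracts the gravity vector, `minus_trunk` subtracts the
trunk accelerometer signal (which also removes gravity, since the trunk
sensor measures it too). Subtraction happens before filtering; because the
filter is linear the order is immaterial when both signals see the same
filter, and the property suite verifies the gravity effect on a synthetic
session with a slowly tilting trunk.

The ratio statistic is `ln((x_uaf + 1)/(x_af + 1))`. The +1 offset keeps
idle quants (both counts zero) at ratio 0 and tames the positive skew of
raw ratios; it does make the statistic depend on the measurement unit,
which we accept to keep the published form. Integrals use the trapezoidal
rule on the native sample grid, and `T × rate` must be an integer (0.25 s
× 80 Hz = 20 samples; × 200 Hz = 50 samples) so quant edges land exactly
on samples. A trailing partial quant is discarded rather than padded.
Dwell-time grids clip out-of-range quants to edge bins, so total dwell is
conserved exactly — a property the suite asserts with `identical()`, not a
tolerance.

Windowed path-length ratios (1/3/5 s windows) have *no* +1 offset —
lengths are in metres and an additive offset would dominate them — so
windows in which either limb traversed less than 1 mm are flagged invalid
and excluded instead of being evaluated to ±∞.

## Speed estimation

Both tracks need a speed estimate that reads ≈ 0 at rest despite sensor
noise. `hand_speed()` differentiates each position component with central
differences, low-passes the velocity components (second-order zero-phase
Butterworth, default cut-off 5 Hz — above the bandwidth of reaching
movements, low enough to suppress differentiated sample noise), and takes
the norm. Filtering components before the norm keeps the estimate exactly
rotation-invariant and unbiased at rest (norm-first estimators rectify
noise into a positive floor). All zero-phase filters pad the record by odd
reflection before filtering; without padding, a limb resting away from the
origin acquires a large zero-state transient at the record edges.

With the default 2 mm position noise at 80 Hz, the resulting speed noise
floor at rest is ≈ 0.018 m/s on average (99th percentile ≈ 0.038 m/s).
This number drives a key default: the rest threshold must sit above it.

## Path-based segmentation

A continuous trajectory is split at two kinds of boundaries:

*Rest*: the smoothed composite speed (`max` over the two limbs, so a
unimanual movement of either limb is captured) stays below `rest_speed`
(default **0.05 m/s**) for at least `rest_min_duration` (0.2 s). The
threshold is set just above the measured noise floor quoted above; a
threshold at or below the floor never detects rest on realistic noise
levels. Within a detected rest span, the preceding movement terminates at
the *first* near-minimum-speed sample and the next begins at the *last*
one. The near-minimum band is `max(s_min + 1e-9, min(rest_speed/2,
3·s_min))`: on noise-free data only the true zero-speed samples qualify,
which places boundaries exactly at stroke endpoints and hexagon vertices;
on noisy data the band opens up so the bracketed stillness is excluded
from both neighbours. A consequence of the stop-to-stop convention is that
movements include the bordering deceleration into, and acceleration out
of, stillness; reported onsets can precede the visible motion by a few
tens of milliseconds.

*Direction change*: the trajectory is low-passed at 10 Hz (above the
speed cut-off, so corners are barely rounded, while arc-scale sensor noise
— which otherwise dominates tangent directions — is suppressed), resampled
at uniform 10 mm arc steps, and the angle between mean tangent directions
of two 20 mm windows separated by a one-step gap is computed at every
resampled point. The gap absorbs what corner rounding remains. Local
maxima above `heading_threshold` (45°, chosen below the 60° heading change
at a regular hexagon vertex) are boundaries, after non-maximum suppression
at two window widths and refinement to the sample that maximizes the local
chord angle (the arc grid alone quantizes boundary position to ±5 mm).

Candidates shorter than `min_movement_length` (50 mm) are dropped — not
merged into a neighbour, since only completed movements above the floor
are of interest. Candidate length is measured as the larger of the raw
endpoint displacement (exact and noise-immune for straight strokes,
including a side exactly at the floor) and the smoothed-trajectory
polyline length (which catches curved movements); raw polyline lengths are
never used for gating because position noise inflates them by roughly
0.3 m per second of dwell. Segmentation is invariant under rigid
transforms, and direction-change boundaries under time re-scaling, both
asserted in the suite.

## Movement metrics and the BMP

Per-movement path length integrates the smoothed speed (trapezoid) over
the shared segment — equivalent to the polyline for clean data, robust for
a noisy near-stationary limb. PCC, RV and F all operate on the two speed
profiles over the shared window, as functions of time at the native rate
(no arc-length warping and no alignment before the Fréchet distance — the
point of F is precisely to penalize temporal misalignment). The discrete
Fréchet distance uses the scalar metric |a − b| and a standard dynamic
program; the test suite pins it to an exhaustive enumeration of monotone
couplings for all sequence lengths up to 6.

Speed mean and variance use the sample mean and the unbiased (n − 1)
variance over the segment's samples.

The BMP averages four normalized penalties with weights
`α_PCC = 2, α_RV = 5.5, α_F = 1.3, α_RL = 2.5` (each weight scales its
criterion by its empirical 95th-percentile magnitude, so one fully violated
criterion costs at most ¼) and is clamped to [0, 1]: the formula can go
negative when criteria exceed their caps, and clamping is the mechanism
that makes the normalization claim exact. Classification uses
`BMP < 0.4` → unimanual, `BMP > 0.7` → bimanual, the closed middle band →
unclassified.

Degenerate movements are kept total rather than erroring: a zero-variance
speed profile contributes the neutral PCC value 0 with a flag; log-ratios
with a numerator or denominator at the floor (1 mm for lengths, 0 for EMG
power) saturate at ±6 with a flag. Flagged values are excluded from
distribution summaries (the caps are artifacts of the saturation rule, not
data) but counted in `n_flagged_excluded`. Kurtosis is reported in the
Pearson (non-excess) convention — a normal sample reads ≈ 3.

## Synthetic data: what it does and does not establish

The generators produce the study conditions used for validation:
minimum-jerk strokes (fifth-order polynomial, zero endpoint velocity and
acceleration, peak speed 1.875 D/T — the standard model of point-to-point
reaching), hexagon tracing with exact stroke counts and 60° vertex turns,
coordinated symmetric bimanual sessions (identical stroke schedules, with
±2% timing jitter and 2% amplitude jitter on the affected limb by
default), and strictly unimanual sessions (passive limb stationary up to
sensor noise, its EMG baseline noise only). Default scales: 0.3 m strokes
of 1 s with 0.5 s gaps, 2 mm position noise on both limbs (sensor noise is
a property of the sensors, not of one limb), accelerometers synthesized
noise-free from the analytic stroke accelerations plus a constant
trunk-frame gravity of (0, 0, −9.81) m/s², and EMG as a speed-coupled
envelope (flexor channels weighted on the acceleration phase, extensor
channels on deceleration) with gain 0.6 and noise SD 0.02.

Passing on these fixtures establishes correctness of the algorithms under
the stated model — it does not establish performance on real patient data,
where trunk-frame estimation errors, EMG crosstalk and non-stationary
noise, involuntary movements, and movement forms far from minimum-jerk
all occur. The acceleration double-integration consistency check (1 μm
tolerance, via cumulative Simpson, which is exact for the cubic
minimum-jerk acceleration) verifies the generator's internal physics, not
any sensor model.

Problem sizes: the validation hexagon uses 120 strokes (20 circuits of
50 mm sides), the symmetric session 100 strokes with seed 42, the
unimanual session 50 strokes with seed 7; the moment-recovery check uses
10⁵ standard-normal draws. The full suite runs in well under a minute on a
single core.

## Other design decisions

- **Shared bilateral segmentation.** Movement-level metrics need one set
  of intervals for both limbs; we derive it from the composite speed and
  run direction-change detection on both trajectories, merging boundaries
  closer than 0.15 s (keeping the one at lower composite speed). Per-limb
  segmentation remains available for single-trajectory tasks such as the
  hexagon validation.
- **EMG stays on its own clock.** Muscle counts integrate on the 200 Hz
  grid (0.25 s = 50 samples exactly); movement windows are mapped to EMG
  samples by time. No resampling, no interpolation bias.
- **EMG scaling.** Files written by this package store normalized
  amplitudes in [−1, 1]; `emg_scale = 128` reproduces the common raw
  8-bit armband export convention at read time.
- **Boundary samples are shared.** Movements are closed at both ends;
  consecutive movements may share the boundary sample (the hand is at a
  near-stop there, so the double-counted sample carries no path length).
- **Config is explicit.** Every tunable above is a field of
  `analysis_config()`, serializable to YAML or JSON, and recorded in each
  run's manifest.

## Known limitations

- Movements whose tracing speed sits at or below `rest_speed` throughout
  (e.g. deliberately slow tracing at ≤ 0.05 m/s) fall below the rest
  threshold and are not segmented; the threshold trades this against rest
  detection under noise.
- Direction changes are only detectable when at least ~40 mm of clean path
  exists on each side of the corner; successive corners closer than two
  heading windows merge.
- The ±6 saturation of log-ratios bounds, but does not remove, the
  sensitivity of ratio distributions to near-zero denominators; flagged
  exclusion is the intended analysis path.
- Involuntary or passive movements of an impaired limb are segmented and
  scored like any other movement; EMG-based measures (`W`, `RW`) are the
  tool for separating them, not the kinematic track.
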