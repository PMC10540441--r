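---
title: "Methods: from raw IMU streams to the semiogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw IMU streams to the semiogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiogram)
```

This vignette is the package's own account of its models and numerical
choices: what each stage assumes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## The measurement model

A trial is one 10-m walk, a U-turn, and 10 m back, recorded by three
inertial units (left foot dorsum, right foot dorsum, lower back) sampled
nominally at 100 Hz. All computations happen in an anatomically aligned
frame — AP (anteroposterior), ML (mediolateral), CC (craniocaudal) — with
accelerations in m/s² and angular velocities in deg/s. The loader applies a
declared static axis mapping per site; no dynamic sensor-to-segment
calibration is attempted, because every downstream quantity is either a
timing (robust to small static misalignment), a band-power ratio, or an
RMS/arc-length magnitude for which a fixed mounting is the testable
contract. Gaps of at most 1% non-finite samples are linearly interpolated
(with a warning); larger corruption is an error, since every parameter
formula assumes a continuous signal. Inputs at other rates are linearly
resampled.

## Gait events

Initial Contact (IC, foot strike) and Final Contact (FC, toe off) per foot
are detected on the foot ML angular velocity: zero-phase 4th-order
Butterworth low-pass at 10 Hz; swing = peak with topographic prominence of
at least 50 deg/s (an adaptive fallback at 0.4 × the signal maximum covers
severely degraded gait, where swing lobes can be far smaller); FC = last
local minimum before the swing peak and IC = first local minimum after it,
the classic signature of sagittal foot rotation (negative dips at the two
contacts around the positive swing lobe). Peaks closer than 0.2 s are
merged, keeping the more prominent, since no plausible swing lasts less
than 0.2 s. The detector's contract — not its internals — is what the rest
of the package depends on: ordered, alternating FC→IC pairs per foot.

## U-turn

The trunk CC angular velocity is integrated (trapezoid) into an angular
position trace. Drift is removed by the protocol's own geometry: the walker
faces 0° before the turn and ±180° after it, so an intercept-and-slope
line is fitted jointly on the two plateaus and subtracted; left turns are
folded to +180°. Boundaries are the points where the 1-Hz-smoothed angular
velocity leaves, and later re-enters, 2% of its turn peak — the shoulder
("inflection") points at which the angle trace leaves its plateaus. We
deliberately do **not** place boundaries where the *angle* crosses fixed
fractions of 180°: for any smooth turn profile the angle accumulates slowly
near its plateaus, so angle-threshold boundaries sit far inside the turn
and the enclosed displacement undershoots a half revolution by tens of
degrees. With velocity-shoulder boundaries the enclosed drift-corrected
displacement is 178–180° on simulated turns with up to 1 deg/s of gyro
drift, and the boundary error on a clean 3-s pulse is about 0.1 s. The
walk outward from the pulse peak tolerates sub-threshold dips shorter than
0.2 s so that shoulder noise cannot truncate the interval. A trial whose
pre-plateau-detrended angle never exceeds 120° has no U-turn and is
rejected.

## Segmentation

Valid strides are IC-to-next-IC intervals of one foot that do not intersect
the U-turn, excluding the initiation stride of each foot (gait initiation
is transient, not steady-state walking). Steps are the merged IC events of
both feet outside the turn. Trunk-signal measures use the two maximal
straight-walking windows, which additionally exclude the terminal stride
(deceleration). A U-turn covering more than 80% of the trial, or fewer
than 4 steps outside it, is a degenerate segmentation.

## The 17 parameters

Timings follow their definitions directly: `V` = path length / (event span
− U-turn duration); `StrT` pools the valid strides of both feet; `SteL` =
path length / step count; `dstT` sums the two double-support intervals of
each cycle (ipsilateral IC to contralateral FC) over the cycle time;
coefficients of variation use the sample SD (n−1; the usual small-sample
convention). Cycles with inverted event ordering are discarded with a
warning rather than contributing negative support times.

Smoothness: `SPARC-G` is the negative arc length of the normalized Fourier
magnitude spectrum of the tri-axial trunk gyration magnitude, computed on a
zero-padded FFT (≥4096 points and ≥8× the window length), normalized by the
spectral maximum, over an adaptive band that ends at the last frequency
where the normalized magnitude still exceeds 0.05 (capped at 20 Hz). These
are the standard published defaults for the index; the magnitude (rather
than a single axis) is used because turning smoothness is not axis-aligned.
`LDLJ-A` = −ln(T/a_peak² · ∫ j² dt) with jerk from centered finite
differences of the 10-Hz low-passed AP acceleration — differentiation
amplifies noise, so differentiating the raw stream would make the index a
noise meter. Both indices are duration-weighted means over the straight
windows.

Regularity and symmetry: `P1/P2_aCC` are maxima of the mean-removed,
unbiased normalized autocorrelation of the trunk CC acceleration in lag
windows seeded by the detected mean step and stride times (step lag ×
[0.5, 1.5]; stride lag × [0.75, 1.25]) — the peak location rule is not part
of the index's published definition, so the search windows are declared
here. The improved harmonic ratios decompose each stride into stride-locked
Fourier harmonics 1..20 (a conventional harmonic count for trunk
acceleration; higher harmonics at 100 Hz carry mostly noise) and report
the percentage of harmonic power in the intrinsic set — even harmonics for
AP/CC, odd for ML. `swTr` is min/max of the per-foot mean swing times;
`P1P2_aCC` = P1/P2.

## Scoring

Each parameter is z-scored against a reference population and premultiplied
by its z-coefficient, so that positive always means better than reference;
criterion scores are arithmetic means of their members' signed z-scores.
The packaged reference table (means, SDs, signs for all 17 parameters; 19
healthy adults, 110 trials of this protocol) is shipped verbatim, including
the negative z-coefficient of `SPARC-G` — noteworthy because a *less*
negative spectral arc length conventionally indicates a smoother movement;
the table is reproduced as published and the sign can be overridden by
supplying a custom reference YAML. Two exact identities pin the
implementation: scoring the reference means yields the all-zero semiogram,
and scoring means + k·c·SD yields every criterion equal to k.

## Reliability statistics

ICC(1,1) = (BMS − WMS)/(BMS + (k−1)·WMS) from the one-way ANOVA treats all
within-subject variability as error; ICC(3,1) = (BMS − EMS)/(BMS +
(k−1)·EMS) from the two-way ANOVA without interaction removes a systematic
per-repeat bias. SEM = SD·√(1 − ICC) with the SD pooling all observations.
Banding: ICC ≥ 0.75 excellent, 0.4–0.75 moderate-to-high, below 0.4 low;
exactly 0.75 counts as excellent and exactly 0.4 as moderate-to-high (the
published wording is inclusive on both sides, so the boundary assignment is
declared here). Heteroskedasticity is screened as the Pearson correlation
between |test − retest| and the pair means. Group differences use the
Mann–Whitney U with tie-corrected normal approximation (exact enumeration
for tie-free samples of at most 8), Bonferroni-adjusted with a family size
defaulting to 8 (speed plus seven criteria — the family is an argument
because no single family size fits every table). Correlations with
clinical scales are Pearson r tested via the Fisher z-transformation; the
"exact" test named alongside Pearson correlations in the clinical
literature is interpreted as this z-test, there being no exact test for a
continuous correlation.

For repeated-measures layouts, the intra-session unit is the pair of trials
of one visit (visits pooled as independent rows), and the inter-session
unit is the per-session mean of the two trials — matching the chart, whose
plain line is the session mean.

## The synthetic walker

`walker_spec()` defaults describe a healthy adult at the packaged reference
means: stride time 1.10 s with 2.34% CV, step length 0.68 m on a 20-m path,
total double-stance fraction 23.34% of the cycle, swing-time ratio 0.96,
trunk ML RMS 1.28 m/s², U-turn 2.62 s. Event times come first (cycles with
Gaussian duration noise; right ICs offset half a cycle;
swing-aligned FCs with 10-ms jitter so double-stance variability is
realistic); signals are then painted onto them: raised-cosine swing lobes
(250 deg/s) flanked by −25 deg/s contact dips on the foot ML gyro, damped
15-Hz impact transients on the foot CC accelerometer, a stride-locked
harmonic series on the trunk (even harmonics dominant on AP/CC, odd on ML,
plus calibrated white noise), periodic trunk angular velocity, and a
raised-cosine turn pulse integrating to ±180° plus an optional constant
drift on the trunk CC gyro. The trunk AP amplitudes and the 8-Hz
intermittency term (`smoothness_noise`, default 0.10 m/s²) were calibrated
once so that the default walker's smoothness and regularity indices fall
inside the reference bands; they are generator design constants, not
fitting knobs. Ground truth records the exact event times, turn interval
and realized stride/double-stance/swing series; the commanded velocity
target is defined as path/(true event span − true turn duration), i.e. the
exact value the velocity parameter estimates, which differs from the naive
2·step length/stride time by a few percent because real trials include
start/stop strides and turn margins.

What the generator does **not** emulate: joint kinematics, ground-reaction
mechanics, device-specific noise spectra, turning steps (the simulated
walker pauses stepping during the turn), or pathology-specific signal
morphology beyond the exposed knobs. Passing the recovery suite therefore
demonstrates that the pipeline inverts its own signal model within stated
tolerances — it does not certify accuracy on any particular device or
patient population.

## Numerical choices and degenerate inputs

* Problem sizes in the test-suite: single trials are ~20–25 s at 100 Hz;
  detector sweeps use stride times 0.9–2.0 s with CV up to 10%; recovery
  and U-turn suites use 20 seeded trials each.
* The SPARC arc length is grid-dependent in its third digit (the adaptive
  band covers spectral sidelobe ripples whose polyline length converges
  slowly); the oracle tests therefore compare against an independent
  direct-DFT computation on the same nominal grid (1e-6) plus a coarse
  stability check under 8× grid refinement.
* The LDLJ oracle is the exact discrete closed form of a sampled sinusoid
  (geometric cosine sums for the trapezoid quadrature), because a
  continuous closed form cannot match a finite-difference pipeline below
  the ~1e-3 truncation error of centered differences at 100 Hz.
* All-zero signals, missing sensors, non-monotonic timestamps, turns
  covering >80% of a trial, running-like patterns without double support
  and constant test-retest differences are rejected or flagged rather than
  silently scored.
* Radar rendering clips scores below the lower radial limit (default −4 SD)
  at the limit and flags the session label; severe disease can exceed the
  chart range without distorting the polygon ordering.

## Known limitations

Stability is represented by the trunk ML RMS alone; dynamical-stability
measures (e.g. local divergence exponents) are out of scope. Step length is
count-based (path/steps), not a per-step spatial estimate. The reference
table is a single adult group without age strata. The CLI and file formats
are plain-text by design; vendor binary formats are not read.
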