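---
title: "Counting steps from raw accelerometry: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting steps from raw accelerometry: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepwave)
```

## The measurement model

A body-worn accelerometer measures gravity plus body acceleration in the
device frame. The device's orientation is unknown and drifts, so stepwave
works exclusively on the vector magnitude
$v(t) = \sqrt{x^2 + y^2 + z^2}$, which is invariant under any rigid rotation
of the sensor. During walking, $v(t)$ oscillates around a local mean of
about 1 g with a fundamental frequency equal to the step rate (cadence), and
with energy at the second harmonic (individual heel strikes) and at the
0.5× stride subharmonic (left/right asymmetry). Step counting therefore
reduces to instantaneous-frequency estimation on a quasi-periodic,
amplitude-varying signal — a task the continuous wavelet transform (CWT)
handles better than short-time Fourier analysis because its time resolution
adapts to the analysed frequency.

## The pipeline

**Standardisation.** Inputs arrive in g or m/s² (converted by
1 g = 9.80665 m/s², never autodetected: a "resting magnitude near 1 vs 9.8"
heuristic misfires on clipped ±2 g sensors), at anywhere from 15 to 205 Hz.
Each axis is linearly interpolated onto a uniform 10 Hz grid — ample for the
walking band, cheap to process. Inter-sample intervals longer than the
`gap_threshold` (default 2 s) delimit recording gaps; each contiguous
segment is resampled and transformed independently, and no value is ever
interpolated across a gap. This matters for duty-cycled phone data, where
≈ 20 s off-cycles would otherwise be bridged with fictitious samples.

**Scalogram.** The demeaned magnitude (1 s moving-average local mean
removed) is projected onto coefficients $W(t, f)$ with an analytic Morlet
wavelet, centre frequency $\omega_0 = 6$, evaluated on a frequency grid of
0.5–4.5 Hz in 0.05 Hz steps — slow pathological gait up to fast walking and
its first harmonic, bounded by the 5 Hz Nyquist limit of the 10 Hz working
rate. Two numerical choices deserve note:

* *L1 normalisation.* With the conventional $\sqrt{s}$ (L2) scaling, the
  coefficient maximum for a pure tone sits slightly above the tone's scale,
  biasing an argmax-based frequency reader by roughly $1/(2\omega_0^2)$ in
  relative terms. stepwave's kernel
  $\hat\psi(\omega) = 2\exp(-(a\omega - \omega_0)^2/2)$ (for
  $\omega > 0$, scale $a = \omega_0 / 2\pi f$) peaks exactly at the tone
  frequency and returns ridge heights on the amplitude scale of the signal
  (a 0.3 g oscillation yields a ≈ 0.3 g ridge), which makes the walking
  gate's threshold interpretable in g.
* *Edges.* Each segment is reflection-padded over four envelope standard
  deviations of the slowest wavelet before the FFT-based transform, so edge
  windows of short (e.g. 10 s duty-cycle) segments remain usable.

**Cadence and steps.** The scalogram is split into nonoverlapping 1-second
windows aligned to integer seconds of the absolute clock; partial windows
are dropped. Cadence per window is the grid frequency with the maximum
average coefficient, ties broken toward the lowest frequency to prefer the
fundamental over a harmonic. The step count of a bout is the half-up rounded
sum of per-second cadences over walking windows. Rounding happens once, at
final bout or day reporting (`rounding: per_bout | per_day` in the config);
keeping minute aggregates fractional avoids compounding up to 0.5 steps of
rounding error per window.

**Walking gate.** The full walking-recognition problem is out of scope here;
stepwave ships a deliberately simple, documented gate — a window is walking
when (i) the ridge is strong (`coeff_threshold`, default 0.08 g), (ii) the
demeaned magnitude's peak-to-peak amplitude reaches `amp_threshold`
(default 0.12 g), and (iii) cadence lies in 0.6–3.0 steps/s — and accepts
externally supplied walking segments that bypass the gate entirely, so a
fuller recognition model can be plugged in. The two thresholds were fixed
once, from signal-scale reasoning: simulated walking oscillations are
0.2–0.35 g while still-sensor noise and non-walking foils stay below
≈ 0.05 g in ridge height; at these values the simulator corpus reaches
sensitivity and specificity above the 0.92 / 0.95 floor that wavelet-based
walking recognition reports across body locations.

**Aggregation and duty-cycle recovery.** Windows are attributed to wall
clock minutes by their start time and never split. For duty-cycled
recordings, observed minute counts are multiplied by
$(\text{on} + \text{off})/\text{on}$ — computed, not hard-coded, so schemes
other than the default 10 s on / 20 s off (factor 3) are expressible. For
minute-level method comparison, minutes with 0 steps on either device are
removed first: non-wear and clock lag between devices otherwise masquerade
as disagreement. Daily totals sum the retained minutes per calendar day
(UTC); validation-day selection returns the first full day inside the
recording span and the first day with ≥ 1000 observed steps, the latter
possibly absent for low-wear participants.

## Agreement and fairness statistics

Bland-Altman bias is `mean(a - b)`; limits of agreement use exactly 1.96
times the sample SD (n − 1 denominator — standard Bland-Altman practice; a
t-multiplier is deliberately not used). The relative bias divides by the
grand mean of the pairwise averages $(a+b)/2$; a reference-method mean would
be an equally defensible denominator, so the choice is documented and the
components needed to recompute it are all in the result object. The sign
convention is first argument minus second throughout; cross-body pairs are
ordered canonically thigh, waist, chest, arm.

The fairness models regress per-participant device differences on age and
BMI: OLS with t-based 95% CIs for single-observation designs, and an
lme4 random-intercept model for repeated observations, with normal
approximation CIs for the fixed effects. "No systematic bias" is read as
every covariate CI containing 0. A singular variance component is flagged,
not fatal; when every participant contributes exactly one observation, the
random intercept is unidentifiable and the fit degenerates to pooled OLS
with the variance component at 0, which is reported as such.

## The synthetic gait simulator

The simulator is phenomenological, not biomechanical: walking is gravity
plus a sinusoid at the cadence, a second harmonic, a 0.5× subharmonic, and
a small lateral sway, rotated by a device orientation, with white Gaussian
sensor noise added in the device frame. That suffices because the algorithm
consumes only the time–frequency structure of the magnitude. Location
presets (waist 0.25 g, thigh 0.35 g with a strong 0.5× subharmonic, chest
0.20 g, arm 0.30 g with more noise) are plausibility choices, labeled as
such — no quantitative amplitudes per body location were available to match.
Non-walking foils cover rest, desk work (sporadic 0.03 g posture
transients), motorized transport (broadband vibration plus 0.2 Hz sway),
and gesturing (1–2 s arm-oscillation bursts without sustained cadence).
Ground truth is exact by construction, and second/minute/day totals agree
identically. All randomness flows from one explicit seed.

What the simulator does **not** emulate — and hence what green tests do not
establish about real data: soft-tissue and footwear filtering, cadence
drift and turning, stair climbing, impaired or assisted gait, children's
gait, running/walking ambiguity, device clipping, and non-wear detection.
Validation on real, labeled recordings remains the standard for those.

Orientation invariance is exact at the pipeline level — rotating a recorded
signal leaves the magnitude bit-for-bit comparable — and stepwave's tests
rotate a fixed simulated recording to verify counts are identical to the
step. Re-simulating with a different orientation preset is only
approximately invariant, because sensor noise is added after rotation in
the device frame, as it is in a physical sensor.

## Problem sizes and numerical behaviour

The shipped tests and the acceptance script run the cadence sweep at
1.2–2.4 steps/s × 10–300 s (28 bouts), a 40-item × 60 s labeled corpus,
20 random rotations, ten 6-minute duty-cycle replicates, and one ≈ 58-minute
synthetic day with 3000 true steps — sizes chosen so a complete validation
is a desk-scale computation while still exercising every code path,
including minute and midnight boundaries. On these conditions the pipeline
recovers constant-cadence bouts exactly (the simulated cadences sit on the
0.05 Hz grid and the unbiased L1 ridge lands on them), duty-cycle recovery
errs by ≈ 1 %, and the full day errs by under 1 %. Degenerate inputs are
contracts, not crashes: single-sample resampling, sub-second scalograms,
undeclared units, non-monotonic timestamps, and duplicate minutes raise
typed errors naming the offending row or minute.

## Known limitations

* The gate is intentionally minimal; on real free-living data it will pass
  rhythmic non-gait (e.g. cycling at walking-band cadence) that the full
  walking-recognition approach would reject. External segments exist for
  precisely that case.
* Fractional cadences between grid lines alias to the nearest 0.05 steps/s;
  over a long bout this bounds the relative error by about 1.5 % at slow
  cadence, well inside the validation tolerance but not zero.
* Timestamps are taken at face value with a single configurable UTC offset;
  no timezone inference, no daylight-saving handling.
* Minute-level comparison inherits the joint-nonzero filter's bias: minutes
  where exactly one device recorded steps are discarded, which removes
  genuine disagreement along with non-wear.
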