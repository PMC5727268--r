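---
title: "Linear modelling of multi-CMAP recruitment curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear modelling of multi-CMAP recruitment curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmaplin)
```

## The measurement and the model

A motor nerve stimulated with a brief current pulse produces a compound
muscle action potential (CMAP) in the innervated muscle. As the stimulus
intensity rises above the motor threshold (MT), axons of increasing
threshold are recruited and the CMAP grows, until all axons conduct and the
response saturates. Over the narrow window used here — five intensities
P1..P5 at roughly 100, 110, 120, 130, 140 %MT — the growth is close to
linear, which motivates summarizing each condition by a straight line.

The pipeline, per nerve condition:

1. Segment the EMG into epochs from −5 to +20 ms around each trigger
   (half-open windows; at 2 kHz an epoch is 50 samples, with sample 11 at
   trigger time 0 in R's 1-based indexing).
2. Grand-average the epochs of each intensity across the (default four)
   stimulus trains. Averaging precedes amplitude extraction: peak-to-peak
   is a nonlinear (convex) statistic, so extracting first and averaging
   after would systematically overestimate amplitudes under noise. A
   regression test pins this order.
3. Extract the peak-to-peak voltage Vpp = max − min over the 1–15 ms
   post-stimulus window, after subtracting the mean of the pre-stimulus
   segment. Vpp itself is offset-invariant; the baseline subtraction
   additionally makes the *corrected waveform* meaningful and costs
   nothing.
4. Normalize intensities, `x[n] = (P[n] − P[1]) / P[5] × 100`, and
   responses, either against the initial condition's maximal response
   (baseline mode) or against the same trial's maximal response (per-trial
   mode). Both modes force `y[1] = 0`; the two coincide exactly on the
   initial condition.
5. Fit `y = a x + b` by ordinary least squares from the normal equations
   `θ = (XᵀX)⁻¹ Xᵀ y` with `X = [1, x]`. No weighting and no robust loss:
   five points per fit do not support either, and the plain OLS slope is
   the feature the downstream criterion was designed around. Coefficients
   are returned by *name* (`a`, `b`); the solution vector's internal
   ordering (intercept first) is never exposed, which forecloses a classic
   sign-up/slope-intercept swap.

The fit is performed on the normalized percent scales, matching the scales
on which the parameters are interpreted and classified; a `raw_intensity`
flag in `fit_conditions()` allows fitting on raw %MT intensities for
comparison.

Degenerate inputs are first-class: a condition whose 140 %MT response has
disappeared (a non-conducting nerve, the clinical endpoint of maximal
injury) has a zero per-trial denominator. That raises a distinct
"non-conducting" error, and the cohort-level drivers record the
(subject, condition) pair separately instead of fitting garbage; paired
tests exclude such subjects pairwise in the pipeline.

## Why the per-trial normalization needs a shape change

The per-trial normalization divides each condition by its own maximal
response, so it is exactly invariant under uniform scaling of a condition's
amplitudes. An injury that only scales the CMAP down — e.g., conduction
block hitting axons independently of their threshold — is therefore
*invisible* to it. The baseline-free method works only because real injury
also changes the *shape* of the recruitment curve: the suprathreshold
segment flattens, the slope `a` falls.

The simulator makes this explicit (and tests assert both halves). Injury is
modelled as conduction block whose per-axon probability depends on the
axon's threshold rank `q`:

```
P(block) = (1 − γ) B + γ · 1{q > 1 − B}
```

where `B` is the level's block fraction (defaults 0, 0.15, 0.45, 0.75) and
`γ ∈ [0, 1]` its selectivity (defaults 0, 0.7, 0.85, 1.0). The expected
blocked fraction is exactly `B` for any `γ`. At `γ = 0` the block is
uniform — pure proportional scaling, and the per-trial slope carries no
information (the scale-invariance trap). At `γ = 1` the highest-threshold
axons are removed outright, so the surviving population is already fully
recruited near MT and the 100–140 %MT segment flattens toward slope zero.
The defaults grade the selectivity with severity, reproducing the empirical
pattern that motivates the method: the slope declines monotonically with
injury level under *both* normalizations, and the severest level is nearly
flat.

A multiplicative `threshold_shift` (≥ 1) for surviving axons is available
but defaults to 1 (off). It is worth stating why: raising thresholds moves
the steep part of the recruitment ogive *into* the 100–140 %MT window,
which makes the per-trial-normalized curve steeper, not flatter. Threshold
elevation alone therefore predicts a slope that *rises* with injury —
opposite to what the flattening mechanism produces. Keeping it off by
default keeps the generator's effect direction consistent with the
phenomenon the method exploits; the parameter remains exposed for
exploring that alternative regime.

## Simulator parameters and what they emulate

| Parameter | Default | Meaning |
|---|---|---|
| `n_axons` | 200 | motor axons per nerve |
| `threshold_median` | 1.0 MT | by construction half the axons conduct at MT |
| `threshold_sigma` | 0.25 | lognormal spread of thresholds (so ~91% recruited at 140 %MT) |
| `amp_median_uv` | 3 uV | median unit contribution to Vpp (≈ 0.6 mV full CMAP) |
| `amp_sigma` | 0.5 | right-skewed unit-size distribution |
| `noise_sd_uv` | 15 uV | additive noise: Vpp-level in `simulate_amplitudes()`, sample-level in `simulate_recording()` |
| `block_fraction` | 0, 0.15, 0.45, 0.75 | blocked axon share per damage level |
| `selectivity` | 0, 0.7, 0.85, 1.0 | threshold-dependence of the block |
| `pop_jitter_sigma`, `pop_jitter_amp` | 0.1, 0.2 | between-subject lognormal jitter on spread and amplitude scale |
| `n_subjects` | 16 | cohort size |
| schedule | 100–140 %MT, 500 us pulses, 1 s ISI, 5 s between trains, 4 trains | stimulation protocol |

Lognormal thresholds and unit amplitudes were chosen for positive support
and right skew, the standard phenomenology for motor-unit properties; none
of the quantitative values are measured frog parameters (none are published
for this preparation), so they are stated assumptions, fixed once at design
time from the closed-form recruitment analysis in the previous section.

Synthetic recordings place a biphasic template (3 ms latency, 2 ms positive
and 4 ms negative half-sine phases, 60/40 amplitude split) at each trigger,
scaled so the template's peak-to-peak value inside the 1–15 ms feature
window is exactly the programmed amplitude; with zero noise the front end
recovers programmed amplitudes to numerical precision, which the tests
assert at 1e-6 relative.

What the simulator deliberately does **not** model: conduction-velocity
dispersion (all axons share one waveform), stimulus artifacts, latency
shifts with injury, electrode drift, or any biophysical membrane dynamics.
Passing tests on synthetic cohorts therefore demonstrate the *pipeline's*
correctness and the *logical* requirement for shape-sensitive injury — not
that real surgical injuries have these effect sizes. The classifier
accuracies printed by the examples are properties of the generator's
designed separability, not re-measurements of the animal experiment.

## Classifier and evaluation protocol

Fitted `(a, b)` points are labelled healthy (conditions 0–1) or injured
(conditions 2–3) and split 70/30 — stratified by label by default, which
the original protocol did not specify but which avoids degenerate test sets
at n = 64; `stratified = FALSE` restores plain random splitting. The SVM is
linear with `C = 1` (the conventional defaults of the reference
implementation), without feature standardization, matching the raw
parameter scatter; a scaler is opt-in. Points exactly on the boundary
classify as healthy — an arbitrary, documented, tested tie rule on a
measure-zero set. The transfer evaluation trains on baseline-mode points
and classifies the per-trial points of all subjects, the scenario that
matters clinically (criterion learned where baselines exist, applied where
they do not).

## Numerical and protocol choices

- **Trigger detection**: threshold at half the trigger channel's range,
  rising edge, 200 ms refractory (far below the 1 s ISI, far above the
  500 us pulse), plus a two-sample debounce — TTL pulses last ≥ 1 ms = 2
  samples at 2 kHz, so the debounce rejects single-sample noise spikes
  without delaying detection.
- **Trains are positional**: triggers are grouped into consecutive blocks
  of five ascending intensities, because the protocol delivers them that
  way; inter-train gaps are not used for grouping.
- **Edge handling**: epochs whose window would cross a recording edge are
  dropped with a warning (never padded); averaging proceeds when at least
  one train survives per intensity, with `n_averaged` recorded.
- **Damage schedules**: the graded levels default to fractions (1/3, 2/3,
  1) of the measured maximum — consistent with reported 30/60/90 g levels —
  with the halving variant (1/3, 1/2, 1) selectable, since both conventions
  appear in descriptions of this protocol. Compression rounds to whole
  grams, incision to whole percent.
- **Motor-threshold surrogate**: the observational "visible twitch"
  criterion is replaced by the smallest intensity whose Vpp exceeds
  `k = 3` noise SDs; `k` is configurable. MT is determined once, before
  injury, as in the protocol.
- **Incision quantification**: Otsu's threshold per image (explicit
  threshold overridable), optional rectangular ROI, percent of baseline
  white pixels removed.
- **EDF I/O**: EDF is a 16-bit format; samples are quantized to the
  channel's physical range (round trip accurate to half an LSB) and
  recordings are padded to whole 1 s data records. The CSV path is
  lossless.
- **Statistics**: paired two-sided t-tests on per-subject parameter
  differences, no multiplicity correction by default (a Bonferroni option
  exists), mirroring how such condition-wise comparisons are convention-
  ally reported; zero-variance differences are handled explicitly (t = 0,
  p = 1 when identical; a flagged p → 0 when constant and nonzero).

## Problem sizes used in the test-suite

Unit and property tests run on synthetic data generated in-process: cohorts
of 8–16 subjects, recordings of ~33 s at 2 kHz, 100–1000 replicates for
Monte-Carlo properties, and 500 replicates for blocking expectations.
These sizes give stable statistics for the designed effect sizes while
keeping the full suite fast; all randomness is seeded, so every reported
number is reproducible.

## Known limitations

- The linear model is only sensible over the narrow 100–140 %MT window; it
  is not a recruitment-curve model (no sigmoid, no saturation parameter).
- Slope and intercept are fitted from five points; their sampling noise is
  substantial at severe injury where the per-trial denominator is small.
- The healthy/injured boundary is a single linear criterion; four-level
  damage grading is out of scope.
- Real intraoperative data add artifact classes (cautery, irrigation,
  movement) that the front end does not attempt to reject beyond edge
  checks.
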