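---
title: "Methods: CGM analysis for hepatic glycogen storage disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CGM analysis for hepatic glycogen storage disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotrace)
```

`glycotrace` analyses continuous glucose monitoring (CGM) traces from
patients with hepatic glycogen storage disease (GSD), where dietary
carbohydrate therapy must hold glucose above the hypoglycemic range without
overshooting into sustained hyperglycemia. This vignette documents the
models, conventions and numerical choices behind each stage, and what the
synthetic-data tests do and do not establish about real sensor data.

## The data model

A trace is a tibble of `(timestamp, glucose, clipped)` at a nominal 5-minute
cadence (288 readings/day). Timestamps are treated as *naive device-local
clock time*: the nocturnal analysis window is defined on the wall clock, so
no timezone conversion is ever applied. The canonical unit is mmol/L; mg/dL
is accepted only at the ingestion boundary and converted with the molar mass
of glucose, 18.016 mg/dL per mmol/L (the conversion and its inverse compose
to identity).

Dexcom sensors are validated down to 2.2 mmol/L (40 mg/dL). Readings below
that floor are *clipped to 2.2 and flagged*, never dropped: during
hypoglycemia the sub-floor readings are exactly the ones that matter, and
omitting them would bias every descriptive statistic upward. `clip_floor()`
is idempotent. Device `"High"` flags are mapped to the 22.2 mmol/L display
ceiling with a warning — no validated upper clipping exists, so this is
flagged as a data-quality event rather than silently accepted.

Duplicate timestamps keep the first occurrence (with a warning); rows whose
timestamp or glucose fail to parse are dropped and counted in a warning
rather than aborting the whole ingestion.

## Intervals and the nocturnal window

All metrics are computed per intervention segment (diet or drug phase) and,
within each segment, for the nocturnal clock window. Both use *half-open*
conventions: intervention segments `[start, end)` so abutting phases
partition the trace with boundary samples assigned to the later phase, and
clock windows `[01:00, 05:00)` so one night holds exactly 48 samples at
5-minute cadence (192 over 4 nights). Diurnal variation in diet and physical
activity confounds glucose homeostasis; the 01:00–05:00 window is the part
of the night where neither typically operates.

A night is labelled by the calendar date its window starts on. Nights with
fewer than 80% of the expected samples are flagged incomplete and excluded
by default from the spectral and CUSUM analyses (the threshold is an
argument; sensor dropouts are common and a half-empty window would distort
both the DFT bin layout and cumulative sums). Nocturnal "interpolation" here
means interval extraction, not resampling: no gap-filling is performed by
default, and the derivative stage masks rather than bridges gaps.

## Primary metrics

`descriptive()` reports median, min, max, range, and the variation outcomes:
sample (n−1) standard deviation, variance, and CV = 100·SD/mean (CV is
defined against the mean, not the median). The tabulated "95%" column is
implemented as a *normal reference interval* mean ± 1.96·SD, floored at
zero — it describes where readings lie, not the precision of the mean, and
is labelled `ri95_*` to avoid implying a confidence interval.

`time_in_ranges()` uses the ADA-2020 boundary conventions exactly as the
inequalities read: level-2 hypoglycemia `< 3.0`, level-1 `[3.0, 3.9)`, time
in range `>= 3.9 & <= 7.8` (tight) and `>= 3.9 & <= 10.0` (standard), time
above range `> 7.8` and `> 10.0`. A reading of exactly 3.9 counts in range;
exactly 7.8 counts in the tight band; exactly 10.0 in the standard band. The
four exclusive bands (`<3.0`, level-1, tight TIR, `>7.8`) partition every
input, so their percentages sum to 100 before rounding — a property the test
suite checks on 1000 random traces. Level-3 hypoglycemia is a clinical event
definition (assistance required) and is deliberately *not* computable from
CGM values. Percentages are computed over non-missing samples; missingness
is a separate report column. Report tables round concentrations, slopes and
percentages to 1 decimal; all computation is full precision with rounding
applied only at presentation.

## Starch loads

A monitored starch load is summarised by its anchors — initial value, maximum
(earliest occurrence on ties), time-to-max, end value, end time — and derived
quantities: rising slope `(max − initial)/(t_max/60)` and falling slope
`(end − max)/((t_end − t_max)/60)` in mmol/L/h, and the *total* trapezoidal
AUC above zero in mmol/L·h (not incremental above the initial value; total
AUC is what matches the magnitude `duration × mean level` of the tabulated
values). When the maximum falls on the first or last sample the
corresponding slope is reported as 0 (with a `fall_degenerate` flag for the
latter) rather than as an undefined division.

`compare_arms()` resolves a genuine ambiguity in partial crossovers: per-arm
means are computed over *all available loads* in that arm, while the paired
t-test uses *complete pairs only*. With the bundled reference table
(`starch_load_reference()`, 11 UCCS loads, 9 complete Glycosade loads) this
combination reproduces both the published arm means and the published paired
p-values simultaneously, which neither "pairs-only means" nor "all-loads
t-test" does. Degrees of freedom are `n_pairs − 1`; no multiple-testing
correction is applied (13 metrics are compared and reported raw, matching
the source analysis). The reference table's slope columns are consistent
with their own printed anchors only up to the anchors' 1-decimal rounding;
recomputation therefore uses a propagated tolerance of
`0.1/(t_max/60) + 0.05` mmol/L/h for the rising slope (the falling slope,
with its longer time base, reproduces exactly at 1 decimal).

## Derivatives and CUSUM

glucose′ and glucose″ use three-point finite differences in *slope form* on
the actual timestamp spacing: for interior points with left/right slopes
`s1, s2` over spacings `h1, h2`,

```
glucose′ = (h1·s2 + h2·s1)/(h1 + h2),   glucose″ = 2·(s2 − s1)/(h1 + h2)
```

with one-sided extrapolation of the same stencil at the boundaries. The
slope form is exact for quadratics and — unlike the expanded-coefficient
form — returns *exactly* zero on constant or linear data, so degenerate
traces do not smear cancellation noise across derivative bins. Units are
mmol/L per minute (and per minute²). Sample pairs more than 2 cadences apart
are treated as a gap: the flanking samples are masked (`NA` derivatives) and
contribute zero CUSUM increment.

Method A is the classical cumulative sum
`CUSUM_t = Σ_{i≤t}(glucose_i − reference)`. The reference mean is
configurable because the subscripting of "mean glucose" is genuinely
ambiguous in descriptive CUSUM practice: `"self"` (the interval's own mean)
gives the zero-terminating within-interval drift curve, while a fixed
baseline-period mean shows sustained departures from earlier behaviour
across interventions. The pipeline defaults to the first intervention's mean
when a schedule is present, else `"self"`.

Method B accumulates `glucose_calculated − glucose`, where
`glucose_calculated` is predicted from (glucose′, glucose″) by a per-patient
"hypercube" regression. The estimator behind that name is not recoverable
beyond its description — predicting absolute glucose from binned
derivatives — so the implementation takes the literal reading:
multidimensional binning of the (glucose′, glucose″) plane into an
equal-width 8×8 grid (configurable) with the cell mean of observed glucose
as the prediction. Empty cells fall back to the nearest nonempty cell by
Euclidean bin-index distance, ties toward the lower linear index, so every
prediction is a mean of actually observed glucose and stays inside the
training range. Because each cell's residuals sum to zero by construction,
method B on its own training trace has mean increment zero — the CUSUM is
trendless on the period the model was fitted to, and drifts exactly when the
glucose-dynamics relationship changes. Models are strictly per patient; no
pooling.

## Spectral analysis

Each complete night's window (48 samples) is mean-centred and transformed
with the DFT; bin `k` (1 ≤ k ≤ n/2) has amplitude `2·|X_k|/n` and frequency
`k / window_hours` cycles per hour (`k` is also directly the cycles per
night). The factor 2 converts one-sided modulus to sinusoid amplitude, so a
bin-aligned sinusoid of amplitude A is recovered as exactly A; the same
factor is applied at the Nyquist bin for consistency with the single
amplitude formula, and the suite's Parseval check accounts for that
convention (`mean(x²) = Σ_{k<n/2} amp²/2 + amp_Nyq²/4`). No taper is applied
by default — the amplitude formula implies a raw transform — and no zero
padding; a Hann taper (amplitude-corrected) is available for leakage-heavy
exploration.

Component detection has no published rule, so it is a documented,
configurable choice: a component is a *local maximum* of the amplitude
vector at or above `max(0.2 mmol/L, 20% of the peak amplitude)`. The
local-maximum requirement stops the leakage lobes of a non-bin-aligned
component from inflating the frequency count; the absolute floor keeps noise
bins (≈0.04 mmol/L at 0.2 mmol/L sensor noise and n = 48) out. Detection is
monotone in the threshold. The per-night stability summary reports the three
outcome parameters — dominant frequency (ties broken toward the lower
frequency), number of frequencies, dominant amplitude — and deliberately
forms no composite score.

## The synthetic generator

`generate_trace()` evaluates baseline + sinusoidal components + event terms
on the half-open grid `t = 0, Δ, 2Δ, … < duration` (exactly 288 samples/day
at 5 minutes), adds seeded Gaussian sensor noise, and applies the 2.2 mmol/L
floor. Defaults mirror the study conditions the pipeline targets: 5-minute
cadence, midnight start (so nocturnal windows are deterministic), noise off
unless requested. Where no value is published the choices are what a CGM
practitioner would call realistic: sensor noise sd 0.2 mmol/L in noisy
fixtures (Dexcom MARD ≈ 9% at euglycemia), hypoglycemic dips as smooth
raised cosines, meal/starch excursions as asymmetric triangles peaking a
third of the way through the event. Noise is independent Gaussian by
default; an AR(1) option (marginal-variance-preserving) exists because real
sensor error is autocorrelated, but it is off by default since no noise
model is published. One integer seed drives all draws, and generation
restores the caller's RNG state.

What the generator does *not* emulate: sensor drift and recalibration steps,
compression lows, the 10–15 minute interstitial lag, non-Gaussian outliers,
and physiological meal dynamics beyond additive shapes. Passing the
ground-truth recovery tests therefore establishes the *arithmetic* of the
pipeline (windowing, binning, DFT conventions, range boundaries), not the
clinical performance of the metrics on real sensors.

Load curves are generated through their three anchors
(piecewise-linear by default, monotone Hermite optionally); on a grid whose
cadence divides the anchor times, `load_summary()` recovers the
specification exactly — the identity the test suite checks on random
specifications.

## Problem sizes and tolerances

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path in seconds: 1000 random traces for the range-partition property,
200 for CUSUM termination (tolerance `1e-9·n`), 100 seeded nights for noisy
amplitude recovery (mean absolute error < 10% at noise sd 0.2, n = 48;
< 1% noise-free), 50 random load specifications for the round-trip identity
(exact), and 50 seeded days for range-occupancy recovery (< 1 percentage
point under noise; exact without). The occupancy check uses a 0.87 cycles/h
sinusoid so that grid samples spread uniformly through the 3.9 mmol/L
threshold crossing instead of stacking at a single phase value — with a
bin-aligned 1 cycle/h component, 48 of 288 samples sit exactly 0.1 mmol/L
above the threshold and any noise inflates TUR by construction, which is a
property of that degenerate alignment, not of the estimator.

## Known limitations

- Range percentages are per-sample proportions; no dwell-time weighting for
  irregular sampling (gaps are excluded, not re-weighted).
- The hypercube model is a step-function regression: predictions jump at bin
  edges, and with few training samples per cell it inherits their noise.
  Quantile edges and bin counts are configurable but the default 8×8 is a
  pragmatic, not an optimised, choice.
- Spectral analysis requires a uniform grid; nights failing the completeness
  policy are dropped rather than analysed with an uneven-sampling method.
- The paired t-test assumes approximately normal within-pair differences;
  with 9 pairs this is an assumption, not a verifiable property.
- No clinical interpretation is produced: the package computes the
  quantities and leaves dominant-frequency/amplitude thresholds for "good
  management" to the treating team.
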