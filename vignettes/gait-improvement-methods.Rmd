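---
title: "Scoring gait improvement with dynamic time warping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gait improvement with dynamic time warping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdtw)
```

## The measurement problem

A force plate records the vertical ground-reaction force (GRF) of one foot
during stance. A healthy stance traces a two-peak "M" curve: a rise at
heel strike, a loading-response peak of roughly 1.1–1.2 body weights (BW),
a mid-stance valley near 0.7–0.8 BW, a push-off peak near 1.1 BW, and a
fall to zero at toe-off. Knee impairment flattens the middle three phases
while heel strike and toe-off are usually still performed.

Comparing a patient's curve to a healthy reference is complicated by
timing: a cautious pre-treatment step lasts longer than a confident
post-treatment one, so the sequences have different lengths and their
phases are shifted. `gaitdtw` therefore scores similarity with dynamic
time warping (DTW), which aligns two sequences by a monotone warping path
before accumulating pointwise differences.

## The DTW formulation

For a reference `r[1:n]` and measurement `t[1:m]`, local cost
$d(k,l) = |r_k - t_l|$ and accumulated cost

$$F(k,l) = d(k,l) + \min\{F(k-1,l),\; F(k,l-1),\; F(k-1,l-1)\}$$

with $F(0,0)=0$ and $+\infty$ sentinels along the first row and column.
The distance is $F(n,m)$; the warping path is recovered by backtracking
the argmin predecessor from $(n,m)$ to $(1,1)$.

Deliberate choices:

* **Unconstrained recurrence.** No Sakoe–Chiba window, slope constraint
  or path-length normalization. Stance curves are short (about a second)
  and the outcome statistic normalizes per subject, so constraints would
  only add parameters. All normalization lives in the scoring step.
* **Absolute-value local cost**, making the distance symmetric.
* **Deterministic tie-breaking** in the backtrack: diagonal first, then
  the predecessor reducing `k`, then the one reducing `l`. Optimal paths
  are often non-unique; a fixed preference makes results reproducible.
* **Exactness over speed.** The full $O(nm)$ matrix is computed in C++;
  at typical sizes (about $1000 \times 1200$) a fill takes milliseconds,
  so approximate variants (FastDTW and relatives) are unnecessary. When
  only the distance is needed a two-row fill is used; it returns the
  identical value, which the tests assert.
* **Oracle testing.** The recurrence is checked against an independent
  brute-force enumeration of every monotone warping path
  (`dtw_brute_force()`) on hundreds of short random pairs, plus algebraic
  properties (symmetry, identity, the diagonal upper bound, path-cost
  consistency). One property worth spelling out: duplicating a sample of
  one sequence adds the local cost of its matched partner, so stuttering
  can only *increase* the distance, and a resampled copy of the same
  curve stays at distance exactly zero — which is what makes recordings
  of 1010 and 1180 samples directly comparable.

## The outcome statistic

Each condition (before / after treatment) contributes several detected
steps; the condition's raw distance is the **mean** of its per-step DTW
distances to the reference (median available via `aggregate = "median"`;
the mean is the default because per-step distances of a steady walker are
roughly symmetric and few in number). Distances are normalized to the
before condition:

$$\text{error}_{after} = \frac{D_{after}}{D_{before}}, \qquad
  \text{improvement} = \operatorname{round}\!\big(100\,(1 -
  \text{error}_{after})\big)\,\%$$

so `error_before` is 1 by construction, improvement 100% means the
post-treatment gait is indistinguishable from the reference, 0% means no
change, and negative values indicate worsening. The division makes the
score invariant to any uniform rescaling of distances, which is why a
reference recorded from a *different* healthy person is usable: constant
multiplicative mismatches cancel.

Scoring is per step and per foot, averaged within a condition; whether a
study scored single steps or concatenations is generally ambiguous from
outcome tables alone, and per-step scoring composes better with step
rejection.

## Preprocessing protocol

`run_analyze()` applies, in order:

| Step | Function | Default | Rationale |
|---|---|---|---|
| Trim | `trim_signal()` | off | drop low-quality recording edges; window in seconds |
| Gap removal | `remove_gaps()` | `max_gap = 5` samples | short dropout runs are linearly interpolated; longer runs split the trace and the longest clean stretch is kept |
| Smoothing | `smooth_signal()` | off (`window = 1`) | high-frequency noise is better handled by trimming to clean movements; a centered moving average is available when needed |
| Step detection | `detect_steps()` | threshold 5% of peak, duration band [0.3, 1.5] s | the conventional relative contact threshold; the band rejects double contacts and partial edge steps, mirroring how an improper first contact is discarded from a trial |
| Amplitude normalization | `normalize_amplitude()` | body weight if known, else peak | removes body-mass confounding when comparing to another person's reference |

Conventions: sample windows are 0-based and half-open everywhere;
units are seconds and newtons with no auto-detection (a scale factor can
be supplied at read time); missing force values travel as an explicit gap
mask and are never interpolated before `remove_gaps()` decides.

The reference curve is processed exactly like a measurement: whether it
comes from a healthy recording or from the built-in generator
(`reference_step()`), it is restricted to its contact support (samples
above the detection threshold) and expressed in BW units. Comparing a
thresholded measurement against an unthresholded reference would add a
spurious fixed cost from the sub-threshold tails.

## The synthetic GRF generator

No patient recordings ship with the package; the generator provides
ground-truthed stand-ins.

**Healthy curve.** A C1 interpolation with zero slope through five control
points — 0 at stance onset, the loading-response peak (1.15 BW at 25% of
stance), the mid-stance valley (0.75 BW at 50%), the push-off peak
(1.10 BW at 75%), and 0 at toe-off. Zero-slope (smooth-step) segments put
the curve's extrema exactly on the control points, so the generator's
contract (peak and valley values within 2%) is exact by construction.
Canonical vGRF morphology motivates the default amplitudes and timings.

**Impairment.** Each of the three middle phases carries an attenuation in
[0, 1]. Within a raised-cosine window of half-width 0.12 stance around
each control point, the healthy curve's deviation from a low featureless
arch (a single hump at half the healthy mid-stance load) is
multiplicatively reduced. Severity 0 reproduces the healthy curve
sample-for-sample; severity 1 flattens the phases onto the arch — the
foot still bears weight, so an impaired step remains one detectable
contact, as it must for a walking patient. The windows cannot overlap at
the default geometry, making the curve exactly linear in each attenuation
and the DTW distance to the healthy reference empirically monotone over
the whole severity grid (a property the acceptance tests check).

**Plate model.** Gaussian sensor noise (SD 0.01 BW, a realistic noise
floor for a portable plate), quantization to the plate resolution
(0.3 N), and saturation at 3500 N compression / −900 N tension.
Quantization precedes clipping, and the clip limits are themselves
rounded to resolution multiples, so every emitted sample is a multiple of
0.3 N within range.

**Trials and cohorts.** `synth_trial()` concatenates steps with
zero-force baseline and records ground-truth contact windows from the
noiseless curve, using the same relative contact-threshold definition the
segmenter defaults to — the standard force-plate contact criterion; with
a shared definition the generator/segmenter round trip is exact to ±2
samples even under quantization. `synth_subject_pair()` gives one subject
two trials with independent seeded noise streams; default stance
durations are 1.18 s before and 1.01 s after against a 1.025 s reference
(at 1000 Hz: 1180, 1010 and 1025 samples), so compared sequences
naturally differ in length as real recordings do. Default severities in
the simulated cohort are 0.7–0.9 before and 0.03–0.1 after — a severely
impaired knee recovering almost fully.

**What the generator does not emulate** — and hence what passing tests do
and do not show: no left/right asymmetry or double-support coupling, no
stance-to-stance variability in shape (only noise), white rather than
structured sensor noise, no drift or load-cell hysteresis, no kinematics.
Recovering known severities from synthetic cohorts validates the
pipeline's mechanics, not the clinical sensitivity of the score on real
patients.

## Cohort summaries

`summarize_cohort()` reports mean and sample (n−1) standard deviation of
age, integer-rounded sex percentages, the obesity rate and the female
share among obese volunteers. The default obesity threshold is BMI ≥ 28
kg/m², not the WHO's 30: the bundled 18-volunteer cohort's four heaviest
members (BMI 28, 29, 30, 30.5) are its obese subgroup, which only a
threshold of 28 reproduces. The threshold is an explicit argument, and an
empty obese subgroup is reported as 0% with a flag rather than an error.

## Problem sizes and determinism

The test-suite and example simulations use cohorts of up to 18 subjects
with 10 steps per trial at 1000 Hz — about 360 DTW fills of roughly
$10^6$ cells each, a few seconds in total — which matches the scale of
the study design the defaults emulate (18 volunteers, 10 steps, at least
three recordings). All randomness flows through explicit integer seeds:
a trial's noise stream is seeded per trial, a subject pair derives two
independent sub-seeds from its master seed, and `run_simulate()` is
byte-identical across runs with the same configuration.

## Known limitations

* Only the vertical force channel is modelled; no center-of-pressure,
  shear forces or moments.
* Improvement is relative to the chosen reference; a poorly chosen
  reference biases all subjects alike (the normalization removes scale,
  not shape, mismatch).
* A subject whose pre-treatment gait already matches the reference has
  an undefined normalized error (division by a vanishing before-distance)
  and is rejected rather than scored.
* The printed improvement is rounded to integer percent; downstream
  statistics should use `error_after` instead.
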