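---
title: "Oximetry pattern phenotyping: methods and design choices"
author: "oxipheno authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oximetry pattern phenotyping: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxipheno)
```

## The problem

Obstructive sleep apnea (OSA) exposes the cardiovascular system to
intermittent hypoxia, yet the standard severity index (the apnea–hypopnea
index, AHI) is only a modest predictor of later cardiovascular disease.
The nocturnal SpO2 trace recorded by every polysomnogram carries far more
information than an event count, and a number of analytic families have
been proposed to summarize it: desaturation characteristics, the
distribution of saturation values, the signal's frequency content, and
non-linear regularity measures.

`oxipheno` implements a complete phenotyping pipeline around these four
families: 31 named oximetry patterns per night (optionally per sleep
stage), plus the cohort-level association protocol — z-standardization,
group comparisons, Spearman correlation with AHI, covariate-adjusted Cox
proportional-hazards models with sex stratification, and
Benjamini–Hochberg false-discovery-rate control within each analysis
family. Because population sleep-study data are access-restricted, the
package includes a synthetic cohort generator with the statistical
structure the analysis assumes, so every stage is testable end to end.

## Signal model and cleaning

A signal is a sampled %SpO2 vector with a rate, a validity mask and a
start offset. Cleaning (`clean_signal()`) marks samples outside the
physiologic window [50, 100] %SpO2 — including oximeter dropout zeros —
invalid, then bridges interior invalid runs up to `max_gap_s` (default
30 s) by linear interpolation. Longer runs stay invalid and are excluded
from every downstream statistic; they are never imputed. The 50% floor
and the 30 s gap are conventional oximetry artifact handling, surfaced
as configuration because devices and laboratories differ.

Resampling (`resample_signal()`, used at 0.2 Hz for the non-linear
family) is a block mean over valid samples rather than decimation: the
mean suppresses measurement noise, and windows containing no valid
sample propagate invalidity instead of inventing data.

Stage restriction (`restrict_to_stage()`) invalidates samples outside
the selected hypnogram stages. All per-hour denominators then use the
time in the selected stages, so stage-specific features (NREM/REM) are
exactly the features of the cut segments — a property the test suite
checks against manual segmentation.

## Desaturation characteristics

`detect_desaturations()` finds falls of at least the threshold below a
running local baseline (the maximum valid SpO2 over the preceding
100 s). An event starts at the last near-baseline sample before the
fall and ends on resaturation to within 1 %SpO2 of the event baseline;
events shorter than 10 s or longer than 600 s are discarded. These four
constants mirror conventional AASM-style oximetry analysis and are all
configurable. The oxygen desaturation index (ODI) divides the event
count at thresholds 2–5% by hours of sleep; all desaturations count,
not only those linked to an annotated respiratory event.

Hypoxic burden (`hypoxic_burden()`) quantifies event-related
desaturation *area*. The SpO2 signal is ensemble-averaged in a ±240 s
window aligned on respiratory-event termination; the patient-specific
integration window runs from the last pre-nadir maximum of that mean
response to its first post-nadir maximum. The nadir is searched at or
after event end, since the desaturation lags the event via circulatory
delay — restricting the search also prevents a neighbouring event's
tail inside the ensemble span from capturing the minimum. Per event,
the baseline is the maximum SpO2 in the 100 s before event end and the
area is the trapezoidal integral of `max(0, baseline − SpO2)` over the
window on the native 1 Hz grid; the result is summed area divided by
total sleep time, in %·min/h. On a constructed night of fifteen
rectangular 4%-deep one-minute desaturations in one hour of sleep the
trapezoid reproduces the analytic 60 %·min/h essentially exactly.

## Time-series distribution

Moments use the population-formula standardized central moments:
skewness `m3/m2^1.5` and *non-excess* kurtosis `m4/m2^2` (a Gaussian
tends to 3, a symmetric two-point mass gives exactly 1); the SD is the
sample SD. With zero variance the shape moments are undefined and
reported missing, never as 0. Time-below thresholds (T80–T94) take
"at or below X%" inclusively, as written, with an option for the strict
form used by some tools; the denominator is valid sample time within
sleep, so artifacts inflate neither side of the ratio. The median uses
midpoint interpolation on ties — worth stating because oximeters
quantize to integer percent.

## Power spectral density

The PSD is a Welch averaged periodogram: 2048 s Hann-tapered segments,
50% overlap, per-segment mean detrend, one-sided density normalization
(`sum(power) * df` approximates the detrended variance; the white-noise
check holds within 5%). No installed estimator provides Welch averaging,
so the few lines of FFT bookkeeping are implemented here and verified
against Parseval and peak-location checks. Invalid samples are linearly
interpolated before the transform and the valid fraction is recorded.

Band features treat the in-band bin powers as a sample: their four
moments, in (%SpO2)², plus the spectral entropy `−Σ p log p` of the
normalized in-band powers (natural log; a flat band of N bins gives
log N, a single-bin band gives 0). Two bands are analyzed: the full
band 0–0.1 Hz, and an "OSA band" covering periodic desaturations at
15–180 events per hour, i.e. 0.00417–0.05 Hz. Some descriptions of
this band print an upper edge of 0.005 Hz, which contradicts the stated
event-rate span; the event-rate reading is the default here and the
band is a plain configuration value, so either choice is runnable.

## Non-linear measures

Both operate on the 0.2 Hz resampled signal. Sample entropy uses
template length `m = 1` and tolerance `r = 0.25`; following the
dominant convention in the oximetry-entropy literature the tolerance is
`r × SD` of the resampled trace, with an absolute-units mode available
since bare "r = 0.25" is ambiguous. Both template lengths are counted
over the first `n − m` starting positions (the Richman–Moorman
convention), self-matches excluded, so a constant sequence yields
exactly 0. Templates touching invalid samples are excluded from both
counts. The central tendency measure forms the Poincaré plot of first
differences and reports the fraction of points strictly inside a
1 %SpO2 radius.

One caveat the tests make explicit: with SD-scaled `r`, sample entropy
is *not* monotone in disease severity on synthetic data, because the
tolerance widens with the desaturation swings while block-averaged
measurement noise is maximally irregular. The expected
"more events → less regular" ordering holds under absolute `r`, and
that is how the property is tested.

## The synthetic cohort

`generate_spo2()` emulates one night: a 96% baseline, respiratory
events placed by a homogeneous process without overlap (uniform
placement conditional on non-overlapping footprints), each followed
after a 10 s circulatory lag by a linear 15 s fall of sampled depth and
a 20 s recovery, plus Gaussian measurement noise (0.2%), optional
signal-loss dropouts, and a hypnogram with leading wake and
late-night-weighted REM periods. Feasibility is judged on the
*configured* rate (an error if expected footprints exceed 90% of the
night); an unlucky Poisson draw is capped rather than fatal. The
non-overlap constraint bounds configured rates at about 46 events/h
with the default footprint, so severity ranges in the cohort generator
top out at 45/h. Defaults (8 h nights, 15 events/h, 4 ± 1% depths)
describe a moderate-OSA community cohort; what the generator does *not*
emulate — periodic breathing morphologies, heart-rate coupling,
oximeter quantization, treatment effects — bounds what passing tests
say about real recordings.

`generate_cohort()` adds demographics (age 63.5 ± 10.5, BMI 28.8 ± 5.3,
88% Caucasian, 52% ever-smokers, 52% female — a community sleep-cohort
profile), a mild-to-severe severity range, and survival outcomes from
an exponential proportional-hazards model: log-hazard = log(baseline
hazard) + Σ β·z(feature) + covariate terms, administrative censoring at
12 years and a 2-year landmark (events before the landmark are flagged
prevalent and excluded downstream, mirroring the exclusion of disease
present at or shortly after baseline). The exponential baseline is the
simplest model consistent with proportional hazards, and Cox estimates
are invariant to that choice. Two modes exist because full signal
synthesis for thousands of participants is needless for statistical
checks: `"features"` draws fast parametric proxy features from the
latent severity, `"signals"` attaches a full synthetic night per
participant; the survival machinery is identical.

## Association protocol

The inclusion filter keeps participants with AHI ≥ 5, a central-apnea
fraction < 0.5, a non-missing outcome and no event before the 2-year
landmark, tallying each exclusion reason. The follow-up clock is
re-anchored at the landmark, so the risk set starts there — the
landmark default (with a baseline-origin option) matches the exclusion
of early events.

Each feature is z-scored over its complete cases and fitted in its own
Cox model (`survival::coxph`, Efron ties by default because follow-up
times tie at coarse resolution; Breslow available) adjusted for age,
race, smoking and BMI, plus sex in non-stratified models; hazard ratios
are per 1 SD. Missingness is handled by per-model complete cases —
standard cohort practice — with no imputation. AHI runs through the
identical path as a comparison predictor but is excluded from FDR
families. BH adjustment is applied within each family (5/14/10/2
features) and stratum; the step-up implementation is cross-checked
against both `stats::p.adjust` and a brute-force evaluation of the
step-up rule. The Cox wrapper itself is checked against a brute-force
partial-likelihood maximization on untied data.

## Problem sizes and numerical choices

The test suite exercises parameter recovery at n = 2000 participants
with ~15% post-landmark event incidence (baseline hazard 0.016/year):
100 replicates per true hazard ratio (1.0, 1.5, 2.0) for bias, and 500
replicates for null CI coverage, where the binomial standard error of
the coverage estimate is about 1%. End-to-end determinism is checked on
200 participants with 4-hour nights. Oracle-equivalence checks use
50-sample series where the O(n²) references are exact. Degenerate
inputs follow one rule throughout: undefined is reported as missing
(never zero), empty is an error, and every error message names its
cause.

## Known limitations

Only CSV inputs are supported in this version; EDF channel extraction
is a planned external interface. The detector's constants stand in for
laboratory-specific artifact rules that vary between devices; the
synthetic generator's simplifications are listed above. Joint
multivariable models over all 31 features, penalized regression and
proportional-hazards diagnostics beyond the basics are out of scope.
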