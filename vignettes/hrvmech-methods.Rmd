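---
title: "Mechanistic HRV analysis: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic HRV analysis: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvmech)
library(dplyr)
```

## The automaticity model

`hrvmech` treats the sinoatrial pacemaker cell as a four-parameter machine.
After an action potential, the membrane repolarizes to `MP` (mV) and then
depolarizes linearly with slope `m` (mV/ms) until it crosses the threshold
`th` (mV), firing the next beat; the action potential itself (Phase 0
through the end of Phase 3) occupies a fixed systolic duration `tsys` (ms).
The heart period is therefore `HP = tsys + (th − MP)/m` and the heart rate
`HR = 60000/HP`. Four assumptions keep this closed-form: `tsys` and `th`
are autonomically inert, `MP` responds to parasympathetic drive (via the
potassium current), and `m` responds to both branches (via cAMP and the
funny current) — but, because cAMP turnover is slow, `m` cannot follow
high-frequency (respiratory, ~0.25 Hz) modulation, only low-frequency
(~0.1 Hz) modulation. This is why the HF fluctuation rows of
`scenario_presets()` force `dm = 0`, and why `modulation_spec()` defaults
`m_hf_amp` to 0 and documents overriding it as a departure from the
framework.

Autonomic fluctuation half-amplitudes `ΔMP` and `Δm` swing the two
parameters in phase, so the heart-period extremes occur at the paired
excursions `(MP + ΔMP, m + Δm)` (shortest period) and `(MP − ΔMP, m − Δm)`
(longest). `hp_variability()`/`hr_variability()` return the magnitude of
the difference between the extremes — the peak-to-trough "Delta"
convention; the half-deviation quoted as `±x` in figure insets is half of
that value. The signed closed form is negative for typical resting
parameters (the short-period term comes first), which is why the functions
take the absolute value and the documentation records the signed
convention. `tsys` cancels algebraically in `ΔHP` but not in `ΔHR`; the
test suite asserts this by evaluating at `tsys ∈ {0, 300, 1000}` ms.

Default parameters (the `control` scenario) are `tsys = 300` ms,
`th = −40` mV, `MP = −60` mV, `m = 0.036` mV/ms, giving HP ≈ 856 ms and
HR ≈ 70 bpm, with `ΔMP = 2` mV and LF `Δm = 0.002` mV/ms. The two
perturbed scenarios move `MP` by ∓3 mV and `m` by ±0.004 mV/ms with LF `Δm`
of 0.003/0.001 mV/ms — reciprocal sympathetic/parasympathetic shifts of
resting tone with the fluctuation *amplitude* of the membrane potential
held fixed. Printed integer predictions are rounded half away from zero,
the convention under which all nine reproducible scenario Deltas match
their published integer forms. Three of the twelve (LF ΔHR of the high-SNA
scenario and HF ΔHR of both perturbed scenarios) evaluate to 18.7, 11.5
and 7.3 bpm but circulate as 18, 12 and 8 — consistent with rounding the
`±` half-deviations before doubling; the package documents them as
rounding-ambiguous and guarantees them only to within 1 bpm.

## The synthetic generator

`simulate_beats()` produces beat series by iterating the model: at each
beat onset `t` it evaluates `MP(t)` and `m(t)` as the base values plus
fixed-frequency sinusoids (defaults 0.1 Hz for LF, 0.25 Hz for HF, phase
0), computes that beat's period from the closed form, and advances one
period. Modulation is *sampled at beat onsets*, not integrated across the
beat — the simplest discretization consistent with the model's per-beat
algebra. Each period is timestamped at its opening beat, and the analysis
side anchors spline knots the same way. The generator is fully
deterministic; randomness enters only through `inject_artifacts()`, whose
seeded ectopic (0.6×/1.4× of the local pair mean, pair duration conserved)
and missed-beat (adjacent periods merged) events carry ground-truth
validity flags for testing the cleaner.

What the generator emulates is deliberately narrow: sinusoidal LF/HF
parameter modulation plus injectable artifacts. Real recordings have
broadband and nonstationary autonomic drive, respiratory frequency drift,
baroreflex feedback and correlated noise. Passing tests on synthetic data
therefore demonstrate that the pipeline is *numerically faithful* and that
the model's directional logic survives the full analysis chain — not that
any particular physiological effect size will be observed in humans.

## The analysis pipeline

**Cleaning.** Real tachograms contain ectopic beats and detection errors
that are conventionally repaired by interpolation. `clean_beats()` flags
beats deviating from an 11-beat running median by more than 30% (both
configurable) and replaces them linearly from the nearest normal
neighbors; beat count is preserved and the replaced fraction is reported,
with a quality warning above 5%. The detection rule is this package's own
operationalization of what is often done by visual inspection; against
seeded ectopic ground truth it recovers ≥90% of injected events in the
test suite.

**Time domain.** The record is divided into 50%-overlapping 5-minute
segments; SDNN and RMSSD are computed per segment and averaged. Segments
are defined by elapsed time, not beat count. SDNN uses the population
(divide-by-n) convention — at ~350 beats per segment the n−1 difference is
far below any physiological signal, and the convention is switchable.
RMSSD restricts successive differences to adjacent normal beats. Trailing
remainders are dropped rather than padded (averaging unequal-length
segments biases SDNN), with one deliberate tolerance: the final full-width
window is kept when the record falls short of it by less than one median
beat interval, so a nominal 30-minute recording that ends mid-beat still
yields its 11 segments.

**Frequency domain.** Beat series are unevenly sampled, so both
representations of the *same* beats — heart period in ms, and heart rate
via the element-wise involution `60000/x` — are cubic-spline interpolated
and resampled at 12 Hz. Spectra are estimated by averaging one-sided
periodograms of 50%-overlapping segments of 2024 samples (168.7 s),
mean-removed and Hann-tapered with window-energy correction, so the PSD
integral equals the taper-corrected variance (the Parseval property the
tests assert within 5%, and exactly-to-tolerance for sinusoids via the
A²/2 identity). The 2024-sample default is kept as such rather than
"corrected" to the power of two 2048 — the FFT handles arbitrary lengths —
and both the length and a rectangular-taper option are configurable. No
zero-padding and no detrending beyond per-segment mean removal are
applied. Band powers are areas under the PSD over LF `[0.04, 0.15)` Hz and
HF `[0.15, 0.40)` Hz, integrated trapezoidally with the spectrum
interpolated at the exact band edges: abutting bands then tile the axis,
the shared 0.15 Hz edge has zero width, and disjoint band powers are
exactly additive. `hrv_spectral()` reports the four absolute powers
(ms² and bpm²), the two within-representation LF/HF ratios, and the
cross-representation ratio `LF_HR/HF_HP`; ratios are flagged `NA` when the
denominator is zero rather than returned as infinities.

A record shorter than one spectral segment is analyzed as a single
shortened segment with a warning; a record shorter than one time-domain
window falls back to a single whole-record segment, likewise flagged.

## Interpretation rules

The model's central observation is representational: sympathetic
modulation is monotone in LF power of the *heart-rate* series, and
parasympathetic modulation is monotone in HF power of the *heart-period*
series; the other two combinations invert. `infer_autonomic()` codifies
this as an ordered rule set (R1: HF_HP/RMSSD → parasympathetic axis; R2:
LF_HR → sympathetic axis; R3: LF_HP rise with silent parasympathetic
markers → sympathetic withdrawal; R4: the SDNN analogue of R3 at lower
confidence; R5: the cross ratio as corroboration only). The two axes are
reported independently — the simulations assume reciprocal change, but
experimental interpretation must not. The precedence and the
conflict-handling (opposing firings on an axis, or HF_HP and HF_HR moving
in the same direction, yield `indeterminate` with all firings listed) are
this package's own codification of reasoning that is narrated in prose in
the physiology literature; significance judgments are the caller's
(upstream statistics), and non-significant changes carry no evidence.

## Numerical and design choices

* **Thresholds and windows.** Cleaning: 30% relative deviation, 11-beat
  median window. Segmentation: 300 s windows, 50% overlap. Spectra: 12 Hz,
  2024 samples, Hann. All configurable; defaults are the canonical
  pipeline settings described above.
* **Half-open conventions.** Phase windows and band edges are
  `[lo, hi)`; a beat exactly on a protocol boundary belongs to the later
  phase, eliminating double assignment.
* **Degenerate inputs.** Non-firing parameterizations (`MP ≥ th`,
  `m ≤ 0`, or excursions that reach them) are domain errors naming the
  offending quantity — and, in the generator, the offending beat time.
  Constant series produce zero variability, all-zero spectra and
  undefined ratios. Batch processing isolates per-record failures with a
  warning and continues.
* **Problem sizes.** The test suite and acceptance script use 600 s
  synthetic records (~700 beats, 6 spectral segments) for end-to-end
  checks and 1800–4500 s records for segmentation and protocol tests —
  sizes at which every stochastic assertion is comfortably stable while
  the whole suite runs in well under a minute.

## Limitations

The model omits ionic-current dynamics (no Hodgkin–Huxley integration),
threshold modulation, and any change in the fluctuation amplitude of
autonomic drive accompanying a change in its mean — under strong maneuvers
(head-up tilt) the heart-period and heart-rate readings may therefore
reconverge. The generator's fixed-frequency sinusoids are a caricature of
respiratory sinus arrhythmia. The interpretation engine outputs
model-based inferences about cardiac autonomic *tone*, not measurements of
nerve traffic, and group-level statistics are deliberately out of scope:
`batch_table()` is the hand-off point to standard repeated-measures
tooling.
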