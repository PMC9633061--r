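---
title: "Feature-based categorization of vocalizations: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based categorization of vocalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(callcat)
```

## The model

`callcat` implements a three-stage account of auditory categorization in a
Go/No-go setting.

**Spectrotemporal layer.** Sound is converted to a cochleagram: one row
per characteristic frequency (CF), 67 CFs geometrically spaced from
200 Hz to 20 kHz, frames at 1 kHz. The built-in front end is a
Slaney-type fourth-order gammatone filterbank with half-wave
rectification, a 2nd-order Butterworth envelope low-pass (300 Hz),
power-law compression (exponent 0.3) and frame averaging. The original
account uses a biophysical inner-hair-cell model; re-implementing that
periphery is out of scope here, and the front end is deliberately
pluggable (`cochleagram_params(front_end = <function>)`) because the
feature layer is front-end agnostic. All shipped tests use the built-in
front end, so green tests establish properties of the algorithm under a
gammatone periphery, not under the biophysical one.

**Feature-detection layer.** Candidate features are rectangular
cochleagram fragments sampled uniformly from the target category's
training cochleagrams: 1500 candidates by default (500 at the reduced
desk scale used in the tests), durations uniform in [20, 200] ms
(75 ms maximum in the constrained short-feature variant), CF extents
uniform from 4 channels to the full axis. Each candidate is scored
against every training call by its maximum normalized cross-correlation
(r_max): the fragment slides in time only, anchored at its native CF
rows, and each placement is scored by the Pearson correlation between
fragment and window. Anchoring preserves the tonotopic identity of a
feature; whether fragments should also slide in frequency is an open
question we resolve in favor of anchoring.

Each candidate then receives (i) the detection threshold on r_max that
maximizes the mutual information (MI, in bits, empirical class priors)
between detection and category, found by sweeping midpoints between
consecutive sorted unique r_max values; and (ii) a weight equal to the
log-likelihood ratio ln P(detect | target) / P(detect | other), with
add-one smoothing so that weights stay finite when a class has zero or
all detections. Feature sets are assembled by forward greedy selection:
at each step the candidate that maximizes the MI between the ensemble's
weighted detection score (the `fd_response()` formula) and the category
is added, with the score threshold re-optimized at each step. Selection
stops at 20 features or when the MI gain falls below `min_gain_bits`
(default 1e-3), which produces variable-size sets. Five instantiations
per category are trained by removing each selected feature from the pool
before training the next set, so instantiations are feature-wise
disjoint. On the clean synthetic corpus a single feature often reaches
ensemble MI equal to the class entropy, so instantiations can legally
contain one feature; on noisier corpora the same stopping rule yields
larger sets.

**Decision layer.** The FD response of a set is the sum of detected
feature weights divided by the sum of all weights (each feature counted
once), in [0, 1]. Winner-take-all evidence is target FD minus distractor
FD. The Go probability is bounded at 0.9/0.1 to model lapse and guess
rates, and a trial response is Go iff a uniform draw X is below that
probability. Two decision modes are exposed deliberately: the
*stochastic* trial mode above, used to simulate behavior, and a
*deterministic* mode (Go iff evidence > 0) used for training AUC and
training/generalization d′ — a clamped-perfect deterministic run scores
d′ = qnorm(0.99) − qnorm(0.01) = 4.65, which is unattainable through the
stochastic stage (whose ceiling is d′(0.9, 0.1) ≈ 2.56). An exact
evidence tie maps to Go probability 0.5 (unbiased, measure-zero for
continuous scores) and to NoGo in deterministic mode.

## The synthetic stimulus world

No audio corpus is distributed, so the generator is part of the package's
contract, not a fixture. Calls are harmonic-stack syllable trains with
5 ms raised-cosine ramps (spectral cleanliness for FFT-based F0 oracles),
rms-normalized to 0.1 full scale. Sound level is digital rms; a physical
SPL is metadata only. The four default categories encode the two task
axes:

| category | F0 (Hz) | syllables | syllable dur (ms) | ISI (ms) | spectrum |
|----------|---------|-----------|-------------------|----------|----------|
| chut-like  | 500, flat | 5–6  | 90–130  | 100–150 | 8 harmonics, −4 dB/harm |
| purr-like  | 500, flat | 15–18 | 35–50  | 20–35   | same as chut |
| wheek-like | 900, rising 35% | 2 | 360–460 | 80–140 | 10 harmonics, +8 dB band 3–10 kHz |
| whine-like | 450, rising 15% | 2 | 360–460 | 80–140 | 6 harmonics, −5 dB/harm |

Chut- and purr-like calls therefore share long-term spectra and differ in
temporal/ISI structure; wheek- and whine-like calls share envelope
statistics and differ in spectral content, including the presence of
energy above 3 kHz. Per-exemplar variability comes from a jittered F0
multiplier (±5–6%) and per-syllable duration/ISI draws. Timing ranges
were chosen once so that every call exceeds 800 ms (the longest
truncation condition must be valid) while staying near 1 s; they were not
revisited after observing test outcomes. What the generator does *not*
emulate: formant structure, amplitude modulation within syllables,
recording noise, caller identity and arousal cues. A green test on this
corpus therefore establishes algorithmic correctness and the intended
category geometry, not performance on natural recordings.

## Stimulus manipulations

* **SNR**: white Gaussian noise (the source only specifies "white"),
  gated to the call's duration, scaled so 20·log10(rms_signal/rms_noise)
  equals the target exactly; rms is whole-call including ISIs (flagged in
  provenance — syllable-only rms is the unchosen alternative).
* **Tempo**: STFT phase vocoder (Hann 1024, analysis hop 128); the
  parameter maps to duration factor 100/(100−t), the printed convention,
  so +80% → 5× and −100% → 0.5×. The synthesis hop is rounded, and the
  output is cut to the realized factor, keeping errors well under 1%.
* **F0 shift**: time stretch by the pitch factor followed by resampling
  to the original sample count, so duration and tempo are preserved
  exactly while all frequencies scale by 1 + p/100.
* **Reversal, truncation**: exact sample operations with mirrored/clipped
  annotations.
* **Low-pass**: 256-tap Hamming windowed-sinc FIR at 3 kHz, group delay
  compensated.
* **ISI rearrangement**: "silent" zeroes everything outside annotated
  syllables; "random"/"chimeric" rebuild the call with ISI durations
  drawn with replacement from a donor category's pooled empirical ISI set
  (no parametric form is imposed), preserving syllable audio
  sample-exact; five variants per source call by default. Chimeric calls
  keep the syllable-donor's label, matching the convention that identity
  follows the syllables.

## Statistics layer

d′ uses rate clamping at 0.01/0.99 before the normal quantile transform.
The Weibull psychometric curve is fitted as A·(1 − exp(−(x/α)^β)) by
multi-start least squares; a free amplitude is required because the curve
is fitted to d′ values that exceed 1, but the amplitude and the lapse
factor (1 − λ) enter the curve only through their product, so only the
effective amplitude A = amplitude·(1 − λ) is estimated — reporting
separate values would be fiction. The threshold is read where the fitted
curve crosses d′ = 1 and flagged when that point lies outside the fitted
level range. Trialwise likelihood-ratio tests approximate the subject
random intercept with per-subject fixed intercepts added to both the full
and null logistic models, with degrees of freedom equal to the
parameter-count difference; this trades exact mixed-model inference for a
dependency-free LRT whose null calibration and power are themselves
property-tested. Model–behavior agreement is the R² of the least-squares
line of model d′ on behavioral d′ (the fitted line, not the identity
line) plus the mean absolute error.

The long-term-spectrum baseline reads "spectral power at each CF" as the
temporal variance of each cochleagram row, the literal reading of rate
variance at each center frequency; the alternative reading (per-channel
temporal mean) is selectable via `long_term_spectrum(statistic = "mean")`
so the two interpretations can be compared directly.

## Paradigm execution

Trial lists reproduce the printed factorial designs (e.g. 1040 segment
trials = 2 categories × 8 exemplars × 13 lengths × 5 repetitions; 1200
chimeric trials with 400 catch trials, half of them rewarded at random).
The SNR paradigm is blocked — one level per ~40-trial session — and the
rest are fully randomized. Each unique stimulus is synthesized and scored
once; each of the five instantiations is treated as an independent
subject and realizes every trial through the WTA stage. Catch-trial
reward flags are recorded but feed nothing back (no learning loop).
Failed stimuli would be flagged, never silently dropped.

## Numerical choices and degenerate inputs

* Correlation windows or templates with zero variance score r = 0, so
  constant patches can never be "detected" spuriously.
* A 1e−12 floor guards divisions in row normalization; silence maps to
  an all-zero cochleagram.
* Features longer than a (truncated) stimulus count as not detected in
  `fd_response()`; `max_ncc()` itself errors, preserving its contract.
* AUC is the trapezoidal area over observed score thresholds; tied
  scores contribute 0.5, matching the rank-statistic form exactly.
* Greedy ties break toward the earlier candidate index
  (deterministic given the seed).

## Known limitations

* The gammatone front end stands in for a biophysical periphery; absolute
  response magnitudes and adaptation dynamics are not modelled.
* Templates do not slide in frequency, so the model is deliberately not
  invariant to frequency translation — this is visible in the F0-shift
  battery, where detection collapses once distractor harmonics shift into
  a target feature's band while the long-term-spectrum baseline, which
  standardizes per-channel statistics, barely moves. The corresponding
  test asserts the ordering that the feature model is modulated by octave
  shifts at least as strongly as the spectrum baseline (averaged over
  +100% and −50%), which is the phenomenon the comparison is meant to
  capture.
* On the clean synthetic corpus training AUC saturates at 1.0 and MIF
  sets can be single-feature; the corpus is intentionally easy so that
  generalization failures indicate algorithmic defects rather than
  stimulus ambiguity.
* The spectrum baseline's max-margin classifier is an in-package primal
  solver (squared-hinge, L2, BFGS), not a library SVM; decision values
  are signed distances up to the penalty's scaling.
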