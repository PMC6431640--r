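---
title: "Per-recording sleep-stage scoring and its validation apparatus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-recording sleep-stage scoring and its validation apparatus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypnoscore)
```

## The scoring model

`hypnoscore` automates wake–sleep stage scoring of polysomnography (PSG)
the way a sleep laboratory would hand it to a scorer: one recording at a
time. The workflow is deliberately *within-recording*: a brief training
set of manually scored epochs is sampled from the recording itself, a
classifier is fitted to those epochs' features, and every epoch of the
recording is then scored by the model. Nothing is transferred between
subjects, so electrode placement, amplifier gain and individual
physiology do not have to generalize — they are absorbed by per-recording
feature scaling and per-recording training.

An epoch is a fixed window of 4, 10 or 30 s (the conventional animal and
human lengths); epoch `i` covers `[(i-1)L, iL)` seconds and a trailing
partial epoch is dropped. Epochs are indexed from 1 throughout, the
natural R convention. The stage vocabularies are the AASM human set
(W, N1, N2, N3, REM) and the animal set (W, NREM, REM); `ARTIFACT` and
`UNDETERMINED` are carried alongside but are never stages: they are
excluded from training-set sampling and from evaluation, although every
epoch still receives a prediction.

### Features

The per-epoch feature battery is the standard sleep-staging repertoire,
documented as a replaceable interface rather than a fixed truth:

* EEG/EOG channels: log absolute and relative band powers over
  delta (0.5–4 Hz), theta (4–8), alpha (8–12), sigma (12–16) and beta
  (16–30), the log delta/theta ratio, the 95% spectral edge frequency
  and the zero-crossing rate. Band edges are clipped to the channel's
  Nyquist frequency; a band entirely above Nyquist is dropped with a
  warning, and relative powers are renormalized over the surviving
  bands so they always sum to 1.
* EMG channels: log RMS amplitude and log high-band (>30 Hz) power —
  muscle tone separates wake from sleep and collapses in REM.
* EOG pairs: the lag-0 cross-correlation per epoch (conjugate slow
  rolling eye movements versus saccadic REM activity).
* Accelerometer: log variance and log mean absolute first difference
  (head movement, the avian stand-in for nuchal EMG).
* Temperature: per-epoch mean and slope.

Spectral estimates are averaged modified periodograms: Hann-tapered
segments with 50% overlap, segment mean removed. The default segment is
2 s at every epoch length of 4 s and above. A shorter 1 s segment would
average more segments per 4 s epoch, but its 1 Hz resolution leaves only
three bins in the delta band and the resulting estimator variance is too
high to recover delta dominance reliably at the single-epoch level; 2 s
segments (0.5 Hz resolution, three averages per 4 s epoch) are the better
trade and are used uniformly.

All log-power features are z-scored per recording (never per cohort —
training and prediction are within-recording by design), with a
`1e-12` floor before the log so silent channels stay finite. The
z-scoring makes the features invariant to channel gain: multiplying a
channel by a positive constant leaves the feature matrix unchanged.

### Classifier and consistency rules

The classifier is a seeded random forest with class-balance weights.
This is an implementation choice, not a reproduction of any proprietary
scorer's internals: an ensemble of decision trees handles mixed-scale
features and small training sets, and exposes normalized per-class
scores that downstream smoothing needs. Stage assignment is the argmax
of the class scores; exact ties break toward the earlier vocabulary
label, so ambiguity resolves deterministically.

Predicted hypnograms can then be smoothed by *consistency rules*:
per-stage minimum bout durations in seconds, converted to epochs by
ceiling division (8 s at 4 s epochs is 2 epochs; 12 s is 3). The
smoother repeatedly takes the shortest violating bout (earliest on
ties) and relabels it to whichever neighboring stage has the higher
mean class score over those epochs; edge bouts take their single
neighbor, and ARTIFACT/UNDETERMINED runs neither move nor absorb.
Each merge reduces the bout count, so termination is guaranteed; the
output provably contains no sub-minimum bout and no stage absent from
the input. No stage-sequence grammar is imposed — REM directly after
wake is allowed, matching the "no other contextual rules" convention of
rodent microstructure analysis.

## The validation apparatus

Agreement between an automated and a manual hypnogram is quantified per
stage by sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)` and their
harmonic mean, the F-measure. Any 0/0 ratio is defined as 0, so a stage
absent from both hypnograms scores 0 rather than NaN. The *overall*
F-measure is micro-averaged — counts pooled across stages — which on
single-label data equals epoch accuracy; the macro average is reported
alongside for inspection. F-measures map onto the conventional
agreement bands, inclusive at the lower edge: intra-scorer ≥ 0.9,
excellent ≥ 0.85, strong ≥ 0.8, average ≥ 0.7, inadequate < 0.7.

Group contrasts use two-sided Student's t-tests (paired or independent)
plus Hedges' g with the plain pooled SD,
`g = (M1 - M2) / SD_pooled`; magnitudes are classified on |g| as
miniscule (< 0.2), small, medium and large (≥ 0.8). The small-sample
correction factor is available behind a flag but off by default, since
the plain form is the one conventionally reported in scorer-validation
work. Bonferroni adjustment is never automatic: the caller states the
number of planned comparisons (two planned paired tests give the 0.025
threshold).

Three secondary analyses complete the apparatus:

* **Transition-epoch exclusion.** Transition epochs are the first and
  last epoch of every bout (a length-1 bout counts once; recording-edge
  bouts are treated like any other, so the tagged count is exactly
  `sum over bouts of min(2, length)`). Exclusion is computed from the
  *predicted* hypnogram, and the corresponding reference epochs are
  simply not analyzed. Scoring errors concentrate at stage boundaries,
  so exclusion isolates how much disagreement is transitional rather
  than structural.
* **Stage reclassification.** Human-vocabulary simplifications applied
  identically to both hypnograms before evaluation: N1→W, N1→N2, the
  rodent-like W1NREM23 (N1→W, N2/N3→NREM) and NREM123 (N1/N2/N3→NREM).
  Reclassification commutes with evaluation by construction.
* **Ablation and size curves.** Channel ablation re-scores the same
  recording under channel presets (ALL, one EEG, two EOG, EEG+EMG, EEG
  only, EMG only, EEG+ACC, ACC only) while holding the training epoch
  indices fixed, so only the feature set differs. Training-size curves
  rerun sample→fit→predict→evaluate over a size grid with replicates,
  reporting mean ± SEM per stage and overall.

## The synthetic PSG generator

Real validation cohorts are not redistributable, so the package carries
a generator that produces recordings with known ground truth. It is a
first-class module, not a test shim.

Hypnograms come from a semi-Markov bout model: a stage holds for a bout
whose length is geometric with that stage's mean (minimum one epoch;
a dispersion knob switches to negative binomial), then hands over
according to zero-self-transition weights. Geometric bouts are
memoryless per epoch, which makes expected transition-epoch fractions
analytic: for mean bout length `1/p` epochs, `E[min(2, L)] = 2 - p`,
the property the bout-analysis tests check against.

Signals are stage-conditional additive Gaussian noise: EEG is white
noise shaped in the frequency domain to the stage's relative band-power
profile plus a flat noise floor carrying 15% of total power; EMG/ACC
are broadband noise at stage-dependent amplitude (wake > NREM > REM
muscle tone); EOG is slow 0.2–3 Hz noise. A lognormal per-epoch
amplitude jitter (sd 0.1 log units) roughens the amplitude scale. Only
the spectral and amplitude *contrast* between stages is modeled — there
are no spindles, K-complexes, eye-blink artifacts, line noise or
circadian drift. Consequently, passing end-to-end tests demonstrates
that the pipeline is correct and that the protocol behaves as designed
(training-size response, ablation direction, transition concentration
of errors), **not** that any particular F-measure will be attained on
real laboratory data, where agreement is bounded by inter-scorer
reliability long before classifier capacity matters.

Preset parameters, chosen once as conventional values for each system:

* `rodent` — 4 s epochs, W/NREM/REM, EEG+EMG at 128 Hz; mean bouts
  120/160/80 s; NREM EEG profile delta-dominant (0.70 delta, 0.10
  theta), REM theta-dominant (0.62 theta), wake mixed. The NREM delta
  dominance is pinned by a design constraint: the default preset must
  let the feature extractor recover the stage's band ordering in at
  least 99% of single 4 s epochs, and the band-power estimator's
  variance at 0.5 Hz resolution makes that unattainable with weaker
  dominance. Real rodent slow-wave sleep shows comparably strong delta
  dominance.
* `human` — 30 s epochs, five stages, two EEG + two EOG + chin EMG at
  128 Hz; long N2/N3/REM bouts (600/360/300 s); profiles follow the
  textbook progression (alpha/beta wake, theta N1, sigma-elevated N2,
  delta N3, theta REM with low EMG and high EOG).
* `avian` — 4 s epochs, EEG at 128 Hz plus a 64 Hz accelerometer in
  lieu of nuchal EMG; REM mean bout 7 s, derived analytically so the
  geometric bout distribution's 95th percentile is at most 16 s — avian
  REM episodes rarely exceed that — with wake distinguished from the
  wake-like REM EEG chiefly by head movement.

## Numerical choices and degenerate inputs

* Epoch counts guard against floating-point shortfall
  (`floor(x + 1e-9)`), so a 24 h recording at 4 s epochs is exactly
  21600 epochs.
* EDF I/O uses plain 16-bit EDF. Physical scaling limits are rounded
  outward to values whose 8-character ASCII header fields parse back
  exactly, making a write/read round trip lossless up to the 16-bit
  quantization step. EDF+ annotations and discontinuous records are
  out of scope.
* A recording with a flat channel still writes valid EDF (the physical
  range is widened by one unit rather than emitting zero gain).
* Dead epochs (zero total power) get a flat relative band profile and
  the log floor for absolute power; feature matrices are guaranteed
  finite.
* Training sampling with a stage rarer than the requested size takes
  all eligible epochs and warns; a stage with no eligible epoch is an
  error naming the stage. Longitudinal paired sampling splits evenly,
  odd remainder to baseline.
* Zero-variance paired comparisons are flagged degenerate rather than
  producing an infinite t; a zero pooled SD yields g = 0 when the means
  agree and a flagged NaN otherwise.

## Problem sizes used in the shipped checks

The package's own test suite and the acceptance script run the full
protocol scale for the rodent preset — a 24 h recording of 21600 4 s
epochs with the default 100 training epochs per stage, 20 seeded
replicates in the tests and 10 in the script — and desk scale for the
rest: an 8 h human-preset recording (960 epochs) for the training-size
curve over sizes 5/20/40/60 with 3 replicates, and a 2 h rodent-preset
recording (1800 epochs) for the ablation contrast. These sizes were
chosen to exercise every printed protocol constant at its stated value
while keeping a complete run in the tens of seconds.

## Known limitations

* The synthetic generator's cleanliness means F-measures on it sit near
  the ceiling; it can falsify the pipeline but cannot calibrate
  real-world accuracy.
* Only uniform epoch grids are supported; sub-epoch (e.g. 1 s sliding)
  manual scoring must be resampled onto a grid upstream.
* The consistency-rule smoother is greedy; it satisfies all minima but
  does not claim a globally optimal relabeling.
* Modality inference from channel-label prefixes is a heuristic;
  montage-style labels ("C3:A2") need the explicit override map.
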