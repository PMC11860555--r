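---
title: "Methods: synthetic wearable signals and feature-based anxiety classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic wearable signals and feature-based anxiety classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearanx)
```

## The problem

Feature-based anxiety classifiers for wearables are usually trained on data
recorded under controlled conditions — a seated subject, a fixed room — and
then expected to work during everyday life, where motion and environmental
noise corrupt every channel. `wearanx` is a test bed for that whole chain:
it synthesises multimodal recordings (ECG, respiration, electrodermal
activity, blood volume pulse, skin temperature, chest and wrist
accelerometry) whose anxiety structure is known exactly, pushes them through
signal conditioning, beat detection, windowed feature extraction,
STAI-score-based labelling, class rebalancing, cross-validated training of
seven classifier families, and a no-fine-tuning transfer evaluation across
noise-augmented copies of the data.

Because every recording carries its own ground truth (beat times, breath
timing, SCR onsets, condition truth per interval), each stage can be scored
against what the generator actually did, which is impossible with real
recordings.

## The signal generators

Generators are deliberately template-level: the goal is that rates,
variability, asymmetries and class differences are *exactly known and
recoverable*, not that waveform morphology is clinically faithful. No
attempt is made at 12-lead ECG morphology, pulse-wave physiology, or EDA
tonic/phasic decomposition realism.

* **ECG** — RR intervals are i.i.d. normal (mean `60/hr`, sd `sdnn`)
  truncated to [0.3, 2] s; this is the simplest model that exposes the
  mean/spread statistics the feature extractor consumes (no autoregressive
  or point-process structure). Beats are Gaussian QRS bumps (~40 ms wide,
  amplitude 1) over 0.2 Hz sinusoidal baseline wander (amplitude 0.1) and
  white noise (sd 0.02).
* **Respiration** — piecewise-sinusoidal breath cycles of duration
  `60/resp_rate` with 3% multiplicative jitter; the inhale occupies
  `ie_ratio/(1+ie_ratio)` of each cycle, so inhale/exhale asymmetry is a
  generator parameter.
* **EDA** — tonic level plus slow drift plus skin-conductance responses
  arriving as a Poisson process (bi-exponential pulses, 1 s rise / 4 s
  decay, ~0.3 uS); ground-truth onsets ride along as an attribute.
* **BVP** — a pulse train on the *same* beat times as the ECG (delayed by a
  fixed 0.25 s transit time inside sessions), systolic plus dicrotic bumps,
  so its dominant spectral frequency equals the heart rate.
* **Accelerometry** — gravity (z on the chest, tilted onto x at the wrist,
  a fixed documented convention) plus an activity term: seated is white
  noise of sd 0.01 g, standing adds slow sway, walking a 2 Hz / 0.3 g step
  oscillation, and "variable" alternates regimes on random dwell times
  (mean 30 s).
* **Temperature** — baseline plus a random-walk drift; the anxious state
  lowers distal temperature (peripheral vasoconstriction).

Anxious-state physiology is an additive shift per subject: by default
+15 bpm heart rate, −0.02 s SDNN, +4 breaths/min, +6 SCR/min, −0.5 °C.
No published effect sizes are asserted here — the defaults are plausible,
clearly visible to the pipeline, and exposed in `subject_profile()`; what
passing tests show is that the *pipeline recovers whatever structure the
generator put in*, not that real anxiety looks like this.

Sampling rates follow the two-device setup the pipeline emulates: chest
ECG 256 Hz, respiration 128 Hz, chest accelerometer 64 Hz; the wrist-side
rates are not fixed by that convention, so the package adopts public
wrist-device documentation values (BVP 64 Hz, EDA 4 Hz, TEMP 4 Hz, wrist
accelerometer 32 Hz) and records them in the JSON sidecar so they are
overridable.

**Cohorts.** `generate_cohort()` draws subject profiles around
population-typical values and builds one session per subject:
*calibration* alternates relaxation and cold-pressor blocks (seated, fixed
environment, ~42% anxious time); *in-lab* runs relaxation, TSST and
seated/walking Stroop blocks (~41% anxious); *in-the-wild* is unconstrained
"wild" time with variable activity, 3x channel noise, and anxious time
allocated exactly at the configured fraction (default 19.34%) in randomly
ordered blocks. STAI Y6 scores are sampled per interval on the matching
side of the cutoff, crossing sides with probability 0.05 by default — this
label noise is what keeps classification accuracies realistically below
the ceiling.

## Signal conditioning

* **Low-pass filtering** uses a digital Butterworth design applied forward
  and backward (zero phase, magnitude response squared). The filter order
  is 4 per pass — a common biosignal default; the conditioning step filters
  EDA at 5 Hz and accelerometry at 13 Hz and leaves other channels alone.
  Channels already sampled at or below twice the cutoff (EDA at 4 Hz) are
  band-limited by the device and skipped. Edges are handled by odd
  reflection padding plus DC-steady-state initial filter conditions, so a
  constant series passes through bit-exactly.
* **Outlier removal** is a Hampel filter (rolling median ± 4 scaled MADs,
  window ~1 s); flagged points become missing values rather than being
  replaced, so the imputation stage decides their fate. A constant window
  has MAD 0 and flags nothing.
* **Imputation** replaces missing points with the segment mean when the
  missing fraction is at most 0.2 (configurable — the drop rule is a
  package choice); heavier corruption drops the segment.
* **Normalisation** is min–max to [0, 1], computed per segment by default
  (a per-subject flag would be the alternative; per-segment is the default
  because segments are the unit every other stage operates on).
* **Noise augmentation** adds white Gaussian noise with variance
  `var(series)/snr_linear`. The SNR is a *linear power ratio* — the printed
  augmentation range 0.0001–0.6 is dimensionless and below 1, which rules
  out a dB reading (0.0001 dB would be a no-op). Noise is injected into
  the raw channels *before* feature extraction, matching a pipeline in
  which augmentation sits upstream of the ML stage; a feature-space mode
  is not provided.

## Beat detection

`ampd_scalogram_peaks()` implements multiscale peak detection: after linear
detrending, a local-maxima scalogram is built over scales
`k = 1..ceil(n/2)-1` (row `k` is 0 where `x[i]` strictly exceeds both
`x[i-k]` and `x[i+k]`, and `1 + U(0,1)` elsewhere); the scale `lambda`
minimising the row sum is selected; peaks are the columns whose entries
vanish at every scale up to `lambda` (zero column standard deviation over
the truncated scalogram — with random fills, all-zero and zero-variance
coincide almost surely). The random fill is seeded (default 42) so the
criterion is reproducible, and the implementation consumes R's RNG stream
row-major over all positions, which lets a plain-R brute-force
reimplementation verify it entry-for-entry.

Long records are processed in 6 s windows with 50% overlap (the scalogram
is quadratic in window length), merged, and passed through a 0.25 s
refractory merge (240 bpm physiological ceiling) keeping the
higher-amplitude peak.

One empirical finding shaped the design: on spiky signals whose baseline
carries broadband noise, the row-sum minimum drifts to very small scales,
and isolated noise maxima then survive the all-scales test. (The classic
multiscale argument assumes a smooth oscillation, where the set of
scale-`k` maxima grows with `k`; an impulse train over white noise does not
provide that growth.) Sensitivity is unaffected — every true beat is still
found — but precision collapses, which would corrupt every RR-derived
feature. The detector therefore applies a relative-amplitude gate after the
refractory merge: peaks below 0.4 of the 95th-percentile detected-peak
amplitude are discarded. The high-quantile reference keeps the gate on the
beat cluster even when spurious detections outnumber beats. With the gate,
detection on the package's noisy-ECG benchmark (20 records, 5 min, linear
SNR 10, heart rates 60–100 bpm) is essentially perfect in both sensitivity
and precision, and accuracy degrades monotonically as SNR falls.

Detection accuracy is scored as matched-within-±50 ms over true beats
(greedy one-to-one matching in time order); since the headline "98%
detection accuracy" convention does not fix a metric, sensitivity and
positive predictive value are reported alongside, and the package gates on
matched/true.

## Features and labels

Windows are 60 s long with a 30 s shift — a package choice (one window
holds ≥ 2 breath cycles at the slowest plausible rate and enough beats for
stable HR statistics); both values sit in `window_spec()`. Each window
emits 21 features across six modalities (names in
`feature_modality_map()`):

* `ECG_bpm/min/max/std` are statistics of the *instantaneous heart-rate
  series* (60/RR), not raw ECG voltage — they co-occur with `ECG_bpm` and
  follow time-domain HRV convention. Windows with fewer than 3 beats drop.
* Respiration features segment the smoothed (2.5 Hz zero-phase low-pass),
  mean-removed signal at rising zero-crossings; inhale duration is
  trough-to-peak and exhale peak-to-trough, because for a smooth
  respiration trace the zero-crossings sit mid-limb while the extrema mark
  the actual breath turns. The 2.5 Hz smoothing cutoff keeps the waveform
  harmonics that carry inhale/exhale asymmetry (a 1.5 Hz cutoff biases the
  measured ratio upward by ~10% at ratio 0.6; 2.5 Hz halves that).
  `Resp_min`/`Resp_mean` are raw-amplitude statistics.
* `BVP_peak_freq` is the periodogram argmax over the cardiac band
  0.5–3.5 Hz (window ≥ 10 s for resolution); `EDA_*` and `TEMP_mean` are
  sample statistics; `ACC_net_w_*` are wrist-device net-acceleration
  statistics, `ACC_x_*` wrist x-axis, `ACC_x_C_std` the chest x-axis spread
  (w = wrist, C = chest — the two-device reading of the feature names).

All spreads are population (divisor *n*) standard deviations. A window's
label comes from the STAI score of the annotation covering its *midpoint*
(unambiguous for straddling windows); rows with any failed extractor are
dropped and counted, never emitted with NAs.

STAI Y6 scores (range 6–24) dichotomise at 11, with the boundary score
labelled anxious; a `strict` flag flips that reading. Undersampling keeps
every minority row and `round(n_min (1-p)/p)` uniformly sampled majority
rows for target minority fraction `p`; sampling is seeded and deliberately
not subject-stratified (a subject-stratified variant would change
cross-validation leakage characteristics; the plain uniform rule is the
documented default). The windowed feature table is what gets balanced —
balancing before windowing would entangle the class ratio with window
drop-out.

## Models, validation and importance

Seven families: decision tree (`rpart`), random forest (`randomForest`),
LDA (`MASS`), k-nearest neighbours (`class`), AdaBoost, RBF-kernel SVM
(`e1071`) and gradient-boosted trees (`xgboost`). AdaBoost is a
SAMME-style discrete booster over depth-2 `rpart` stumps implemented in
the package. Scale-sensitive families (LDA, KNN, SVM) standardise inputs
with training-set moments.

`crossval_evaluate()` splits the table into 5 stratified test folds; for
each fold the remaining rows are split 80/20 into training and validation,
every setting in a small fixed hyperparameter grid (tree depth for DT,
k ∈ {5, 11} for KNN, cost ∈ {1, 10} for SVM; single defaults elsewhere) is
fit on the training part and scored on validation, and the winner is scored
once on the held-out fold. Five repetitions with distinct fold seeds are
averaged. F1 is binary with the anxious class positive. Folds are
row-level stratified, not subject-grouped — with synthetic cohorts both
regimes are available to the user by subsetting, and row-level is the
default because it matches the table-level protocol the rest of the
package assumes.

Per-model importances: impurity-based for the tree families, absolute
standardised coefficients for LDA (and linear-kernel SVM), seeded
permutation importance (20 shuffles) for KNN and nonlinear SVM; each
vector is normalised to sum 1. `aggregate_importance()` squares each
feature's importance within a model, sums across models, and divides by
the total of those squared sums, so the weights form a proper distribution
(the raw-total denominator, which does not normalise, is available behind
a flag); the squaring emphasises features that matter consistently across
models. Weights roll up to modality totals, and the dispersion of a
model's weights is reported as Shannon entropy next to its transfer
scores — the package computes that statistic but deliberately does not
assert "flatter importance transfers better" as a test.

## Transfer evaluation

`train_source()` fits a family on the full source table; `evaluate_transfer()`
predicts a target table through the frozen model with name-based schema
alignment and no refitting (tests assert the model object is bit-identical
after evaluation). `snr_sweep()` injects per-channel Gaussian noise into
the raw source recordings at each grid SNR, re-extracts features, retrains,
and evaluates on every target plus a fixed stratified within-source
holdout. The default grid {0.0001, 0.001, 0.01, 0.1, 0.3, 0.6} spans the
augmentation range endpoints on a roughly logarithmic spacing (only the
endpoints are pinned by convention; the grid is fully configurable, and
`Inf` gives the no-augmentation baseline). The source cohort is itself
synthetic, so the source/target distribution shift is controllable through
the generator configs rather than fixed by an external dataset.

## Numerical choices and degenerate inputs

* Truncated-normal RR draws use rejection sampling; `sdnn = 0` short-cuts
  to a metronomic train.
* The first beat sits half an RR interval into the record so whole-beat
  trains fit inside round durations.
* Min–max normalisation on a constant series raises a degenerate-range
  error (the caller decides whether to drop); Hampel on constant windows
  flags nothing; fully missing segments always drop.
* Downsampling takes exact decimation when the rate ratio is an integer and
  linear interpolation on the anti-aliased series otherwise; output length
  is exactly `floor(n fs_out / fs_in)`.
* Ties in the scalogram argmin resolve to the smallest scale
  (`which.min`); the seeded uniform fill makes exact ties measure-zero.
* F1 with no positive truth and no positive predictions is 0 by
  convention, as is PPV with no detections.
* All stochastic entry points take explicit seeds, derive per-component
  sub-seeds with a fixed integer hash, and restore the caller's RNG state.

## Problem sizes in the shipped tests and scripts

The test suite runs generators at 10–20 subjects × 200–600 s, the detector
benchmark at 20 × 5-minute records, model checks at 1000 rows, and the
transfer property at 10 seeded repetitions of a 3-subject source cohort —
sizes chosen so the full suite exercises every claim at desk scale. The
`analysis/` drivers use 6 subjects × 600 s per cohort. All of these are
configuration, not limits: the same code runs larger cohorts unchanged.

## Known limitations

* Waveform morphology is schematic; results say nothing about
  morphology-sensitive algorithms (e.g. QRS classifiers).
* Label noise is interval-level Bernoulli; real STAI measurement error is
  likely autocorrelated within subjects.
* The anxious-state effect sizes are package defaults, not estimates;
  absolute classification accuracies on synthetic cohorts should not be
  read as predictions for real populations — the meaningful outputs are
  recoveries, orderings and degradation curves.
* Session concatenation joins intervals independently, so channel state is
  discontinuous at block boundaries (a one-beat artefact at each join).
* Per-channel SNR injection scales noise to each channel's variance, so
  near-constant channels (temperature, resting accelerometry) receive
  little absolute noise; "SNR 0.0001" destroys information in dynamic
  channels first.
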