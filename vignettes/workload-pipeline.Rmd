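---
title: "Assessing cognitive workload from EEG and eye tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing cognitive workload from EEG and eye tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cogload` estimates an operator's mental workload — binary low (LCL) versus
high (HCL) cognitive load — from two synchronized physiological streams: a
32-channel EEG recording (250 Hz, band-passed 0.5–30 Hz with a mains notch at
acquisition) and a wearable eye tracker (2D gaze plus both pupil diameters at
60 Hz). The motivating setting is robot-assisted surgical training, where
task difficulty manipulations (inverted teleoperation; intraoperative
bleeding) act as ground-truth workload labels, but nothing in the pipeline is
specific to surgery. This vignette explains the models, the free parameters,
the synthetic-data generator used for validation, and the numerical and
design choices made where the procedure left them open.

## EEG spectral features

Continuous EEG is cut into non-overlapping 5 s epochs. Each epoch is a
32 × 1250 matrix of microvolt samples. Per channel we estimate the power
spectral density with Welch's method using 4 s Hann-tapered, linearly
detrended segments at 50 % overlap. One detail deserves note: at the nominal
half-window step, a 5 s epoch admits only one full 4 s segment, which would
discard the final second. We therefore add an end-anchored segment, so the
two segments cover `[0, 4]` s and `[1, 5]` s and every sample contributes.
The estimator stays deterministic, and the oracle tests (agreement with a
trapezoid-integrated raw periodogram to within 5 %) absorb the residual
estimator differences.

Band-power coefficients are the PSD mass in delta (0.5–4 Hz), theta
(4–8 Hz), alpha (8–12 Hz) and beta (12–30 Hz), each divided by the total
mass over the 0.5–30 Hz passband. We treat the acquisition passband as "the
total energy of the signal", which makes the normalization well defined:
the four bands partition the passband (half-open intervals, last closed, so
no bin is counted twice), every coefficient lies in `[0, 1]`, and the four
coefficients of a channel sum to one. The 12–30 Hz range is labeled beta
throughout — it is occasionally called low gamma elsewhere, but 12–30 Hz is
conventionally beta. Stacking 32 channels × 4 bands channel-major gives the
128-element feature vector of one epoch.

For the recurrent classifier, a sliding window groups `L` consecutive
epochs of one trial into a 128 × L sequence (so a sequence spans `5 L`
seconds). The window stride defaults to 1 epoch for sequence construction,
following the sliding-window description; the evaluation loop instead uses
non-overlapping windows (stride = window length) so that train, validation
and test windows never share raw samples — with overlapping windows a
chronological split would leak signal across partitions at every boundary.

## Eye-tracking features

Gaze is cut into 15 s epochs — the shortest span on which fixation
statistics are stable — and reduced to five features: mean left-eye pupil
diameter (mm), number of fixations, mean fixation duration (ms), scan-path
length (summed Euclidean distance between consecutive fixation centroids,
in scene units), and the nearest-neighbour index.

Fixations come from a dispersion-based (I-DT) detector: consecutive valid
samples are grouped while their dispersion (x-range + y-range) stays within
a threshold, and groups covering at least 85 ms are kept. The dispersion
threshold (default 0.02 in normalized scene coordinates) is the detector's
main free parameter; the 85 ms floor is fixed by the procedure. Blink gaps
(validity 0) terminate candidate groups and are excluded everywhere — they
are never interpolated. A fixation's duration counts one sampling period
per member sample, so at 60 Hz the effective floor is 6 samples (100 ms),
the smallest duration not below 85 ms.

The NNI is the observed mean nearest-neighbour distance (self-pairs
excluded) divided by the same statistic averaged over 100 seeded sets of
equally many points drawn uniformly in the scene rectangle. The printed
index bounds in the defining sum are ambiguous; we adopt the standard
mean-nearest-neighbour reading with denominator equal to the number of
fixations, which calibrates the index to 1 for uniformly random sets (a
property the test suite verifies to ±0.15 over 100 seeds). The NNI is
scale-invariant; scan-path length is not, so its units are declared "scene
units" and depend on the gaze coordinate convention.

Epochs in which a feature cannot be computed (no valid pupil sample, fewer
than two fixations) carry `NA`. Imputation happens only at model-fitting
time, using per-subject means computed from the training split, so no test
statistic leaks into training.

## Classifiers

**Recurrent model (EEG sequences).** A per-timestep affine layer reduces
each 128-vector to 64 dimensions (linear; the LSTM supplies the
nonlinearity), followed by two bidirectional LSTM layers of 32 hidden units
whose final states feed a sigmoid output. Training minimizes binary
cross-entropy with Adam (learning rate 1e-3), 100 epochs, batch size 10.
The grid search covers 1–3 LSTM layers, uni/bidirectional connectivity and
dropout {0.45, 0.5} (the printed dropout "range" only admits this two-point
reading). Dropout applies between LSTM layers and before the output head.

**Feed-forward model (fused features).** The 128 × L window is collapsed by
time-averaging into one 128-vector and then channel-averaging into 4 band
coefficients, which are concatenated with the 5 aggregated eye features —
nine inputs, deliberately balanced between modalities. The network is a
stack of dense–batchnorm–ReLU–dropout blocks (grid: 4–8 hidden layers,
dropout {0.45, 0.5}) with a sigmoid output, trained identically. Hidden
widths are not stated by the procedure; we use a constant 64 units per
layer. We initially tried widths halving from 64 down to 8, but under
dropout 0.5 the narrow layers cannot pass enough signal and the network
fails to fit even linearly separable data; constant-width layers converge
reliably, so that is the default.

Eye features are aggregated over a fused window by averaging the 15 s eye
epochs whose span overlaps the window. Windows are multiples of 5 s (the
EEG epoch), so they cannot also sit on 15 s boundaries in general; overlap
aggregation is the consistent generalization.

Because no deep-learning framework is available in the target environment,
both networks, Adam, batch normalization and backpropagation (including
BPTT through the bidirectional stacks) are implemented directly in R matrix
algebra. The models are small (9–128 inputs, tens of units), so this is
fast; correctness rests on finite-difference gradient checks in the test
suite rather than on a framework.

**Baselines.** KNN (k = 5), random forest (200 trees) and an RBF SVM wrap
`class`, `randomForest` and `e1071` behind the same train/predict surface.
They are comparison points, not the contribution.

**Evaluation.** Within each subject, windows are split chronologically
60-20-20 (train/validation/test; `floor` sizes for the first two, remainder
to test). Models train on pooled training windows; reported accuracy is the
mean over subjects of per-subject test accuracy at the 0.5 threshold. A
session-to-session mode trains on all but the last two sessions, validates
on the second-to-last and tests on the last, probing day-to-day signal
drift. The *cognitive index* summarizing one task execution is the mean
predicted HCL probability over its windows — the underlying construct has
no canonical definition, so this interpretation is flagged as ours.

## Scalp topography

Per channel and band, normalized coefficients are averaged within condition
over all trials and subjects, and the contrast is expressed in decibels as
`10 log10(HCL / LCL)` — power-quantity decibels, with the low-load
condition as baseline. Channels with `|dB|` at or below a display threshold
(0.2 dB by default) are set to the neutral colour before thin-plate
interpolation over the head disk; red marks increased activity under high
load, blue suppression. Electrode positions are idealized 10-10 spherical
angles projected azimuthally (vertex at the centre, outer ring on the unit
circle).

One normalization consequence worth knowing: because coefficients are
relative, raising theta power on a channel necessarily lowers that
channel's other three coefficients, so an injected theta increase shows as
theta-red plus faint blue in the other bands at the same site. This is a
property of relative band power, not an artifact.

The 0.2 dB mask is a display criterion, not a significance test. With the
generator's realistically narrowband rhythms, a single per-epoch band-power
estimate carries roughly 50 % relative noise, so condition means need a few
thousand epochs before sampling noise falls safely below 0.2 dB. The
acceptance checks therefore feed the mask about two hours of synthetic
signal per condition; anything much shorter shows spurious masked channels
for purely statistical reasons — as would real data at the same scale.

## The synthetic generator

No public recordings exist for this procedure, so the generator is a
first-class module that emulates the two acquisition protocols:

* **dataset1** — six 5-minute trials per session, three LCL (normal
  teleoperation) and three HCL (inverted teleoperation), order randomized
  per session; EEG only; 8 subjects × 4 sessions in the nominal study.
* **dataset2** — ten 3-minute trials alternating LCL/HCL (starting LCL, the
  natural reading of an alternating protocol); EEG + gaze; 10 subjects × 1
  session nominally.

EEG is synthesized spectrally: per channel, four 2 Hz wide band-limited
Gaussian oscillators (centred in their bands; RMS 4/3/3/2 µV for
delta/theta/alpha/beta) ride on a 1/f background (exponent 1, 3 µV RMS)
confined to the 0.5–30 Hz acquisition passband. A hermitian
complex-Gaussian spectrum is inverse-transformed, giving exact analytic
control of per-band variances (verified against the configured composition
to within 10 %). Under HCL, oscillator amplitudes scale by 1.5 (theta) and
1.3 (alpha) on the fronto-temporal channel sets where workload effects are
expected, and by 0.8 (delta) on F7/FC5/T8 — the qualitative physiological
signature of high load. Magnitudes are free parameters chosen to make a
25 s fused window reliably classifiable, since the procedure reports only a
display threshold, not effect sizes.

Gaze is an alternating fixation/saccade process: uniform fixation centres,
log-normal durations (median 280 ms, truncated at 120 ms under LCL),
within-fixation jitter well inside the dispersion threshold, 1–3-sample
saccades, slow AR(1) pupil drift (stationary SD 0.1 mm) plus measurement
noise, and exponential blink gaps marked invalid. HCL adds 0.4 mm to the
mean pupil diameter and divides fixation durations by 1.3. The truncation
keeps HCL durations above the 85 ms filter so the fixation-rate effect
survives detection.

Studies add per-subject log-normal jitter (SD 0.15) on all effect sizes and
per-session amplitude drift (SD 0.10) plus a small pupil baseline shift —
the inter-subject and day-to-day variability that motivates
session-to-session evaluation. Everything derives from one master seed.

What the generator does **not** emulate: volume conduction and realistic
channel covariance, EMG/EOG/movement artifacts, nonstationary rhythms,
task-locked gaze semantics (fixations have no scene meaning), or label
noise — condition labels are exact by construction. Passing recovery tests
on this generator therefore demonstrates that the pipeline's machinery is
correct and its statistics well calibrated, not that real surgical EEG is
classifiable at any particular accuracy.

## Numerical choices and degenerate inputs

* Probabilities are clipped to `(1e-7, 1 - 1e-7)` inside the loss; batch
  normalization uses eps 1e-5 and momentum 0.1 on running statistics;
  forget-gate biases initialize to 1 (standard LSTM practice).
* Grid-search ties break towards the smaller model (fewer parameters).
* A channel with zero passband energy is a hard error (degenerate input),
  as is a training set containing a single class, an all-invalid gaze
  stream, and annotations extending beyond the synchronized interval
  (rejected with a report).
* Stream CSVs are written with 17 significant digits so sessions round-trip
  bit-identically; readers use correctly-rounded base-R parsing.
* Determinism: every stochastic step (generation, NNI reference draws,
  weight initialization, batch shuffling, dropout) is seeded, and RNG state
  is always restored, so identical seeds give bit-identical results.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the full pipeline at sizes
chosen to finish comfortably on one CPU: the recovery experiment uses the
nominal 10-subject dataset2 study over 5 master seeds (2 in the script) for
the feed-forward model at 25 s windows, under both nominal and null effect
specifications, and a 2-subject dataset1 study for the recurrent model's
10 s versus 100 s comparison; the topographic 0.2 dB checks average about
1400 five-second epochs (two hours of signal) per condition. These sizes are the package's validation choices, not
statements about the original studies.

## Known limitations

* The recurrent model trains in plain R; at the package's model sizes this
  costs seconds per model but would not scale to wide LSTMs or long
  sequences.
* XDF container input is not implemented (tabular CSV only); live
  streaming acquisition is out of scope by design — the package replays
  files recorded on a shared clock and assumes clock offsets were corrected
  upstream.
* The fixation detector is I-DT only; velocity-based detectors (I-VT) may
  label fast smooth pursuit differently.
* Accuracy is the only headline metric (as in the procedure's evaluation);
  no ROC machinery is provided.
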