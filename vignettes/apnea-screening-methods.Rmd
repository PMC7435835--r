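---
title: "Methods: per-minute apnea detection and OSA screening from single-lead ECG"
author: "apneaCNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-minute apnea detection and OSA screening from single-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneaCNN)
```

## The screening problem

Obstructive sleep apnea (OSA) is diagnosed with overnight
polysomnography, which is expensive and burdensome. Because apnea
episodes leave a strong autonomic imprint on the heart — cyclic
bradycardia–tachycardia swings time-locked to the obstruction cycle —
a single-lead ECG carries enough information to pre-screen for OSA.
apneaCNN implements such a screener: every 1-minute ECG segment
(6000 samples at 100 Hz) is classified as normal (`N`) or apneic
(`A`) by a 1D deep convolutional network operating on the raw
filtered waveform, with no QRS detection, no RR-interval series and
no hand-built features. Per-recording screening then follows from the
minute calls alone: with $L$ minutes of which $N$ are called apneic,
the estimated apnea–hypopnea index is

$$\widehat{AHI} = \frac{60\,N}{L} \quad \text{events/hour},$$

and a recording is called OSA when $\widehat{AHI} \ge 5$ (inclusive,
the AASM cutoff).

## Preprocessing

Each minute is conditioned independently, mirroring streaming
acquisition:

1. **Bandpass filtering.** A 4-pole digital Butterworth bandpass,
   0.5–15 Hz at 100 Hz sampling, designed via the bilinear transform
   (`designBandpass()`, backed by `signal::butter`). The low edge
   removes baseline wander (respiration, electrode drift, < 0.5 Hz),
   the high edge suppresses high-frequency interference while keeping
   the QRS energy. "4-pole" means a degree-4 denominator — an order-2
   Butterworth prototype mapped to a bandpass — which at these
   settings yields the numerator $b_0[1, 0, -2, 0, 1]$ with
   $b_0 = 0.1242$; a textbook "order-4" bandpass prototype would have
   8 poles and a 9-term difference equation instead. The filter runs
   as a causal direct-form recurrence with zero initial conditions
   (`applyFilter()`); no forward–backward pass is used, so each
   minute carries a short start-up transient that the classifier sees
   as part of the data contract.
2. **Z-score standardization.** $(x - \mu)/\sigma$ per minute
   (`zScore()`), with $\sigma$ the *population* standard deviation
   (divide by $n$). The convention matters only for exact
   reproducibility — at $n = 6000$ the Bessel factor is
   $\sqrt{6000/5999} \approx 1.00008$ — but one convention had to be
   fixed. A flat-line minute ($\sigma = 0$) standardizes to zeros
   with a warning rather than failing, so one corrupt minute cannot
   abort a whole-recording run.

## The classifier

`modelConfig()` describes the architecture family; the defaults are
the reference network:

* `nFeatureLayers` (default 10) identical feature-extraction blocks:
  1D convolution (45 filters, kernel 32, 'same' padding) → batch
  normalization → ReLU → max pooling (size 2, stride 2) → dropout
  (rate 0.5). Pooling halves the time axis with floor rounding, so
  the 6000-sample input shrinks 6000 → 3000 → … → 11 → 5 over ten
  blocks; the receptive field roughly doubles per block.
* a flatten layer (5 × 45 = 225 features for the reference depth);
* `nClassLayers` (default 4) classification blocks: fully connected
  512 → batch normalization → ReLU → dropout(0.5);
* a 2-unit softmax head.

All weights are He-normal initialized ($\mathcal{N}(0, 2/\text{fanIn})$)
from an explicit seed; two builds from the same seed are bitwise
identical. The reference configuration has
`r format(countParameters(modelConfig()), big.mark = ",")` parameters
(~1.5 million) counting convolution and FC weights and biases plus 4
batch-normalization parameters per channel (scale, shift, moving mean,
moving variance); `countParameters(cfg, trainableOnly = TRUE)` excludes
the moving statistics.

Because no deep-learning framework is part of the package's
dependency set, the network is implemented natively: activations are
kept channels-first as a $(C \times B\!\cdot\!L)$ matrix, convolution
runs as $K$ offset BLAS GEMM calls (no materialized im2col buffer;
`src/conv1d.c`), and batch normalization, pooling, dropout and the
softmax head are vectorized R. The backward pass is exact
backpropagation, verified in the test suite against central finite
differences layer by layer.

Numerical conventions the reference description leaves open were
fixed as follows and are recorded in the configuration object:

* batch-normalization momentum 0.99 and epsilon $10^{-3}$ (Keras-era
  defaults);
* max-pool ties (equal neighbours) keep the earlier sample;
* dropout is "inverted" (scaled by $1/\text{keep}$ during training),
  so inference needs no rescaling and is fully deterministic;
* a hard label is `A` when $P(A) > 0.5$; the measure-zero tie
  $P(A) = 0.5$ predicts `N`.

## Training protocol

`trainOnce()` runs minibatch Adam (learning rate $10^{-3}$,
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\varepsilon = 10^{-7}$ — cited
framework defaults) on categorical cross-entropy, batch size 10. No
class weighting or resampling is applied: the reference datasets are
imbalanced (roughly 61/39 normal/apnea) and are trained raw. Per
epoch, training metrics are averaged over minibatches in training
mode while validation metrics come from one deterministic full pass —
the two are deliberately not comparable early in training (dropout
and batch statistics depress the training-mode numbers). The weights
of the epoch with the best validation *accuracy* (never loss) are
checkpointed; `runExperiments()` repeats training from independent
He-normal initializations and keeps the best checkpoint, breaking
ties toward the lowest experiment index. Every random choice — batch
order, dropout masks, initialization — derives from explicit seeds,
so any run is exactly reproducible.

## Evaluation and diagnosis

Per-minute performance uses apnea as the positive class:
accuracy $(TP+TN)/\text{total}$, sensitivity $TP/(TP+FN)$,
specificity $TN/(TN+FP)$, each reported in percent rounded half-up to
one decimal (the literature's reporting convention; plain `round()`
rounds half to even). A zero denominator yields `NaN` with an
explicit "undefined" flag, never a silent zero. The ROC curve sweeps
every distinct score threshold and the AUC is the trapezoidal
integral, which the tests verify to coincide exactly with the
normalized Mann–Whitney pairwise statistic.

Per-recording screening applies the AHI estimator above. Two Pearson
correlations of the estimated AHI are reported separately because the
comparison literature conflates them: against the *reference* AHI
(the polysomnography value shipped with a database) and against the
*annotation-derived* AHI ($60 N_{\text{annotated}}/L$). On synthetic
cohorts the two coincide by construction.

## The synthetic cohort generator

`generateCohort()` exists so that every stage — IO, preprocessing,
training, evaluation, diagnosis — is exercisable end-to-end with no
access to physiological recordings. Each minute is a quasi-periodic
train of Gaussian-shaped QRS surrogates (width ~12 ms, ~1 mV) placed
by integrating an instantaneous heart-rate profile, plus sinusoidal
baseline wander below 0.5 Hz and additive white noise. The label
signal is the physiological correlate real ECG-based detectors
exploit:

* **Apnea minutes**: cyclic heart-rate modulation — a 20 bpm
  peak-to-peak swing with a 50 s period (the brady–tachycardia cycle;
  configurable within 25–100 s) — plus a mild (15%) EDR-like beat
  amplitude modulation at the same period.
* **Normal minutes**: only respiratory sinus arrhythmia (~3 bpm at
  0.25 Hz) and small rate jitter.

Defaults (72 bpm base rate, 0.2 Hz / 0.4 mV wander, 0.03 mV noise)
were fixed once from the physiology the apnea-ECG literature
describes. The default cohort is deliberately desk-scale: 8 records
of 60 minutes, 5 of 8 records OSA-like, overall apnea-minute
prevalence ~0.35 (the released reference dataset has 0.39). Per-record
reference AHI is computed from the planted labels, so cohorts span
clearly-OSA (AHI ≫ 5) and clearly-non-OSA (AHI ≈ 0) truth. The
generator is deterministic given its seed, and the package tests
assert the planted labels are recoverable by a plain
heart-rate-variability statistic (AUC > 0.9) — the generator must
make the learning problem solvable, otherwise a green training test
would be meaningless.

What the generator does *not* emulate: realistic P/T-wave morphology,
artifacts and electrode noise, hypopnea-versus-apnea distinctions
(the reference database itself merges them), inter-patient
variability of HR dynamics, and the weaker, noisier coupling between
obstruction and heart rate in real patients. A model that learns the
synthetic cohort has therefore demonstrated that the pipeline wiring,
gradients, and capacity are sound — not that it reaches clinical
accuracy; real-data performance must be established on real
recordings (see the reproduction section of the README).

## Desk-scale study conditions

The package's own test suite trains end to end on the default
synthetic cohort under conditions chosen to exercise the full
pipeline on one CPU in minutes:

* training set = 6 records (360 minutes), held-out set = 2 whole
  records (one OSA-like, one non-OSA-like; minutes of one recording
  never straddle the split);
* a reduced network of 6 feature-extraction layers — at 100 Hz the
  6-block receptive field (~20 s) spans a substantial part of the
  50 s modulation cycle, which the planted signature requires —
  with 24 filters and the standard 4 classification layers;
* batch 10, up to 14 epochs with best-validation checkpointing.

The depth/width reduction and epoch budget are runtime scaling
choices for the desk-scale cohort; the accuracy bar they are held to
(held-out per-minute accuracy ≥ 90%) is fixed independently of them.

## Known limitations

* The CSV/WFDB reader covers the single-signal format-16 subset plus
  a text rendering of per-minute annotations; the binary MIT
  annotation format is not parsed.
* Training is CPU-bound R + BLAS; the reference-scale experiment
  (10 layers, 35 recordings, 50 epochs, 10 repeats) is expressible
  but intended for a machine budget well beyond a test suite.
* Metrics follow the two-class minute-level contract; multi-class
  severity grading (mild/moderate/severe) is documented but not a
  classifier output.
* The AHI estimator equates "apneic minutes per hour" with "events
  per hour"; that is the screening convention adopted here, and its
  agreement with event-counted AHI is exactly what the two reported
  correlations quantify.
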