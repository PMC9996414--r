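---
title: "Noise-robust acoustic detection of sleep apnea events: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-robust acoustic detection of sleep apnea events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the models,
the assumptions behind them, the tunable parameters and their defaults,
the synthetic data the pipeline is validated on, and the numerical and
design choices that were genuinely open.

## 1. The detection problem

Obstructive respiratory events have distinctive acoustic signatures in a
bedside recording. An **apnea** is a cessation of breathing: the
breathing sound disappears for 10–60 s and, when the airway reopens,
a loud recovery breath (gasp) follows. A **hypopnea** is a partial
obstruction: breathing continues but attenuated and irregular. The task
is epoch-by-epoch classification — one label from
{no-event, apnea, hypopnea} per 30-second epoch — followed by
aggregation of the epoch detections into an overnight apnea–hypopnea
index (AHI).

### Epoch labeling rules

Epochs are half-open intervals $[30k, 30(k+1))$ s; a trailing partial
segment is dropped. Central and mixed apneas are excluded before
labeling — only obstructive apneas and hypopneas define the event
classes. An epoch with no overlapping event is `no_event`; otherwise its
label is the event type with the larger score in that epoch. Choices the
labeling rules leave open, and how the package resolves them:

* **"Longer" means longer within-epoch overlap**, summed over events of
  the same type, not longer total event duration. Labeling is
  per-segment, so the decision should be local to the segment; the
  alternative reading (compare whole-event durations) is available via
  `label_epochs(..., overlap = "total_duration")`.
* **Exact ties go to apnea**, the more severe class.
* Epochs overlapping wake are not treated specially (no wake/sleep
  information exists in the interface).

## 2. Features

Each epoch is converted to a log-mel spectrogram: Hann-windowed STFT,
power spectrum, triangular mel filter bank (HTK mel scale, peak
amplitude 1), then $\log(\cdot + \varepsilon)$. Defaults in
`mel_config()`: 16 kHz audio, 64 mel bands over the full band, 50 ms
windows, 25 ms hop, $\varepsilon = 10^{-10}$ (an all-zero epoch maps to
the finite constant $\log\varepsilon$). All parameters are
configuration; the synthetic experiments below run at 4 kHz with 24
bands and a 0.25 s hop — breath bursts, gasps and silences live at the
second scale, so a coarse hop loses nothing for this task while keeping
whole-cohort feature extraction fast.

## 3. The detector

The detector maps 14 consecutive epoch spectrograms to class
probabilities for the middle 10 epochs; the outer 2 epochs per side are
past/future context only. The interface follows the idea that apneic
events (10–60 s) need only one or two epochs of context, and the
"input 14, output 10" geometry generalizes a longer-window design used
for sleep staging. Prediction for epoch $t$ therefore requires only
epochs up to $t + 2$ (one-minute lookahead), which is what makes
epoch-by-epoch use in (near) real time possible; the package documents
but does not enforce this.

Architecture (all sizes are per-preset; the contract is fixed, the
realization configurable):

1. **Input normalization.** The time axis is average-pooled to
   `pool_t` chunks. Two channels are formed per mel band:
   the *absolute* channel $(x - \mu_b)/\sigma_b$ with per-band
   statistics $\mu_b, \sigma_b$ fitted on the training nights
   (`fit_input_normalization()`), and a *contrast* channel that
   subtracts the per-band **median over the 14-epoch window**. With
   breathing active less than half the time, the windowed median
   estimates the background level, so the contrast channel reads
   "bursts above background" — a cue that survives additive noise far
   better than absolute levels, while the absolute channel retains the
   amplitude information that hypopnea detection needs. During
   single-epoch pretraining the median is per-epoch.
2. **Per-epoch extractor.** A 1-D convolution over the pooled time axis
   (kernel `conv_kernel`, `conv_channels` filters, leaky-ReLU with
   negative slope 0.01), followed by mean *and* max pooling over time
   positions plus a direct per-band mean-level pathway, then a dense
   layer to `feat_dim` features. Max pooling keeps transients (the
   gasp); the level pathway keeps amplitude (hypopnea); leaky
   rectifiers avoid the dead-unit failure mode that large low-SNR
   gradients can cause.
3. **Multiepoch detector.** The 14 feature vectors form a
   `feat_dim × 14` matrix; a valid temporal convolution with kernel
   width $14 - 10 + 1 = 5$ and `seq_hidden` channels yields exactly 10
   output positions, each seeing its epoch ±2 neighbours; a linear
   layer and a softmax give the per-epoch class distribution. The
   argmax is the predicted class and the maximum probability the
   prediction's *confidence*.

Whole nights are tiled by windows advancing 10 epochs per step; the
final window is shifted back to end at the last epoch and overwrites the
overlap (a deterministic "later window wins" rule), and the terminal
epochs are edge-replicated to fill context, so every epoch receives
exactly one prediction. Nights shorter than 10 epochs get a single
padded window.

Everything — forward pass, backward pass, SGD — is plain base-R matrix
algebra. The analytic gradients are verified against central finite
differences in the test suite (relative tolerance $10^{-3}$ on sampled
coordinates).

## 4. Training

Training follows a two-step schedule with a consistency term for noise
robustness.

**Step 1: 1-to-1 pretraining.** The extractor plus a single-epoch
softmax head is trained on individual epochs with class-weighted
cross-entropy, SGD (momentum 0.9), initial learning rate 0.01, divided
by 10 whenever validation macro F1 has not increased for 3 consecutive
epochs.

**Step 2: 14-to-10 training.** The pretrained extractor is combined with
the multiepoch detector and fine-tuned with the slanted-triangular
learning rate (linear warmup over the first 10% of iterations to
`max_lr`, then linear decay to `max_lr`/32) and gradual unfreezing (the
cross-epoch stage trains from the start, the dense feature layer joins
at epoch 2, the convolution at epoch 3). Both steps run for exactly 10
training epochs and keep the checkpoint with the highest validation
macro F1.

**Class weights** are 1.0 / 1.3 / 2.1 for no-event / apnea / hypopnea:
no-event dominates real nights, so errors on the rare classes are
penalized more.

**Consistency loss.** Each iteration draws, per window, one SNR
uniformly from $[-20, 5]$ dB and a noise cover — clips sampled with
replacement from the training split of the library and concatenated
until they span the 7-minute window, then truncated. The cover is scaled
so that the realized SNR (mean-squared-amplitude definition, one global
gain per window) equals the draw exactly, and added to the clean
waveform. The loss is

$$L = \mathrm{CE}_w(p_\text{clean}, y) \;+\; \lambda\,
      \frac{1}{30}\sum_{e,c} (p_\text{clean} - p_\text{corrupted})^2,$$

with $\lambda = 1$ (plain summation of the two terms). The
cross-entropy uses only the clean branch. Pitch-shift augmentation
(uniform on $\pm 2$ semitones, probability 0.5 per window) is applied to
the clean input before corruption. Setting $\lambda = 0$, or passing no
noise library, reproduces the **control model** — identical
architecture, clean training only — bit for bit.

Open choices and how they were resolved:

* **Stop-gradient on the clean branch.** The consistency term could
  backpropagate through both branches. At this package's scale the
  both-branch gradient reliably finds the collapsed solution — both
  branches drift to a constant output, which zeroes the MSE — so by
  default the clean prediction is treated as a fixed target and only
  the corrupted branch receives the consistency gradient
  (`consistency_stop_gradient = TRUE`), the standard guard in
  consistency-regularization methods. The both-branch variant remains
  available.
* **Checkpoint selection for the consistency model** pools the clean
  validation nights with noise-added copies of them (fixed covers at
  0 dB, the centre of the training SNR range) into one macro F1, so
  the kept checkpoint balances clean accuracy against robustness; the
  control model validates on clean nights only. A single corrupted
  validation night alone proved too noisy a signal to select on.
* **Gradient clipping** (global L2 norm, default 1 in the experiments)
  tames the very large gradients that windows corrupted near −20 dB
  produce; without it those updates destroy the shared features.
* **Batching**: windows are tiled with a configurable training stride
  (overlapping windows give more corrupted views per night); batch
  sizes and the validation split (10–25% of nights, at least one) are
  free parameters and logged in the returned history.
* **Corruption domain during training.** The public [corrupt()] mixes
  waveforms, and all test-time corruption (sweeps, SNR checks) stays in
  the waveform domain. Inside the training loop, however, corrupted
  features are formed by mixing precomputed *linear power-mels*:
  $\log(P_\text{clean} + g^2 P_\text{noise})$ per band and frame. For
  independent additive signals this equals the waveform mixture's
  log-mel up to a zero-mean phase cross-term, and it turns each
  corrupted view into an elementwise operation instead of an STFT —
  roughly a twenty-fold saving that pays for denser window tiling.
  Pitch-shifted copies of each training night (two variants per run,
  magnitudes uniform on ±2 semitones) are likewise precomputed once.
* **Peak learning rate.** Clean (control) training converges well at a
  slanted-triangular peak of 0.05. Consistency fine-tuning uses 0.02:
  at higher rates the supervised term memorizes the small clean cohort
  (training cross-entropy falls to ~0.01) and the consistency term —
  whose gradients are intrinsically weaker, passing through near-
  saturated softmaxes — then never decreases, so no robustness
  develops. The history's `ce_loss`/`consistency_loss` columns make
  this balance visible.
* **Restarts.** `osa_train_restarts()` runs a few seeded restarts and
  keeps the model with the best validation macro F1, the usual guard
  against an unlucky initialization of a small network.

## 5. AHI estimation and evaluation

A single event can straddle two or three epochs, and two short events
can share one; the apneic-epoch count is therefore a biased event count.
The package estimates AHI by a linear calibration fitted with RANSAC:
1000 random 2-point fits, inliers under a residual threshold defaulting
to the MAD of a preliminary least-squares fit, and an ordinary
least-squares refit on the best consensus set. Estimates are floored at
0 events/hour; severity uses upward-inclusive cutoffs (AHI = 15 is
moderate). The rate denominator is total recording time (no sleep
staging exists in this pipeline).

Evaluation implements accuracy, Cohen's κ, macro F1 (the primary
metric, insensitive to class imbalance), one-vs-rest per-class
sensitivity and specificity, the 2-class merge of apnea and hypopnea,
screening sensitivity/specificity at AHI cutoffs with AUC computed from
the continuous estimated AHI by the rank (Mann–Whitney) statistic with
midranks for ties, and Bland–Altman agreement (mean difference ±1.96 SD
limits, MAE, Pearson correlation — flagged undefined rather than
silently zero when a vector has no variance). The test suite
cross-checks κ against `e1071::classAgreement` and AUC against
`pROC::auc` on random inputs at $10^{-9}$.

## 6. Synthetic nights and synthetic home noise

No recorded corpus ships with the package, so a seeded generator
produces the study material.

**Breathing** is band-passed Gaussian noise (default 300–1800 Hz at a
4 kHz rate — the band sits below Nyquist; at higher rates it can be
widened) under raised-cosine bursts of 1 s at 14 breaths/minute with
10% timing jitter and 15% amplitude jitter, base amplitude 0.1. A
permanent broadband floor of amplitude $3\times10^{-3}$ puts silence
roughly 25 dB below the breath bursts, the order of magnitude of a
smartphone recording in a quiet bedroom; an implausibly quiet floor
would make "absolute silence" a magic cue that no real recording
offers. **Apnea** events silence the breathing for the event duration
(uniform 10–60 s) and append a 1.4 s recovery gasp at 3× the base
amplitude with a wider band; **hypopnea** events attenuate breaths to
0.35 of their amplitude with extra irregularity. Events are placed
non-overlapping with ≥10 s gaps by distributing the free slack
uniformly between them, and the reference AHI is exactly the event
count over the duration. Cohorts draw per-subject AHIs across the four
severity strata (default proportions 18/32/32/18% for <5, 5–15, 15–30,
≥30 events/hour) with the integer event count clamped so the realized
AHI stays inside its stratum.

**Noise** comes in nine categories standing in for the usual home-noise
groups. Each category has a distinct spectral support and temporal
character — stationary (fan/air-conditioner 40–400 Hz, room noise
30–600, appliance 100–700, rain/wind 200–1200, each with a mild slow
amplitude modulation) or event-driven (speech-like grouped syllable
bursts 200–1000, media 300–1400, clock ticks 1200–1900, animal calls
1400–1900, vehicle passes 50–300) — mostly narrow and mutually distinct,
the way domestic sources concentrate energy, so cross-category
experiments probe genuinely different spectra. Event-driven clips keep
their between-transient floor about 20 dB below the transients, again
matching recordings rather than digital silence. Train and test splits
are generated from disjoint seeds and share no clip.

**What the synthetic world does not contain:** snoring and airway
vibration, inter-subject amplitude and spectral variation, room
acoustics and reverberation, microphone nonlinearities, wake/sleep
structure, and real annotation noise. Passing the synthetic experiments
therefore shows that the pipeline's machinery is correct and that the
training method confers robustness *under the generator's assumptions*;
it does not certify clinical performance.

## 7. The synthetic experiments and their scale

The packaged experiments are sized for a single CPU:

* **Clean learnability**: 32 nights of 1 h (26 training / 6 held out),
  24 mel bands, 0.25 s hop, the tiny preset, three seeded restarts with
  selection by validation macro F1. Boundary epochs — where an event
  covers only a few seconds of the epoch — are intrinsically ambiguous
  from audio alone (the onset of a silence is only observable to within
  about one breath period), which bounds achievable epoch-level
  accuracy below 1 even on clean data.
* **Robustness**: 13 nights of 0.5 h (9 training incl. validation /
  4 test, the test nights spread over the severity strata with
  `split_cohort()` as evaluation sets for OSA studies usually are). The
  consistency model and the control share data, seeds and geometry; in
  the packaged end-to-end run the consistency model is additionally the
  best of three seeded restarts by noise-corrupted validation macro F1,
  since whether a small network discovers noise-robust features in 10
  training epochs is itself a matter of initialization. The SNR sweep
  corrupts each test night with fixed covers rescaled per SNR
  (`covers_per_night` of them, pooled), so the comparison is paired
  across the grid (clean, 5, 0, −5, …, −30 dB — extending below the
  −20 dB training floor to probe extrapolated robustness) and is not
  drowned by cover resampling noise.
* **Noise-group matrix and noise-fraction curve**: the same machinery
  at even smaller scale; the matrix trains one model per group plus an
  all-group model on a shared pretrained extractor, and the fraction
  curve uses nested clip subsets from a fixed permutation so the
  fractions are comparable.

At these scales the absolute macro F1 under heavy noise is far below
what a full-scale system reaches on real data; the experiments are read
qualitatively — degradation is monotone with falling SNR, and the
consistency-trained model retains more than the control — not as
clinical performance estimates.

## 8. Known limitations

* The detector is a compact network sized for synthetic separability,
  not a production model; the `full_scale` preset mirrors only the
  14→10 interface of a production-size system.
* AHI calibration normalizes by recording time, not sleep time;
  estimates on real recordings with long wake periods would be biased
  low.
* Event-level counting (merging consecutive apneic epochs into discrete
  events) is out of scope; the epoch-rate regression absorbs the
  epoch/event mismatch linearly.
* The WAV layer reads PCM 16/24/32-bit and float32 mono/stereo files;
  exotic RIFF variants are not supported.
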