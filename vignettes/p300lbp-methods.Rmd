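---
title: "Methods: single-trial P300 detection from symbolized EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-trial P300 detection from symbolized EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300lbp)
```

## The detection problem and the model

An odd-ball BCI presents a stream of flashes of which a known fraction is
attended (1 of 4 stimuli in the four-choice paradigm; 2 of 12 row/column
codes in the 6×6 speller). Attended flashes evoke the P300, a positive
event-related deflection peaking roughly 300–500 ms post-stimulus over
central–parietal sites. The package classifies *single* flashes — no trial
averaging — so that a selection can be made from one or two repetitions,
which is what determines the interface's information transfer rate.

The processing chain is:

1. **Epoching.** Each flash yields the window `[0.1 s, 0.8 s]` post-onset
   (half-open, 0-based): 168 samples at the canonical 240 Sa/s. 250 Sa/s
   input is first reduced by Fourier resampling (factor 24/25).
2. **Local baseline correction.** The mean of the first 12 samples
   (`[0.1 s, 0.15 s]`) is subtracted per channel, anchoring each trial at a
   local zero.
3. **Winsorizing.** Amplitudes are clipped to the per-channel 1st/99th
   percentiles computed *on the training set only* (linear interpolation
   between order statistics, the default percentile definition in R). This
   bounds the influence of blink/movement artifacts.
4. **1D-LBP symbolization.** For onset positions stepping by 3 samples,
   the symbol is the count of the following `n = 8` samples strictly
   exceeding the onset amplitude — 54 integers in {0,…,8} per channel for
   a 168-sample trial (`L_s = floor((T − n − 1)/step) + 1`). Ties count as
   0. Because only order comparisons enter, the symbols are invariant
   under any strictly increasing monotone transform of the trial, which
   removes gain and offset nuisance before the network sees the data.
5. **Autoencoded CNN.** A single dense autoencoder (16 ReLU → 8 ReLU → 16
   ReLU → linear output of the input length) is trained on pooled
   single-channel symbol vectors (MSE loss, RMSprop, minibatch 32) and
   then frozen; its weights are shared by all six channel branches. The
   six reconstructions are concatenated, batch-normalized, convolved by a
   non-overlapping 1D convolution (16 filters, kernel 8, stride 8, ReLU —
   about 100 ms of symbols per step), flattened, batch-normalized, and
   classified by two 64-unit ReLU layers with dropout 0.4 and a single
   sigmoid unit. The head is trained with binary cross-entropy and Adam
   (learning rate 1e-4, β₁ = 0.9, β₂ = 0.999, ε = 1e-8, no decay),
   minibatch 64, on a stratified 70/30 train/validation split. The binary
   label is `probability > 0.5`, strictly, so an exact 0.5 maps to 0.

Class imbalance (1:3 or 1:5 target:non-target by construction) is handled
before training by NearMiss-2 undersampling of the majority to 2:1
followed by seeded random duplication of the minority to exact parity.
Both ratios are exposed in `resample_config()`; no synthetic feature
vectors are ever fabricated.

## Architecture profiles: "shapes" vs "counts"

The published description of this architecture carries an internal
inconsistency: every printed tensor shape implies 54 symbols per channel
(the LBP output for a 168-sample trial), while every printed per-layer
parameter count implies 56 (e.g. the first encoder layer's 912 = 56·16 +
16, and the 448-parameter batch norm implies a 112-long flatten, i.e. 7
convolution steps). No single input length satisfies both. The package
therefore exposes two profiles:

* `network_config("shapes")` — 54 symbols/channel, trial window
  `[0.1, 0.8]` s; reproduces the tensor shapes (54,6) → (6,16) → (96,).
  This is the default used for actual detection.
* `network_config("counts")` — 56 symbols/channel, trial window extended
  to `[0.1, 0.825]` s (174 samples) so the symbolizer emits 56 symbols;
  reproduces the parameter accounting: autoencoder 912 + 136 + 144 + 952 =
  2144, sequential layers 24 + 784 + 448 + 7232 + 4160 + 65, total 14,857
  with 12,477 trainable and 2,380 frozen (the shared autoencoder once,
  plus the 12 + 224 batch-norm moving statistics).

Two further reconciliations, recorded here because the ledger asserts
them exactly:

* The convolution kernel is 8 with 16 filters: 784 parameters = 8·6·16 +
  16 and output shape (6,16) at stride 8 force this reading.
* The input-side batch normalization that precedes the channel slicing is
  absent from the printed tables and totals; it is implemented as a fixed
  per-channel standardization fitted on training symbols and is not
  counted as layer parameters, which is the only accounting under which
  the printed totals reconcile.
* The printed convolution MACC (5504) exceeds the natural convention
  `steps × filters × (kernel·channels + 1) = 5488` by exactly one
  accumulate per filter; `count_macc()` reports both columns (`macc`,
  `macc_toolchain`), and with the toolchain convention every printed MACC
  row and total reproduces (autoencoder 2184, sequential 17,995, overall
  20,179).

## Training schedule

Epoch counts and stopping rules are not part of the published recipe and
are exposed in `train_config()` with defaults of 100 autoencoder epochs
and up to 200 classifier epochs. Training stops early when the validation
loss has not improved for `patience = 20` epochs. The *restored* weights
are those of the best validation-F1 epoch rather than best validation
loss: F1 is the design metric of this detector (robust to the odd-ball
imbalance, and the quantity the decision stage depends on), and with
cross-entropy the validation loss begins to overfit while validation F1 is
still improving, so best-loss restoration systematically undershoots the
detector's operating quality.

Two implementation details matter for honest validation:

* Random oversampling appends exact duplicates. The 70/30 split groups
  identical feature rows so duplicates never straddle the split —
  otherwise holdout accuracy is inflated by memorization, and a detector
  trained on pure noise scores well above chance. The test suite checks
  the honest behaviour: at zero SNR the holdout accuracy must stay inside
  0.45–0.55.
* The frozen autoencoder is verified by digest to be bit-identical before
  and after classifier training.

## The synthetic session generator

`generate_session()` emulates the study conditions end to end: flashes at
a 175 ms inter-stimulus interval (the four-flash block then spans 0.7 s
and the twelve-flash block 2.1 s, matching the paradigm timing models
`T = 0.5 + 0.7·n_rep` and `T = 2.5 + 2.1·n_rep`; a 200 ms variant is
configurable), random flash order within each repetition block, exact
1:3 / 1:5 target ratios, and a known attended stimulus per selection.

* **ERP template:** a half-sine of width 0.3 s centred 0.35 s post-onset —
  a smooth positive deflection inside the physiological 250–450 ms window,
  chosen so the peak amplitude is a differentiable function of SNR. Its
  peak equals `snr × noise_sigma` on full-weight channels; the default
  spatial weighting (0.3 everywhere, 1.0 on the last three channels)
  emulates parietal dominance.
* **Noise:** an AR(2) process with poles 0.9 and 0.8, band-limited to
  0.1–20 Hz and rescaled to `noise_sigma` (default 10 µV). The pole
  placement gives a ~1/f power decay across the analysis band (power
  ratio ≈ 33 between 0.5 and 15 Hz), the canonical EEG background
  spectrum. Noise color matters here: the autoencoder bottleneck can only
  retain a low-dimensional summary, and 1/f-style noise concentrates its
  variance in few smooth components, as real EEG does.
* **Artifacts:** with probability `artifact_rate` per trial, an
  8-noise-SD half-sine excursion of 0.15 s lands on one random channel —
  enough to exercise the winsorizing stage.

What the generator does **not** emulate: volume-conduction correlation
between channels, eye-blink morphology, alpha rhythms, latency jitter of
the P300, and non-stationarity across a session. Passing tests on this
generator therefore demonstrate that the pipeline recovers a planted,
time-locked, spatially weighted deflection under realistic spectral noise
— not that it attains any particular accuracy on human EEG.

## Numerical choices

* **Filtering.** The optional 0.1–20 Hz band-pass is an 8th-order
  zero-phase Butterworth applied in the frequency domain (squared
  magnitude response on a mirror-padded FFT). A transfer-function
  implementation of this filter is numerically unstable at a normalized
  cutoff of 8×10⁻⁴; the spectral implementation is exactly the zero-phase
  response and unconditionally stable.
* **Resampling** 250→240 Sa/s is Fourier-domain (band-limited
  interpolation); constants and in-band tones are preserved to machine
  precision.
* **Percentiles** use linear interpolation between order statistics
  (R's default type 7).
* **Batch normalization** uses ε = 1e-3 and moving-average momentum 0.99;
  inference uses the moving statistics, training the batch statistics.
* **Tie-breaks.** LBP comparisons are strict (ties → 0); the decision
  stage breaks occurrence ties by summed probability then lowest code;
  channel elimination breaks criterion ties toward the lower channel
  index; NearMiss-2 breaks distance ties by original index order.
* **Degenerate metrics** (0/0 cells) return 0 with a warning rather than
  an error, so batch evaluations of weak detectors do not abort.

## Channel selection

Recursive backward elimination starts from the full montage and, per
round, removes the channel whose elimination maximizes
`TP/(TP + FP + FN)` computed by a pluggable provisional classifier on a
seeded 70/30 holdout. The default factory is the package's own
convolutional head without the autoencoder branch; a fast logistic
regression on per-channel sub-window means (`glm_channel_factory()`) is
provided for large experiments. Because planted informative channels are
mutually redundant, a single-split criterion estimate can be too noisy to
resolve one channel's marginal contribution; `recursive_elimination()`
therefore accepts `n_splits` and averages the criterion over several
paired splits (all candidates of a round share the same split seeds). The
default remains a single split; the planted-recovery experiment in the
test suite uses five, and requires all six planted channels to survive in
at least 9 of 10 seeded runs at SNR 1 with 1200 trials. Cross-subject consensus ranks
channels by how many subjects retain them, then by mean removal round
(survivors outrank all removals), then by index.

## Problem sizes used by the test suite

The end-to-end experiments were sized to be statistically meaningful at
desk scale: the detector-recovery experiment uses 2000 balanced trials
(500 four-choice selections' worth of events rebalanced to parity) per
SNR condition; the speller-decision experiment uses 40 characters at 15
repetitions with a rate-calibrated simulated detector (measured
single-trial F1 ≥ 0.7 asserted before aggregation); the planted-channel
experiment uses 16 channels (6 informative) with 1200 trials per seed and
10 seeds. The symbolizer, ledger, metric and ITR checks are closed-form
and run in milliseconds.

## Known limitations

* The network engine is plain R; it is adequate for the architecture's
  ~15k parameters but not intended for larger models.
* The generator's channels carry independent noise; spatially correlated
  noise would make channel selection harder than it is here.
* `itr()` follows Wolpaw's formula, which is slightly below zero-bias
  only at `P = 1/N`; values of `P` below chance return positive ITR, as
  the formula dictates — interpret with care.
* The provisional-CNN channel-selection factory retrains a network per
  candidate per round and is expensive for large montages; the GLM
  factory is the practical default there.
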