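# p300lbp

Single-trial detection of the P300 event-related potential from symbolized
EEG, with an autoencoded 1D convolutional neural network — an R toolkit for
odd-ball brain–computer interfaces (BCIs).

## The problem

P300-based BCIs flash stimuli at the user (four direction targets, or the
rows and columns of a 6×6 character speller) and detect which one was
attended from the positive EEG deflection ("P300") that rare, attended
stimuli evoke ~300–500 ms after onset. The classical remedy for the very
low single-trial signal-to-noise ratio is averaging many repetitions, which
destroys the interface's speed (information transfer rate, ITR). This
package implements a detector designed to classify *single* trials well
enough that only one or two repetitions are needed:

1. **Preprocessing** — trial epoching in `[0.1 s, 0.8 s]` post-stimulus
   (168 samples at 240 Sa/s), local baseline correction over the first
   12 samples, winsorizing at per-channel 1st/99th training percentiles,
   and a one-dimensional local-binary-pattern (LBP) symbolization:
   for onsets `P_j` stepping by 3 samples,

       sEEG(k) = Σ_{i = P_j + 1}^{P_j + n} [ EEG(i) − EEG(P_j) > 0 ],  n = 8

   giving 54 integer symbols in {0,…,8} per channel that depend only on
   amplitude *order* (so they are invariant to drifts, offsets and gain).
2. **Model** — a per-channel shared dense autoencoder (16–8–16–linear),
   trained with MSE/RMSprop and frozen; the six reconstructed channel
   streams are concatenated, batch-normalized, passed through a
   non-overlapping 1D convolution (16 filters, kernel 8, stride 8, ReLU),
   flattened, batch-normalized and classified by a 64–64–1 dense head with
   0.4 dropout and a sigmoid output, trained with binary cross-entropy and
   Adam (lr 1e-4, batch 64, 30 % validation holdout).
3. **Imbalance handling** — NearMiss-2 undersampling of the non-target
   majority followed by seeded random oversampling of targets to parity.
4. **Decision aggregation** — per selection, the code (or row/column pair)
   with the most positive single-trial labels wins; ties fall back to
   summed probabilities, then the lowest code.
5. **Analytics** — precision/recall/accuracy/F1 from confusion counts, and
   ITR in bits/min via Wolpaw's formula with paradigm timing models
   `T = 0.5 + 0.7·n_rep` (four-choice) and `T = 2.5 + 2.1·n_rep` (speller).

No EEG recordings are required: a synthetic odd-ball session generator
produces ground-truth-labelled sessions (1/f-style band-limited noise,
half-sine ERP template peaking 0.35 s post-stimulus on parietal-like
channels, optional high-amplitude artifacts), so the whole chain is
testable end to end. The neural network engine (dense/conv/batch-norm
layers, backpropagation, Adam and RMSprop) is implemented in base R matrix
operations and verified against finite-difference gradients.

## Worked example

```r
library(p300lbp)

# simulate a four-choice session: 4 stimuli x 2 repetitions x 10 selections
ses <- generate_session(session_spec("four_choice", n_repetitions = 2,
                                     n_selections = 10, snr = 2, seed = 42))
event_counts(ses$schedule, ses$truth)
#>    n_target n_nontarget
#>          20          60

# preprocess into LBP symbols (80 trials x 54 symbols x 6 channels)
pp <- preprocess_pipeline(ses$recording, ses$schedule)
dim(pp$symbols)
#> [1] 80 54  6

# metrics from a published-style confusion table
metrics(confusion_counts(TP = 2017, FP = 3499, TN = 11501, FN = 983))
#> precision 36.57% | recall 67.23% | accuracy 75.10% | F1 47.37%

# speed analytics: one speller repetition at 42% character accuracy
itr(0.42, N = 36, T_sel = selection_time("speller6x6", 1))
#> [1] 15.82809

# architecture audit (counts profile)
attr(count_parameters(network_config("counts")), "totals")
#>       total   trainable      frozen autoencoder
#>       14857       12477        2380        2144
```

The numbers mean: of the 80 simulated flashes, exactly 20 carried the
target ERP (the odd-ball 1:3 ratio); the detector in its
parameter-accounting profile has 14,857 weights of which the 2,144 shared
autoencoder weights plus 236 batch-norm statistics are frozen; and a
speller selecting characters at 42 % accuracy from single flashes conveys
about 15.8 bits/min.

A command-line interface wrapping the same functions ships at
`inst/cli/p300.R` (subcommands `simulate`, `preprocess`, `train`,
`predict`, `select-channels`, `decide`, `evaluate`, `report-complexity`).

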