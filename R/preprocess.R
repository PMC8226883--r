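# Trial extraction and the symbolization preprocessing chain:
# extract -> local baseline correction -> winsorize -> 1D-LBP symbolize.
#
# Conventions: indices are 0-based at the interface with stimulus onsets,
# and windows are half-open [w_start, w_end). At fs = 240 the default
# window [0.1 s, 0.8 s] yields T = 168 samples per trial.

#' Extract one stimulus-locked trial from a recording
#'
#' Returns samples `[onset + round(w_start*fs), onset + round(w_end*fs))`
#' (half-open, onsets 0-based), i.e. 168 samples for the default
#' `[0.1 s, 0.8 s]` window at 240 Sa/s.
#'
#' @param recording An [eeg_recording()].
#' @param onset_sample 0-based stimulus onset sample.
#' @param w_start,w_end Window relative to the stimulus onset, in seconds.
#' @return Channels x T numeric matrix (class `eeg_trial`).
#' @export
extract_trial <- function(recording, onset_sample, w_start = 0.1, w_end = 0.8) {
  if (!inherits(recording, "eeg_recording"))
    validation_error("'recording' must be an eeg_recording")
  check_scalar(onset_sample, "onset_sample", lo = 0, integer = TRUE)
  if (w_end <= w_start) validation_error("'w_end' must exceed 'w_start'")
  i0 <- onset_sample + round(w_start * recording$fs)  # 0-based, inclusive
  i1 <- onset_sample + round(w_end * recording$fs)    # 0-based, exclusive
  if (i1 > n_samples(recording))
    bounds_error(sprintf(
      "trial window for onset %d ends at sample %d beyond recording end %d",
      onset_sample, i1, n_samples(recording)))
  w <- recording$signal[, (i0 + 1L):i1, drop = FALSE]
  structure(w, class = c("eeg_trial", class(w)))
}

#' Extract all trials of a schedule
#'
#' @param recording An [eeg_recording()].
#' @param schedule A `stimulus_schedule` data frame.
#' @inheritParams extract_trial
#' @return 3-D array trials x T x channels (class `trial_set`), with the
#'   schedule attached as attribute `"schedule"`.
#' @export
extract_trials <- function(recording, schedule, w_start = 0.1, w_end = 0.8) {
  n <- nrow(schedule)
  T_len <- round(w_end * recording$fs) - round(w_start * recording$fs)
  out <- array(0, dim = c(n, T_len, n_channels(recording)))
  for (i in seq_len(n)) {
    tr <- extract_trial(recording, schedule$onset_sample[i], w_start, w_end)
    out[i, , ] <- t(unclass(tr))
  }
  structure(out, schedule = schedule, fs = recording$fs, class = "trial_set")
}

#' Local baseline correction
#'
#' Subtracts, per channel, the mean of the first `baseline_len` samples of
#' the trial (default 12 samples = the `[0.1 s, 0.15 s]` segment at 240
#' Sa/s) from the whole trial.
#'
#' @param trial Channels x T matrix, or a `trial_set` array.
#' @param baseline_len Number of leading samples defining the local baseline.
#' @return Corrected object of the same shape.
#' @export
baseline_correct <- function(trial, baseline_len = 12L) {
  check_scalar(baseline_len, "baseline_len", lo = 1, integer = TRUE)
  if (inherits(trial, "trial_set")) {
    if (baseline_len > dim(trial)[2])
      validation_error("'baseline_len' exceeds trial length")
    base <- apply(trial[, seq_len(baseline_len), , drop = FALSE],
                  c(1, 3), mean)
    out <- trial
    for (ch in seq_len(dim(trial)[3]))
      out[, , ch] <- trial[, , ch] - base[, ch]
    return(out)
  }
  if (baseline_len > ncol(trial))
    validation_error("'baseline_len' exceeds trial length")
  base <- rowMeans(trial[, seq_len(baseline_len), drop = FALSE])
  trial - base
}

#' Fit winsorizing thresholds on training trials
#'
#' Computes, per channel, the 1st and 99th percentile of all training-set
#' amplitudes (linear interpolation between order statistics). Thresholds
#' must be fitted on training data only and reused on test data.
#'
#' @param trials A `trial_set` array (trials x T x channels) or a channels x
#'   T matrix.
#' @param probs Lower/upper percentile probabilities (default 0.01, 0.99).
#' @return Object of class `winsor_thresholds`: matrix channels x 2
#'   (`p_low`, `p_high`).
#' @export
fit_winsor <- function(trials, probs = c(0.01, 0.99)) {
  if (is.matrix(trials)) {
    tmp <- array(0, dim = c(1, ncol(trials), nrow(trials)))
    tmp[1, , ] <- t(trials)
    trials <- tmp
  }
  if (length(dim(trials)) != 3)
    validation_error("'trials' must be a trials x T x channels array")
  n_per_ch <- dim(trials)[1] * dim(trials)[2]
  if (n_per_ch == 0) validation_error("training set is empty")
  if (n_per_ch < 100)
    warning("fewer than 100 training samples per channel; ",
            "percentile thresholds are degenerate", call. = FALSE)
  C <- dim(trials)[3]
  th <- matrix(0, nrow = C, ncol = 2,
               dimnames = list(NULL, c("p_low", "p_high")))
  for (ch in seq_len(C))
    th[ch, ] <- stats::quantile(as.numeric(trials[, , ch]), probs,
                                names = FALSE, type = 7)
  structure(th, class = "winsor_thresholds")
}

#' Clip trial amplitudes to fitted winsorizing thresholds
#'
#' Amplitudes below the per-channel lower threshold are replaced by it, and
#' amplitudes above the upper threshold likewise; in-range samples are
#' untouched, so the operation is idempotent.
#'
#' @param trial Channels x T matrix or `trial_set` array.
#' @param thresholds A [fit_winsor()] result.
#' @return Clipped object of the same shape.
#' @export
apply_winsor <- function(trial, thresholds) {
  if (!inherits(thresholds, "winsor_thresholds"))
    validation_error("'thresholds' must come from fit_winsor()")
  if (inherits(trial, "trial_set") || length(dim(trial)) == 3) {
    if (dim(trial)[3] != nrow(thresholds))
      alignment_error(sprintf(
        "trial set has %d channels but thresholds %d",
        dim(trial)[3], nrow(thresholds)))
    out <- trial
    for (ch in seq_len(dim(trial)[3]))
      out[, , ch] <- pmin(pmax(trial[, , ch], thresholds[ch, 1]),
                          thresholds[ch, 2])
    return(out)
  }
  if (nrow(trial) != nrow(thresholds))
    alignment_error(sprintf("trial has %d channels but thresholds %d",
                            nrow(trial), nrow(thresholds)))
  out <- trial
  for (ch in seq_len(nrow(trial)))
    out[ch, ] <- pmin(pmax(trial[ch, ], thresholds[ch, 1]),
                      thresholds[ch, 2])
  out
}

#' Number of LBP symbols emitted for a trial of length T
#'
#' `L_s = floor((T - n - 1) / step) + 1`; T = 168 with the defaults gives 54.
#'
#' @param T_len Trial length in samples.
#' @param n Comparison-window length (default 8).
#' @param step Onset step (default 3).
#' @export
lbp_length <- function(T_len, n = 8L, step = 3L) {
  as.integer(floor((T_len - n - 1) / step) + 1L)
}

#' One-dimensional local binary pattern symbolization
#'
#' For each onset index `j` in `{0, step, 2*step, ...}` with `j + n <= T - 1`
#' the symbol is the count of the `n` samples following position `j` that
#' strictly exceed the amplitude at `j` (ties count as 0). Symbols therefore
#' lie in `{0, ..., n}` and depend only on amplitude order, making them
#' invariant under any strictly increasing monotone transform of the trial.
#'
#' @param trial Channels x T matrix, or a `trial_set` array.
#' @param n Comparison-window length in samples (default 8).
#' @param step Onset step in samples (default 3).
#' @return For a single trial, an `L_s` x channels integer matrix (class
#'   `symbolized_trial`); for a `trial_set`, a trials x L_s x channels
#'   integer array (class `symbolized_trial_set`).
#' @export
symbolize_lbp <- function(trial, n = 8L, step = 3L) {
  check_scalar(n, "n", lo = 1, integer = TRUE)
  check_scalar(step, "step", lo = 1, integer = TRUE)
  if (inherits(trial, "trial_set") || length(dim(trial)) == 3) {
    T_len <- dim(trial)[2]
    if (T_len < n + 1)
      validation_error(sprintf("trial length %d < n + 1 = %d", T_len, n + 1))
    L_s <- lbp_length(T_len, n, step)
    onsets <- (seq_len(L_s) - 1L) * step  # 0-based
    nt <- dim(trial)[1]; C <- dim(trial)[3]
    out <- array(0L, dim = c(nt, L_s, C))
    for (ch in seq_len(C)) {
      x <- trial[, , ch, drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, nrow = nt)
      ref <- x[, onsets + 1L, drop = FALSE]
      acc <- matrix(0L, nrow = nt, ncol = L_s)
      for (i in seq_len(n))
        acc <- acc + (x[, onsets + 1L + i, drop = FALSE] > ref)
      out[, , ch] <- acc
    }
    sched <- attr(trial, "schedule")
    return(structure(out, schedule = sched, n = n, step = step,
                     class = "symbolized_trial_set"))
  }
  T_len <- ncol(trial)
  if (T_len < n + 1)
    validation_error(sprintf("trial length %d < n + 1 = %d", T_len, n + 1))
  L_s <- lbp_length(T_len, n, step)
  onsets <- (seq_len(L_s) - 1L) * step
  C <- nrow(trial)
  out <- matrix(0L, nrow = L_s, ncol = C)
  for (ch in seq_len(C)) {
    x <- trial[ch, ]
    ref <- x[onsets + 1L]
    acc <- integer(L_s)
    for (i in seq_len(n))
      acc <- acc + (x[onsets + 1L + i] > ref)
    out[, ch] <- acc
  }
  structure(out, n = n, step = step, class = "symbolized_trial")
}

#' Full preprocessing pipeline: recording + schedule to symbolized trials
#'
#' Stage order: trial extraction, local baseline correction, winsorizing,
#' LBP symbolization. For training data omit `thresholds` and they are
#' fitted on the extracted (baseline-corrected) trials; for test data pass
#' the thresholds fitted on the training set.
#'
#' @param recording An [eeg_recording()].
#' @param schedule A `stimulus_schedule`.
#' @param thresholds Optional [fit_winsor()] result (required for test data).
#' @param w_start,w_end Trial window in seconds post-onset.
#' @param baseline_len Baseline samples (default 12).
#' @param n,step LBP parameters.
#' @return List with `symbols` (trials x L_s x channels,
#'   `symbolized_trial_set`), `thresholds`, and `labels` (the schedule's
#'   target flags).
#' @export
preprocess_pipeline <- function(recording, schedule, thresholds = NULL,
                                w_start = 0.1, w_end = 0.8,
                                baseline_len = 12L, n = 8L, step = 3L) {
  trials <- extract_trials(recording, schedule, w_start, w_end)
  trials <- baseline_correct(trials, baseline_len)
  if (is.null(thresholds)) thresholds <- fit_winsor(trials)
  trials <- apply_winsor(trials, thresholds)
  symbols <- symbolize_lbp(trials, n = n, step = step)
  list(symbols = symbols,
       thresholds = thresholds,
       labels = as.integer(schedule$is_target))
}
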