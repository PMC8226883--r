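# Continuous EEG container and signal-level operations.

#' Continuous multichannel EEG recording
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in samples/s. 240 is the canonical rate; 250 is
#'   accepted and can be reduced with [resample_to_240()].
#' @param channel_labels Optional character vector of channel names.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channel_labels = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal))
    validation_error("'signal' must be a numeric channels x samples matrix")
  if (anyNA(signal))
    validation_error("'signal' must not contain missing samples")
  check_scalar(fs, "fs", lo = 1e-9)
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(nrow(signal)))
  if (length(channel_labels) != nrow(signal))
    validation_error("'channel_labels' must have one entry per channel")
  structure(list(signal = signal, fs = fs,
                 channel_labels = as.character(channel_labels)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Sa/s (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$signal)
n_samples  <- function(rec) ncol(rec$signal)

# Zero-phase Butterworth band-pass applied in the frequency domain.
#
# The applied gain is the squared magnitude of an order-`order` Butterworth
# high-pass at `lo` cascaded with a low-pass at `hi` -- exactly the response
# of forward-backward (zero-phase) time-domain filtering, but free of the
# numerical instability of high-order transfer functions at very low
# normalized cutoffs. The signal is mirror-padded to suppress wrap-around
# edge effects.
fft_bandpass <- function(x, fs, lo, hi, order = 8) {
  n <- length(x)
  pad <- min(n, 4L * ceiling(fs / max(lo, 1e-6)))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  np <- length(xp)
  f <- (seq_len(np) - 1L) / np * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis
  # |H|^2 of the forward pass = |H_hp|^2 * |H_lp|^2; squared again for
  # zero-phase (forward-backward) equivalence.
  g_lp <- 1 / (1 + (f / hi)^(2 * order))
  g_hp <- ifelse(f > 0, 1 / (1 + (lo / f)^(2 * order)), 0)
  y <- Re(stats::fft(stats::fft(xp) * g_lp * g_hp, inverse = TRUE)) / np
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase band-pass filter an EEG recording
#'
#' Band-limits every channel to `[lo, hi]` Hz with a zero-phase Butterworth
#' response (default 8th order, 0.1-20 Hz, the standard P300 analysis band).
#' This stage is optional when the acquisition device already band-limits
#' the signal.
#'
#' @param recording An [eeg_recording()].
#' @param lo,hi Band edges in Hz; `0 < lo < hi < fs/2`.
#' @param order Butterworth order (default 8).
#' @return A filtered `eeg_recording` of the same shape.
#' @export
eeg_bandpass <- function(recording, lo = 0.1, hi = 20, order = 8) {
  if (!inherits(recording, "eeg_recording"))
    validation_error("'recording' must be an eeg_recording")
  check_scalar(lo, "lo", lo = 1e-12)
  check_scalar(hi, "hi")
  check_scalar(order, "order", lo = 1, integer = TRUE)
  if (!(lo < hi && hi < recording$fs / 2))
    validation_error("band edges must satisfy 0 < lo < hi < fs/2")
  out <- recording
  for (ch in seq_len(n_channels(recording)))
    out$signal[ch, ] <- fft_bandpass(recording$signal[ch, ],
                                     recording$fs, lo, hi, order)
  out
}

# Fourier-domain resampling of one vector to n_out samples (band-limited
# interpolation; constants and pure tones are preserved exactly).
fft_resample_vec <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(n_out), imaginary = numeric(n_out))
  nh <- min(n, n_out)
  k <- nh %/% 2L
  Y[seq_len(k + 1L)] <- X[seq_len(k + 1L)]
  if (k > 0) Y[(n_out - k + 1L):n_out] <- X[(n - k + 1L):n]
  if (nh %% 2L == 0L) {
    Y[k + 1L] <- Y[k + 1L] / 2
    if (n_out > n) Y[n_out - k + 1L] <- Y[k + 1L]
  }
  # y_t = (1/n) * sum_k Y_k exp(2*pi*i*k*t/n_out): amplitudes preserved.
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Reduce a 250 Sa/s recording to the canonical 240 Sa/s
#'
#' Band-limited (Fourier) resampling by the rational factor 24/25. A
#' recording already at 240 Sa/s passes through unchanged.
#'
#' @param recording An [eeg_recording()] at 240 or 250 Sa/s.
#' @return An `eeg_recording` at 240 Sa/s with duration preserved to within
#'   one sample.
#' @export
resample_to_240 <- function(recording) {
  if (!inherits(recording, "eeg_recording"))
    validation_error("'recording' must be an eeg_recording")
  if (recording$fs == 240) return(recording)
  if (recording$fs != 250)
    validation_error(sprintf(
      "sampling rate must be 240 or 250 Sa/s (got %g)", recording$fs))
  n <- n_samples(recording)
  n_out <- round(n * 24 / 25)
  sig <- matrix(0, nrow = n_channels(recording), ncol = n_out)
  for (ch in seq_len(n_channels(recording)))
    sig[ch, ] <- fft_resample_vec(recording$signal[ch, ], n_out)
  eeg_recording(sig, 240, recording$channel_labels)
}
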