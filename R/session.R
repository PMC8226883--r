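# Synthetic odd-ball EEG sessions with known ground truth.
#
# The generator emulates the two stimulation protocols used by visual P300
# BCIs: a 4-choice direction paradigm (codes 1..4, one attended per
# selection) and the classic 6x6 row/column speller (row codes 1..6, column
# codes 7..12, one attended row and one attended column per selection).
# Target flashes carry an additive positive ERP-like deflection over
# parietal-dominant channels; the background is band-limited colored noise.

#' Session specification for the synthetic odd-ball EEG generator
#'
#' Bundles and validates every knob of the simulated recording session.
#'
#' @param paradigm `"four_choice"` (4 flashing stimuli, one attended) or
#'   `"speller6x6"` (12 row/column flashes, one attended character).
#' @param n_channels Number of EEG channels (default 6).
#' @param fs Sampling rate in samples/s (default 240; 250 is accepted
#'   downstream via [resample_to_240()]).
#' @param isi Inter-stimulus interval in seconds, flash onset to flash onset
#'   (default 0.175, i.e. a 0.7 s four-flash block or a 2.1 s twelve-flash
#'   block).
#' @param flash_duration Flash persistence on screen in seconds (default 0.1).
#'   Must not exceed `isi`.
#' @param n_repetitions Flashes per stimulus per selection.
#' @param n_selections Number of selections (directions or characters).
#' @param snr Ratio of the ERP template peak amplitude to the background
#'   noise standard deviation; `snr = 0` injects no signal.
#' @param artifact_rate Per-trial probability of a large-amplitude artifact
#'   excursion (>= 5 noise SD), exercising the winsorizing stage.
#' @param spatial_weights Per-channel scaling of the ERP template peak.
#'   Default: 0.3 everywhere, 1.0 on the last three channels (parietal-like
#'   dominance). Channels with weight 1 carry the full `snr` x noise-SD peak.
#' @param noise_sigma Background noise standard deviation in microvolts
#'   (default 10).
#' @param seed Integer seed; a fixed seed makes the session bit-reproducible.
#'
#' @return An object of class `session_spec`.
#' @seealso [generate_session()]
#' @export
session_spec <- function(paradigm = c("four_choice", "speller6x6"),
                         n_channels = 6L,
                         fs = 240,
                         isi = 0.175,
                         flash_duration = 0.100,
                         n_repetitions = 10L,
                         n_selections = 10L,
                         snr = 1,
                         artifact_rate = 0.02,
                         spatial_weights = NULL,
                         noise_sigma = 10,
                         seed = NULL) {
  paradigm <- match.arg(paradigm)
  check_scalar(n_channels, "n_channels", lo = 1, integer = TRUE)
  check_scalar(fs, "fs", lo = 1e-9)
  check_scalar(isi, "isi", lo = 1e-9)
  check_scalar(flash_duration, "flash_duration", lo = 1e-9)
  if (flash_duration > isi)
    validation_error("'flash_duration' must not exceed 'isi'")
  check_scalar(n_repetitions, "n_repetitions", lo = 1, integer = TRUE)
  check_scalar(n_selections, "n_selections", lo = 1, integer = TRUE)
  check_scalar(snr, "snr", lo = 0)
  check_scalar(artifact_rate, "artifact_rate", lo = 0, hi = 1)
  check_scalar(noise_sigma, "noise_sigma", lo = 1e-12)
  if (is.null(spatial_weights)) {
    spatial_weights <- rep(0.3, n_channels)
    strong <- seq(max(1L, n_channels - 2L), n_channels)
    spatial_weights[strong] <- 1
  }
  if (length(spatial_weights) != n_channels)
    validation_error("'spatial_weights' must have one entry per channel")
  if (any(spatial_weights < 0))
    validation_error("'spatial_weights' must be non-negative")
  if (!is.null(seed)) check_scalar(seed, "seed", integer = TRUE)

  structure(list(
    paradigm = paradigm,
    n_channels = as.integer(n_channels),
    fs = fs,
    isi = isi,
    flash_duration = flash_duration,
    n_repetitions = as.integer(n_repetitions),
    n_selections = as.integer(n_selections),
    snr = snr,
    artifact_rate = artifact_rate,
    spatial_weights = spatial_weights,
    noise_sigma = noise_sigma,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "session_spec")
}

#' @export
print.session_spec <- function(x, ...) {
  cat("<session_spec>", x$paradigm, "\n")
  cat(sprintf("  %d channels @ %g Sa/s, ISI %g s, flash %g s\n",
              x$n_channels, x$fs, x$isi, x$flash_duration))
  cat(sprintf("  %d selections x %d repetitions, snr %g, artifact rate %g\n",
              x$n_selections, x$n_repetitions, x$snr, x$artifact_rate))
  invisible(x)
}

paradigm_codes <- function(paradigm) {
  if (paradigm == "four_choice") 1:4 else 1:12
}

# Half-sine ERP template sampled at fs: positive deflection supported on
# [0.2 s, 0.5 s] post-onset, peaking at 0.35 s, unit peak amplitude.
erp_template <- function(fs, peak = 0.35, width = 0.3) {
  len <- ceiling((peak + width / 2) * fs) + 1L
  t <- (seq_len(len) - 1L) / fs
  on <- t >= (peak - width / 2) & t <= (peak + width / 2)
  tpl <- numeric(len)
  tpl[on] <- sin(pi * (t[on] - (peak - width / 2)) / width)
  tpl
}

# Band-limited 1/f-style background noise: AR(2) process (poles 0.9 and
# 0.8, giving ~1/f power decay across 0.1-20 Hz) shaped into the analysis
# band and rescaled to unit standard deviation.
colored_noise <- function(n, fs) {
  w <- stats::rnorm(n + 200L)
  ar <- stats::filter(w, filter = c(1.7, -0.72), method = "recursive")
  ar <- as.numeric(ar)[201:(n + 200L)]
  x <- fft_bandpass(ar, fs, lo = 0.1, hi = 20, order = 8)
  x / stats::sd(x)
}

#' Generate a synthetic odd-ball EEG session
#'
#' Simulates a continuous multichannel recording together with its stimulus
#' schedule and ground truth. Within each repetition block the stimulus
#' order is a fresh random permutation. Every target flash adds a positive
#' half-sine ERP template (peak 0.35 s post-onset, width 0.3 s) scaled by
#' `snr * noise_sigma * spatial_weights`; with probability `artifact_rate` a
#' trial additionally receives an 8-noise-SD excursion on one random channel.
#'
#' @param spec A [session_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{recording}{[eeg_recording()]: channels x samples signal.}
#'     \item{schedule}{Data frame (class `stimulus_schedule`) with columns
#'       `onset_sample` (0-based), `code`, `is_target`, `selection`,
#'       `repetition`.}
#'     \item{truth}{Ground truth: `attended` code per selection (for the
#'       speller, a data frame with `row`, `col`, `char`), plus the
#'       per-event target flags.}
#'   }
#' @examples
#' s <- generate_session(session_spec("four_choice", n_repetitions = 2,
#'                                    n_selections = 3, seed = 1))
#' nrow(s$schedule)  # 4 stimuli x 2 reps x 3 selections = 24 events
#' @export
generate_session <- function(spec) {
  if (!inherits(spec, "session_spec"))
    validation_error("'spec' must be a session_spec object")
  with_seed(spec$seed, generate_session_impl(spec))
}

generate_session_impl <- function(spec) {
  codes <- paradigm_codes(spec$paradigm)
  n_codes <- length(codes)
  isi_samp <- round(spec$isi * spec$fs)
  lead_in <- round(1.0 * spec$fs)

  # Ground truth: one attended stimulus (or row/column pair) per selection.
  if (spec$paradigm == "four_choice") {
    attended <- sample(codes, spec$n_selections, replace = TRUE)
    target_codes <- lapply(attended, identity)
    truth_attended <- attended
  } else {
    rows <- sample(1:6, spec$n_selections, replace = TRUE)
    cols <- sample(7:12, spec$n_selections, replace = TRUE)
    target_codes <- Map(c, rows, cols)
    mat <- speller_matrix()
    truth_attended <- data.frame(
      row = rows, col = cols,
      char = mat[cbind(rows, cols - 6L)],
      stringsAsFactors = FALSE
    )
  }

  # Flash schedule: random order within each repetition block.
  per_sel <- n_codes * spec$n_repetitions
  n_events <- per_sel * spec$n_selections
  code_seq <- integer(n_events)
  sel_idx <- rep(seq_len(spec$n_selections), each = per_sel)
  rep_idx <- rep(rep(seq_len(spec$n_repetitions), each = n_codes),
                 times = spec$n_selections)
  k <- 1L
  for (s in seq_len(spec$n_selections)) {
    for (r in seq_len(spec$n_repetitions)) {
      code_seq[k:(k + n_codes - 1L)] <- sample(codes)
      k <- k + n_codes
    }
  }
  onsets <- lead_in + (seq_len(n_events) - 1L) * isi_samp
  is_target <- mapply(function(code, s) code %in% target_codes[[s]],
                      code_seq, sel_idx)

  schedule <- data.frame(
    onset_sample = as.integer(onsets),
    code = as.integer(code_seq),
    is_target = as.logical(is_target),
    selection = as.integer(sel_idx),
    repetition = as.integer(rep_idx)
  )
  class(schedule) <- c("stimulus_schedule", "data.frame")

  total <- as.integer(onsets[n_events] + round(1.0 * spec$fs))
  sig <- matrix(0, nrow = spec$n_channels, ncol = total)
  for (ch in seq_len(spec$n_channels))
    sig[ch, ] <- colored_noise(total, spec$fs) * spec$noise_sigma

  # Additive ERP template on target trials.
  if (spec$snr > 0) {
    tpl <- erp_template(spec$fs) * spec$snr * spec$noise_sigma
    lt <- length(tpl)
    for (e in which(schedule$is_target)) {
      i0 <- schedule$onset_sample[e] + 1L
      i1 <- min(i0 + lt - 1L, total)
      seg <- seq_len(i1 - i0 + 1L)
      sig[, i0:i1] <- sig[, i0:i1] +
        outer(spec$spatial_weights, tpl[seg])
    }
  }

  # Occasional large artifacts (blink/movement-like excursions).
  if (spec$artifact_rate > 0) {
    hit <- stats::runif(n_events) < spec$artifact_rate
    art_len <- round(0.15 * spec$fs)
    art <- sin(pi * seq(0, 1, length.out = art_len)) * 8 * spec$noise_sigma
    for (e in which(hit)) {
      ch <- sample.int(spec$n_channels, 1L)
      off <- sample.int(max(1L, round(0.65 * spec$fs)), 1L)
      i0 <- schedule$onset_sample[e] + off
      i1 <- min(i0 + art_len - 1L, total)
      if (i0 <= total)
        sig[ch, i0:i1] <- sig[ch, i0:i1] + art[seq_len(i1 - i0 + 1L)]
    }
  }

  rec <- eeg_recording(sig, spec$fs,
                       channel_labels = paste0("CH", seq_len(spec$n_channels)))

  truth <- structure(list(
    paradigm = spec$paradigm,
    attended = truth_attended,
    is_target = schedule$is_target
  ), class = "ground_truth")

  list(recording = rec, schedule = schedule, truth = truth)
}

#' Count target and non-target events in a schedule
#'
#' @param schedule A `stimulus_schedule` data frame.
#' @param truth The matching ground truth (used to cross-check alignment).
#' @return Named integer vector `c(n_target, n_nontarget)`.
#' @export
event_counts <- function(schedule, truth = NULL) {
  if (!is.data.frame(schedule) || !"is_target" %in% names(schedule))
    validation_error("'schedule' must be a stimulus schedule data frame")
  if (!is.null(truth)) {
    if (length(truth$is_target) != nrow(schedule))
      alignment_error(sprintf(
        "schedule has %d events but truth flags %d",
        nrow(schedule), length(truth$is_target)))
    if (!identical(as.logical(truth$is_target),
                   as.logical(schedule$is_target)))
      alignment_error("schedule and truth disagree on target flags")
  }
  n_t <- sum(schedule$is_target)
  c(n_target = as.integer(n_t),
    n_nontarget = as.integer(nrow(schedule) - n_t))
}
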