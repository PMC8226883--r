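# Offline recursive backward channel elimination. Starting from the full
# montage, the channel whose removal yields the highest selection criterion
# TP/(TP+FP+FN) on a holdout split is discarded, round after round, until
# `stop_at` channels remain. The provisional classifier is pluggable.

#' Channel-selection criterion
#'
#' `TP / (TP + FP + FN)` computed from validation confusion counts; defined
#' as 0 when the denominator is 0. Always lies in `[0, 1]`.
#'
#' @param counts A [confusion_counts()] or anything with `TP`, `FP`, `FN`.
#' @return Numeric score in `[0, 1]`.
#' @export
selection_criterion <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (any(c(tp, fp, fn) < 0))
    validation_error("confusion counts must be non-negative")
  den <- tp + fp + fn
  if (den == 0) return(0)
  tp / den
}

#' Provisional classifier factory: logistic regression on per-channel
#' sub-window mean amplitudes
#'
#' A fast pluggable classifier for [recursive_elimination()]: each trial is
#' summarized by the mean amplitude of `n_bins` equal sub-windows per
#' channel (letting the model form temporal contrasts that cancel
#' low-frequency drift), a seeded stratified 70/30 split is drawn, a
#' binomial GLM is fitted on the training part, and validation confusion
#' counts at threshold 0.5 are returned.
#'
#' @param fs Sampling rate of the trials (samples/s; kept for interface
#'   symmetry with time-windowed factories).
#' @param n_bins Number of equal temporal sub-windows per channel
#'   (default 4).
#' @param validation_fraction Holdout fraction (default 0.3).
#' @return A function `(trials, labels, seed) -> confusion_counts`.
#' @export
glm_channel_factory <- function(fs = 240, n_bins = 4L,
                                validation_fraction = 0.3) {
  function(trials, labels, seed = 1L) {
    X3 <- unclass(trials)
    T_len <- dim(X3)[2]; C <- dim(X3)[3]; n <- dim(X3)[1]
    edges <- round(seq(0, T_len, length.out = n_bins + 1L))
    feats <- do.call(cbind, lapply(seq_len(n_bins), function(b) {
      idx <- (edges[b] + 1L):edges[b + 1L]
      vapply(seq_len(C),
             function(ch) rowMeans(X3[, idx, ch, drop = FALSE]),
             numeric(n))
    }))
    y <- as.integer(labels)
    with_seed(seed, {
      val <- stratified_split(y, validation_fraction)
      trn <- setdiff(seq_along(y), val)
      Xd <- cbind(1, feats)
      fit <- suppressWarnings(
        stats::glm.fit(Xd[trn, , drop = FALSE], y[trn],
                       family = stats::binomial()))
      cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      p <- 1 / (1 + exp(-(Xd[val, , drop = FALSE] %*% cf)))
      confusion_from_labels(y[val], as.integer(p > 0.5))
    })
  }
}

#' Provisional classifier factory: the package's conv net without the
#' autoencoder branch
#'
#' The default provisional classifier for [recursive_elimination()]: the
#' detector's batch-normalized convolutional head trained directly on
#' standardized LBP symbols (no autoencoder), on a stratified 70/30 split,
#' returning validation confusion counts. Expects symbolized trials.
#'
#' @param epochs Training epochs (kept small; this classifier only ranks
#'   channel subsets).
#' @param n,step LBP parameters used if raw (unsymbolized) trials are
#'   passed.
#' @return A function `(trials, labels, seed) -> confusion_counts`.
#' @export
cnn_channel_factory <- function(epochs = 30L, n = 8L, step = 3L) {
  function(trials, labels, seed = 1L) {
    X3 <- unclass(trials)
    if (max(X3) > n + 0.5 || any(X3 != round(X3)))
      X3 <- unclass(symbolize_lbp(
        structure(X3, class = "trial_set"), n = n, step = step))
    cfg <- network_config(channels = dim(X3)[3],
                          symbols_per_channel = dim(X3)[2])
    tc <- train_config(epochs_clf = epochs, seed = seed)
    det <- train_classifier(structure(X3, class = "symbolized_trial_set"),
                            labels, ae = NULL, tc = tc, config = cfg)
    val <- det$validation_index
    pred <- predict(det, structure(X3[val, , , drop = FALSE],
                                   class = "symbolized_trial_set"))
    confusion_from_labels(as.integer(labels)[val], pred$label)
  }
}

#' Recursive backward channel elimination
#'
#' Greedy elimination: in each round every remaining channel is tentatively
#' removed, the provisional classifier is trained on the rest, and the
#' channel whose removal yields the highest criterion is discarded (ties:
#' the lowest-index channel). Exactly `C - stop_at` rounds are run.
#'
#' @param trials Trials x T x channels array (raw or symbolized - whatever
#'   the factory consumes).
#' @param labels Binary trial labels.
#' @param classifier_factory Function `(trials, labels, seed) ->`
#'   [confusion_counts()]; see [glm_channel_factory()] (fast) and
#'   [cnn_channel_factory()] (the default architecture-matched one).
#' @param stop_at Number of surviving channels (default 10).
#' @param seed Integer seed passed to the factory (varied per round).
#' @param n_splits Number of holdout splits whose criteria are averaged per
#'   candidate (default 1, a single seeded holdout). The same split seeds
#'   are shared by all candidates of a round, so comparisons are paired;
#'   averaging several splits reduces the variance of the criterion
#'   estimate, which matters when channels are highly redundant.
#' @return An `elimination_trace`: data frame of rounds (`round`,
#'   `removed_channel`, `criterion_after_removal`) with attributes
#'   `surviving` (final channel set) and `per_round` (surviving set after
#'   each round).
#' @export
recursive_elimination <- function(trials, labels, classifier_factory,
                                  stop_at = 10L, seed = 1L, n_splits = 1L) {
  X3 <- unclass(trials)
  if (length(dim(X3)) != 3)
    validation_error("'trials' must be a trials x T x channels array")
  C <- dim(X3)[3]
  check_scalar(stop_at, "stop_at", lo = 1, integer = TRUE)
  if (C < stop_at + 1)
    validation_error(sprintf(
      "need at least stop_at + 1 = %d channels, got %d", stop_at + 1, C))

  current <- seq_len(C)
  trace <- data.frame(round = integer(), removed_channel = integer(),
                      criterion_after_removal = numeric())
  per_round <- list()
  round_i <- 0L
  while (length(current) > stop_at) {
    round_i <- round_i + 1L
    scores <- vapply(seq_along(current), function(j) {
      keep <- current[-j]
      crit <- vapply(seq_len(n_splits), function(s) {
        counts <- tryCatch(
          classifier_factory(
            X3[, , keep, drop = FALSE], labels,
            derive_seed(seed, sprintf("round%d_split%d", round_i, s))),
          error = function(e) abort(
            sprintf("provisional classifier failed in round %d (dropping channel %d): %s",
                    round_i, current[j], conditionMessage(e)),
            "p300lbp_elimination_error"))
        selection_criterion(counts)
      }, 0)
      mean(crit)
    }, 0)
    best <- which.max(scores)  # ties: lowest index
    trace <- rbind(trace, data.frame(
      round = round_i,
      removed_channel = current[best],
      criterion_after_removal = scores[best]))
    current <- current[-best]
    per_round[[round_i]] <- current
  }
  structure(trace, surviving = current, per_round = per_round,
            n_channels = C, class = c("elimination_trace", "data.frame"))
}

#' Cross-subject channel consensus
#'
#' Ranks channels by (1) the number of subjects whose surviving top set
#' contains them and (2) the mean round at which they were removed (later
#' or never removed ranks higher), with lower channel index breaking
#' remaining ties, and returns the best `n_final`.
#'
#' @param traces List of [recursive_elimination()] traces (one per subject).
#' @param n_final Number of channels to select (default 6).
#' @return Integer vector of selected channel indices.
#' @export
cross_subject_select <- function(traces, n_final = 6L) {
  if (length(traces) == 0)
    validation_error("at least one elimination trace is required")
  check_scalar(n_final, "n_final", lo = 1, integer = TRUE)
  C <- max(vapply(traces, function(tr) as.numeric(attr(tr, "n_channels")), 0))
  membership <- numeric(C)
  removal_round <- matrix(NA_real_, nrow = length(traces), ncol = C)
  for (s in seq_along(traces)) {
    tr <- traces[[s]]
    surv <- attr(tr, "surviving")
    membership[surv] <- membership[surv] + 1
    max_round <- max(tr$round, 0L)
    removal_round[s, tr$removed_channel] <- tr$round
    removal_round[s, surv] <- max_round + 1  # survivors outrank all removals
  }
  mean_round <- colMeans(removal_round, na.rm = TRUE)
  mean_round[is.nan(mean_round)] <- 0
  ord <- order(-membership, -mean_round, seq_len(C))
  sort(ord[seq_len(min(n_final, C))])
}
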