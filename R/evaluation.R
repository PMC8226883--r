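# Single-trial classification metrics and BCI speed analytics (information
# transfer rate with paradigm-specific selection times).

#' Confusion counts
#'
#' @param TP,FP,TN,FN Non-negative counts. `TP` counts correctly classified
#'   P300 (target) trials, `TN` correctly rejected non-targets.
#' @return Named numeric vector of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(!is.finite(v)) || any(v < 0))
    validation_error("confusion counts must be finite and non-negative")
  structure(v, class = "confusion_counts")
}

#' Confusion counts from label vectors
#'
#' @param truth,pred Binary vectors (1 = target/P300).
#' @return A [confusion_counts()].
#' @export
confusion_from_labels <- function(truth, pred) {
  if (length(truth) != length(pred))
    alignment_error("'truth' and 'pred' lengths differ")
  t1 <- truth == 1
  p1 <- pred == 1
  confusion_counts(TP = sum(t1 & p1), FP = sum(!t1 & p1),
                   TN = sum(!t1 & !p1), FN = sum(t1 & !p1))
}

#' Single-trial classification metrics (percent)
#'
#' precision = 100 TP/(TP+FP); recall = 100 TP/(TP+FN); accuracy =
#' 100 (TP+TN)/total; F1 = 100 * 2TP/(2TP+FP+FN). Any 0/0 cell is reported
#' as 0 with a warning.
#'
#' @param counts A [confusion_counts()].
#' @return Object of class `metrics_report`: named vector `precision`,
#'   `recall`, `accuracy`, `f1`, each in `[0, 100]`.
#' @examples
#' metrics(confusion_counts(TP = 364, FP = 269, TN = 1231, FN = 136))
#' @export
metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts"))
    counts <- do.call(confusion_counts, as.list(counts[c("TP", "FP", "TN", "FN")]))
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  total <- tp + fp + tn + fn
  if (total == 0) validation_error("total count must be positive")
  ratio0 <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s is 0/0; reporting 0", what), call. = FALSE)
      return(0)
    }
    num / den
  }
  structure(c(
    precision = 100 * ratio0(tp, tp + fp, "precision"),
    recall    = 100 * ratio0(tp, tp + fn, "recall"),
    accuracy  = 100 * (tp + tn) / total,
    f1        = 100 * ratio0(2 * tp, 2 * tp + fp + fn, "F1")
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.2f%% | recall %.2f%% | accuracy %.2f%% | F1 %.2f%%\n",
              x[["precision"]], x[["recall"]], x[["accuracy"]], x[["f1"]]))
  invisible(x)
}

#' Aggregate per-subject metric reports
#'
#' Arithmetic mean and sample (n-1) standard deviation of each metric. A
#' single report yields its own values with `sd = 0` and attribute
#' `single = TRUE`.
#'
#' @param reports List of [metrics()] results.
#' @return Data frame with columns `metric`, `mean`, `sd`.
#' @export
aggregate_metrics <- function(reports) {
  if (length(reports) == 0)
    validation_error("at least one report is required")
  M <- do.call(rbind, lapply(reports, unclass))
  out <- data.frame(
    metric = colnames(M),
    mean = colMeans(M),
    sd = if (nrow(M) > 1) apply(M, 2, stats::sd) else rep(0, ncol(M)),
    row.names = NULL
  )
  attr(out, "single") <- nrow(M) == 1
  out
}

#' Time needed for one selection
#'
#' Four-choice: `T = 0.5 + 0.7 n_rep` seconds (a 0.7 s four-flash block per
#' repetition plus a 0.5 s pause). Speller: `T = 2.5 + 2.1 n_rep` seconds
#' (a 2.1 s twelve-flash block per repetition plus a 2.5 s pause).
#'
#' @param paradigm `"four_choice"` or `"speller6x6"`.
#' @param n_rep Number of repetitions used for the decision. The published
#'   timing model covers 1-2 (four-choice) and 1-15 (speller) repetitions;
#'   values outside warn.
#' @return Selection time in seconds.
#' @export
selection_time <- function(paradigm = c("four_choice", "speller6x6"), n_rep) {
  paradigm <- match.arg(paradigm)
  check_scalar(n_rep, "n_rep", lo = 1, integer = TRUE)
  if (paradigm == "four_choice") {
    if (n_rep > 2) warning("four-choice timing model covers n_rep in {1,2}",
                           call. = FALSE)
    0.5 + 0.7 * n_rep
  } else {
    if (n_rep > 15) warning("speller timing model covers n_rep in 1..15",
                            call. = FALSE)
    2.5 + 2.1 * n_rep
  }
}

#' Information transfer rate (bits/min)
#'
#' Wolpaw's formula: with selection accuracy `P` among `N` classes and
#' selection time `T` seconds, the bits per selection are
#' `P log2 P + (1 - P) log2((1 - P)/(N - 1)) + log2 N`, and
#' `ITR = 60 * bits / T`. Limits are handled analytically: `P = 1` gives
#' `60 log2(N)/T`, `P = 1/N` gives 0, and `P = 0` gives
#' `60 log2(N/(N-1))/T`.
#'
#' @param P Selection accuracy in `[0, 1]`.
#' @param N Number of classes (4 or 36 in the supported paradigms).
#' @param T_sel Selection time in seconds (see [selection_time()]).
#' @return ITR in bits/min.
#' @examples
#' itr(1, 4, selection_time("four_choice", 1))    # 100 bits/min
#' itr(0.42, 36, selection_time("speller6x6", 1)) # ~15.8 bits/min
#' @export
itr <- function(P, N, T_sel) {
  check_scalar(P, "P", lo = 0, hi = 1)
  check_scalar(N, "N", lo = 2, integer = TRUE)
  check_scalar(T_sel, "T_sel", lo = 1e-12)
  xlogx <- function(p) if (p <= 0) 0 else p * log2(p)
  bits <- xlogx(P) + (1 - P) * (if (P >= 1) 0 else log2((1 - P) / (N - 1))) +
    log2(N)
  60 * bits / T_sel
}

#' ITR of a paradigm run, in both averaging modes
#'
#' Per-subject accuracies can be converted to a group ITR either by
#' averaging per-subject ITRs (`mode = "per_subject"`) or by applying the
#' ITR formula to the mean accuracy (`mode = "pooled"`); both conventions
#' appear in the BCI literature and they differ whenever the accuracies do.
#'
#' @param P Vector of per-subject selection accuracies.
#' @param N Number of classes.
#' @param T_sel Selection time in seconds.
#' @param mode `"per_subject"` or `"pooled"`.
#' @return ITR in bits/min.
#' @export
itr_group <- function(P, N, T_sel, mode = c("per_subject", "pooled")) {
  mode <- match.arg(mode)
  if (mode == "per_subject")
    mean(vapply(P, itr, 0, N = N, T_sel = T_sel))
  else
    itr(mean(P), N, T_sel)
}
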