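# Class rebalancing for the heavily skewed odd-ball trial sets (1 target :
# 3 or 5 non-targets): NearMiss-2 undersampling of the majority class to an
# intermediate ratio, then random duplication of the minority class to
# exact parity. No synthetic feature vectors are ever fabricated - every
# output row is a row of the input.

#' Resampling configuration
#'
#' @param nearmiss_k Number of *farthest* minority neighbours whose average
#'   Euclidean distance scores each majority sample (default 3).
#' @param undersample_ratio Majority:minority ratio kept after
#'   undersampling (default 2, i.e. 2:1).
#' @param seed Integer seed for the oversampling draw.
#' @return An object of class `resample_config`.
#' @export
resample_config <- function(nearmiss_k = 3L, undersample_ratio = 2,
                            seed = 1L) {
  check_scalar(nearmiss_k, "nearmiss_k", lo = 1, integer = TRUE)
  check_scalar(undersample_ratio, "undersample_ratio", lo = 1)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(nearmiss_k = as.integer(nearmiss_k),
                 undersample_ratio = undersample_ratio,
                 seed = as.integer(seed)),
            class = "resample_config")
}

flatten_features <- function(x) {
  if (length(dim(x)) == 3) {
    d <- dim(x)
    m <- unclass(x)
    dim(m) <- c(d[1], d[2] * d[3])
    return(m)
  }
  if (is.matrix(x)) return(x)
  validation_error("'features' must be a matrix or trials x T x C array")
}

split_classes <- function(y) {
  tab <- table(y)
  if (length(tab) != 2)
    validation_error("exactly two classes are required")
  minority <- names(tab)[which.min(tab)]
  list(min_idx = which(y == minority), maj_idx = which(y != minority))
}

#' NearMiss-2 undersampling of the majority class
#'
#' Retains the majority-class samples whose average Euclidean distance to
#' their `k` farthest minority-class samples is smallest, until the
#' configured majority:minority ratio is reached. The minority class is
#' untouched; ties are broken by original index order, making the operation
#' deterministic.
#'
#' @param features Matrix (rows = trials) or trials x T x C array; arrays
#'   are flattened per trial.
#' @param labels Binary class vector.
#' @param cfg A [resample_config()].
#' @return List with `features`, `labels`, and `kept` (the retained row
#'   indices into the input, minority first).
#' @export
nearmiss2_undersample <- function(features, labels, cfg = resample_config()) {
  X <- flatten_features(features)
  y <- labels
  if (nrow(X) != length(y))
    alignment_error("'features' rows and 'labels' length differ")
  cls <- split_classes(y)
  if (length(cls$min_idx) == 0)
    validation_error("minority class is empty")
  n_keep <- min(length(cls$maj_idx),
                ceiling(cfg$undersample_ratio * length(cls$min_idx)))
  if (length(cls$maj_idx) <= n_keep) {
    kept <- sort(c(cls$min_idx, cls$maj_idx))
    return(list(features = X[kept, , drop = FALSE], labels = y[kept],
                kept = kept))
  }
  Xmin <- X[cls$min_idx, , drop = FALSE]
  Xmaj <- X[cls$maj_idx, , drop = FALSE]
  k <- min(cfg$nearmiss_k, nrow(Xmin))
  # Squared-distance matrix majority x minority via the expansion
  # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(Xmaj^2), rowSums(Xmin^2), "+") -
    2 * Xmaj %*% t(Xmin)
  d2[d2 < 0] <- 0
  score <- apply(sqrt(d2), 1, function(dr)
    mean(sort(dr, decreasing = TRUE)[seq_len(k)]))
  keep_maj <- cls$maj_idx[order(score, seq_along(score))[seq_len(n_keep)]]
  kept <- sort(c(cls$min_idx, keep_maj))
  list(features = X[kept, , drop = FALSE], labels = y[kept], kept = kept)
}

#' Random oversampling of the minority class to parity
#'
#' Duplicates minority-class rows uniformly at random (with replacement,
#' seeded) until both classes have equal counts. Every appended row is an
#' exact copy of an original.
#'
#' @inheritParams nearmiss2_undersample
#' @return List with `features`, `labels`, and `duplicated` (input row
#'   indices of the appended copies).
#' @export
random_oversample <- function(features, labels, cfg = resample_config()) {
  X <- flatten_features(features)
  y <- labels
  if (nrow(X) != length(y))
    alignment_error("'features' rows and 'labels' length differ")
  cls <- split_classes(y)
  n_extra <- length(cls$maj_idx) - length(cls$min_idx)
  if (n_extra <= 0)
    return(list(features = X, labels = y, duplicated = integer(0)))
  dup <- with_seed(derive_seed(cfg$seed, "oversample"),
                   sample(cls$min_idx, n_extra, replace = TRUE))
  list(features = rbind(X, X[dup, , drop = FALSE]),
       labels = c(y, y[dup]),
       duplicated = dup)
}

#' Full rebalancing pipeline: NearMiss-2 then random oversampling
#'
#' @inheritParams nearmiss2_undersample
#' @return List with `features`, `labels` (exact 1:1 ratio), and an `audit`
#'   record of kept and duplicated input indices.
#' @export
rebalance_trials <- function(features, labels, cfg = resample_config()) {
  und <- nearmiss2_undersample(features, labels, cfg)
  ove <- random_oversample(und$features, und$labels, cfg)
  dup_orig <- und$kept[ove$duplicated]
  list(features = ove$features, labels = ove$labels,
       audit = list(kept = und$kept, duplicated = dup_orig))
}
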