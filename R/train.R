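# Two-phase training: (1) the shared autoencoder is fitted on pooled
# single-channel symbol vectors with MSE/RMSprop and then frozen; (2) the
# convolutional classifier head is fitted on the frozen autoencoder's
# reconstructions with binary cross-entropy/Adam.

#' Training configuration
#'
#' Defaults follow the detector's published training recipe: autoencoder
#' with MSE loss, RMSprop optimizer (default hyperparameters) and minibatch
#' 32, monitoring mean absolute error; classifier with binary cross-entropy,
#' Adam at learning rate 1e-4 (beta1 0.9, beta2 0.999, epsilon 1e-8, no
#' decay) and minibatch 64, with a 30% holdout for validation. Epoch counts
#' and early stopping are not part of the recipe and are exposed here with
#' defaults of 100 (autoencoder) and 200 (classifier) epochs, stopping when
#' the validation loss has not improved for `patience` epochs.
#'
#' @param epochs_ae,epochs_clf Maximum training epochs for the two phases.
#' @param ae_batch,clf_batch Minibatch sizes (32 and 64).
#' @param ae_lr RMSprop learning rate (default 1e-3).
#' @param clf_lr Adam learning rate (default 1e-4).
#' @param validation_fraction Holdout fraction for validation (default 0.3).
#' @param patience Early-stopping patience in epochs (default 20); the
#'   weights of the best validation epoch are restored.
#' @param seed Integer seed controlling shuffling, initialization and
#'   dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs_ae = 100L, epochs_clf = 200L,
                         ae_batch = 32L, clf_batch = 64L,
                         ae_lr = 1e-3, clf_lr = 1e-4,
                         validation_fraction = 0.30,
                         patience = 20L, seed = 1L) {
  check_scalar(epochs_ae, "epochs_ae", lo = 1, integer = TRUE)
  check_scalar(epochs_clf, "epochs_clf", lo = 1, integer = TRUE)
  check_scalar(ae_batch, "ae_batch", lo = 1, integer = TRUE)
  check_scalar(clf_batch, "clf_batch", lo = 1, integer = TRUE)
  check_scalar(ae_lr, "ae_lr", lo = 1e-12)
  check_scalar(clf_lr, "clf_lr", lo = 1e-12)
  check_scalar(validation_fraction, "validation_fraction",
               lo = 1e-9, hi = 1 - 1e-9)
  check_scalar(patience, "patience", lo = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(epochs_ae = as.integer(epochs_ae),
                 epochs_clf = as.integer(epochs_clf),
                 ae_batch = as.integer(ae_batch),
                 clf_batch = as.integer(clf_batch),
                 ae_lr = ae_lr, clf_lr = clf_lr,
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

symbols_to_array <- function(symbols) {
  if (inherits(symbols, "symbolized_trial_set") || length(dim(symbols)) == 3)
    return(unclass(symbols))
  validation_error("'symbols' must be a symbolized trial set (n x L_s x C)")
}

# Per-channel standardization statistics (the input-normalization stage).
fit_norm <- function(X3) {
  C <- dim(X3)[3]
  mu <- numeric(C); sd_ <- numeric(C)
  for (ch in seq_len(C)) {
    mu[ch] <- mean(X3[, , ch])
    sd_[ch] <- stats::sd(as.numeric(X3[, , ch]))
    if (!is.finite(sd_[ch]) || sd_[ch] < 1e-8) sd_[ch] <- 1
  }
  list(mu = mu, sd = sd_)
}

apply_norm <- function(X3, norm) {
  out <- X3
  for (ch in seq_len(dim(X3)[3]))
    out[, , ch] <- (X3[, , ch] - norm$mu[ch]) / norm$sd[ch]
  out
}

# Pool the channel slices of a standardized symbol array into independent
# training vectors (rows).
pool_channels <- function(X3) {
  do.call(rbind, lapply(seq_len(dim(X3)[3]), function(ch) {
    m <- X3[, , ch, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(X3)[1])
    m
  }))
}

#' Train the shared autoencoder
#'
#' Fits the 16-8-16-linear autoencoder on pooled single-channel symbol
#' vectors from the training split (each channel slice is an independent
#' training vector), using MSE loss, RMSprop and minibatch 32, then freezes
#' the weights. A `validation_fraction` holdout monitors reconstruction
#' error; training aborts with a `training_error` if the loss turns
#' non-finite.
#'
#' @param symbols A `symbolized_trial_set` (n x L_s x C) of training trials.
#' @param tc A [train_config()].
#' @param config A [network_config()]; its `symbols_per_channel` must match
#'   the symbol array.
#' @return A frozen `p300_autoencoder` with the fitted input normalization,
#'   training history, and initial/final held-out MSE.
#' @export
train_autoencoder <- function(symbols, tc = train_config(),
                              config = network_config()) {
  X3 <- symbols_to_array(symbols)
  if (dim(X3)[2] != config$symbols_per_channel)
    validation_error(sprintf(
      "symbol length %d does not match config (%d)",
      dim(X3)[2], config$symbols_per_channel))
  with_seed(derive_seed(tc$seed, "autoencoder"), {
    norm <- fit_norm(X3)
    X <- pool_channels(apply_norm(X3, norm))
    m <- nrow(X)
    idx <- sample.int(m)
    n_val <- max(1L, round(tc$validation_fraction * m))
    val <- idx[seq_len(n_val)]
    trn <- idx[-seq_len(n_val)]
    Xtr <- X[trn, , drop = FALSE]
    Xval <- X[val, , drop = FALSE]

    L <- config$symbols_per_channel; u <- config$ae_units
    params <- c(nn_rename(nn_dense_init(L, u[1]), 1),
                nn_rename(nn_dense_init(u[1], u[2]), 2),
                nn_rename(nn_dense_init(u[2], u[3]), 3),
                nn_rename(nn_dense_init(u[3], L), 4))
    names(params) <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")
    st <- rmsprop_init(params)

    val_mse <- function(p) mean((ae_forward(p, Xval)$Y - Xval)^2)
    val_mae <- function(p) mean(abs(ae_forward(p, Xval)$Y - Xval))
    initial_mse <- val_mse(params)

    nb <- ceiling(nrow(Xtr) / tc$ae_batch)
    hist_ <- data.frame(epoch = integer(), loss = numeric(),
                        val_mse = numeric(), val_mae = numeric())
    for (ep in seq_len(tc$epochs_ae)) {
      ord <- sample.int(nrow(Xtr))
      ep_loss <- 0
      for (bi in seq_len(nb)) {
        rows <- ord[((bi - 1L) * tc$ae_batch + 1L):
                      min(bi * tc$ae_batch, nrow(Xtr))]
        cache <- ae_forward(params, Xtr[rows, , drop = FALSE])
        loss <- mean((cache$Y - cache$X)^2)
        if (!is.finite(loss))
          training_error("autoencoder loss became non-finite",
                         history = hist_)
        ep_loss <- ep_loss + loss * length(rows)
        g <- ae_backward(params, cache)
        upd <- rmsprop_step(params, g, st, lr = tc$ae_lr)
        params <- upd$params; st <- upd$state
      }
      hist_ <- rbind(hist_, data.frame(
        epoch = ep, loss = ep_loss / nrow(Xtr),
        val_mse = val_mse(params), val_mae = val_mae(params)))
    }

    structure(list(params = params, norm = norm,
                   config = config, frozen = TRUE,
                   initial_val_mse = initial_mse,
                   final_val_mse = val_mse(params),
                   history = hist_),
              class = "p300_autoencoder")
  })
}

#' @export
print.p300_autoencoder <- function(x, ...) {
  cat("<p300_autoencoder>", if (isTRUE(x$frozen)) "frozen" else "unfrozen",
      "\n")
  if (!is.null(x$history))
    cat(sprintf("  held-out MSE %.4g (initial %.4g) after %d epochs\n",
                x$final_val_mse, x$initial_val_mse, nrow(x$history)))
  invisible(x)
}

# Frozen-AE reconstruction of a standardized symbol array, channel-shared.
ae_reconstruct <- function(ae, X3) {
  out <- X3
  for (ch in seq_len(dim(X3)[3])) {
    m <- X3[, , ch, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(X3)[1])
    out[, , ch] <- ae_forward(ae$params, m)$Y
  }
  out
}

ae_weights_digest <- function(ae) {
  paste(vapply(ae$params, function(p) sprintf("%.17g", sum(p) + sum(p * p)),
               ""), collapse = "|")
}

stratified_split <- function(y, frac_val) {
  idx_val <- integer(0)
  for (cl in unique(y)) {
    cls <- which(y == cl)
    n_val <- max(1L, round(frac_val * length(cls)))
    idx_val <- c(idx_val, sample(cls, n_val))
  }
  sort(idx_val)
}

# Stratified split that keeps identical feature rows (e.g. the exact copies
# appended by random oversampling) on the same side, so the validation
# estimate is never inflated by memorized duplicates.
grouped_stratified_split <- function(X, y, frac_val) {
  key <- apply(X, 1, function(r) paste(r, collapse = ","))
  idx_val <- integer(0)
  for (cl in unique(y)) {
    cls <- which(y == cl)
    groups <- split(cls, key[cls])
    ord <- sample(length(groups))
    target <- frac_val * length(cls)
    got <- 0L
    for (gi in ord) {
      if (got >= target) break
      idx_val <- c(idx_val, groups[[gi]])
      got <- got + length(groups[[gi]])
    }
  }
  sort(idx_val)
}

#' Train the classifier head on frozen autoencoder features
#'
#' Reconstructs every trial through the frozen shared autoencoder, then
#' fits the batch-normalized convolutional head with binary cross-entropy
#' and Adam (lr 1e-4), minibatch 64, on a stratified 70/30 train/validation
#' split. Dropout (rate 0.4) is active only during training. The
#' autoencoder weights are never touched (verified by digest). Early
#' stopping restores the best-validation-loss weights.
#'
#' @param symbols Training `symbolized_trial_set` (n x L_s x C).
#' @param labels Binary vector (1 = P300/target trial). Class balance is
#'   expected to be handled beforehand (see [rebalance_trials()]).
#' @param ae A frozen [train_autoencoder()] result, or `NULL` to train the
#'   head directly on standardized symbols (the provisional,
#'   autoencoder-free variant used during channel selection).
#' @param tc A [train_config()].
#' @param config A [network_config()].
#' @return A trained `p300_detector`.
#' @export
train_classifier <- function(symbols, labels, ae = NULL,
                             tc = train_config(),
                             config = network_config()) {
  X3 <- symbols_to_array(symbols)
  y <- as.integer(labels)
  if (length(y) != dim(X3)[1])
    alignment_error("'labels' length does not match the trial count")
  if (length(unique(y)) < 2)
    validation_error("'labels' must contain both classes")
  if (!all(y %in% c(0L, 1L)))
    validation_error("'labels' must be binary (0/1)")
  if (dim(X3)[2] != config$symbols_per_channel ||
      dim(X3)[3] != config$channels)
    validation_error(sprintf(
      "symbol array (%d,%d) does not match config (%d,%d)",
      dim(X3)[2], dim(X3)[3],
      config$symbols_per_channel, config$channels))
  if (!is.null(ae)) {
    if (!inherits(ae, "p300_autoencoder") || !isTRUE(ae$frozen))
      validation_error("'ae' must be a frozen p300_autoencoder")
    digest_before <- ae_weights_digest(ae)
  }

  with_seed(derive_seed(tc$seed, "classifier"), {
    if (is.null(ae)) {
      norm <- fit_norm(X3)
      feats <- apply_norm(X3, norm)
    } else {
      norm <- ae$norm
      feats <- ae_reconstruct(ae, apply_norm(X3, norm))
    }

    Xflat <- X3; dim(Xflat) <- c(dim(X3)[1], dim(X3)[2] * dim(X3)[3])
    val <- grouped_stratified_split(Xflat, y, tc$validation_fraction)
    trn <- setdiff(seq_along(y), val)
    Xtr <- feats[trn, , , drop = FALSE]; ytr <- y[trn]
    Xval <- feats[val, , , drop = FALSE]; yval <- y[val]

    clf <- clf_init(config)
    st <- adam_init(clf$params)
    nb <- ceiling(length(ytr) / tc$clf_batch)
    hist_ <- data.frame(epoch = integer(), loss = numeric(),
                        val_loss = numeric(), val_acc = numeric(),
                        val_f1 = numeric())
    # Early stopping monitors the validation loss; the restored weights are
    # those of the best-validation-F1 epoch, F1 being the design metric of
    # this detector (imbalance-robust, and what the decision stage feeds on).
    best_loss <- Inf
    best <- list(f1 = -Inf, clf = clf, epoch = 0L)
    stall <- 0L

    for (ep in seq_len(tc$epochs_clf)) {
      ord <- sample.int(length(ytr))
      ep_loss <- 0
      for (bi in seq_len(nb)) {
        rows <- ord[((bi - 1L) * tc$clf_batch + 1L):
                      min(bi * tc$clf_batch, length(ytr))]
        fw <- clf_forward(clf, Xtr[rows, , , drop = FALSE], config,
                          training = TRUE)
        loss <- bce_loss(fw$prob, ytr[rows])
        if (!is.finite(loss))
          training_error("classifier loss became non-finite",
                         history = hist_)
        ep_loss <- ep_loss + loss * length(rows)
        g <- clf_backward(clf, config, fw$cache, ytr[rows])
        upd <- adam_step(clf$params, g, st, lr = tc$clf_lr)
        clf$params <- upd$params; st <- upd$state
        clf$moving$bn1.mean <- BN_MOMENTUM * clf$moving$bn1.mean +
          (1 - BN_MOMENTUM) * fw$cache$c1$mu
        clf$moving$bn1.var <- BN_MOMENTUM * clf$moving$bn1.var +
          (1 - BN_MOMENTUM) * fw$cache$c1$v
        clf$moving$bn2.mean <- BN_MOMENTUM * clf$moving$bn2.mean +
          (1 - BN_MOMENTUM) * fw$cache$c2$mu
        clf$moving$bn2.var <- BN_MOMENTUM * clf$moving$bn2.var +
          (1 - BN_MOMENTUM) * fw$cache$c2$v
      }
      pv <- clf_forward(clf, Xval, config, training = FALSE)$prob
      vl <- bce_loss(pv, yval)
      lab <- as.integer(pv > config$decision_threshold)
      va <- mean(lab == yval)
      tp <- sum(lab == 1L & yval == 1L)
      vf1 <- if (2 * tp + sum(lab != yval) == 0) 0 else
        2 * tp / (2 * tp + sum(lab == 1L & yval == 0L) +
                    sum(lab == 0L & yval == 1L))
      hist_ <- rbind(hist_, data.frame(
        epoch = ep, loss = ep_loss / length(ytr),
        val_loss = vl, val_acc = va, val_f1 = vf1))
      if (vf1 > best$f1) best <- list(f1 = vf1, clf = clf, epoch = ep)
      if (vl < best_loss - 1e-6) {
        best_loss <- vl
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tc$patience) break
      }
    }
    clf <- best$clf

    if (!is.null(ae) && !identical(ae_weights_digest(ae), digest_before))
      training_error("frozen autoencoder weights were mutated")

    det <- structure(list(
      config = config, norm = norm, ae = ae, clf = clf,
      history = hist_, best_epoch = best$epoch,
      validation_index = val, trained = TRUE),
      class = "p300_detector")
    det
  })
}

#' Predict P300 probabilities and labels for symbolized trials
#'
#' Inference is deterministic: dropout is inactive and batch norms use
#' their moving statistics. The binary label is `probability >
#' decision_threshold` (strict, so a probability of exactly 0.5 maps to 0).
#'
#' @param object A `p300_detector`.
#' @param symbols A `symbolized_trial_set` (n x L_s x C).
#' @param ... Unused.
#' @return List with `prob` (numeric in `[0, 1]`) and `label` (integer 0/1).
#' @export
predict.p300_detector <- function(object, symbols, ...) {
  X3 <- symbols_to_array(symbols)
  if (dim(X3)[2] != object$config$symbols_per_channel ||
      dim(X3)[3] != object$config$channels)
    validation_error(sprintf(
      "symbol array (%d,%d) does not match detector input (%d,%d)",
      dim(X3)[2], dim(X3)[3],
      object$config$symbols_per_channel, object$config$channels))
  feats <- apply_norm(X3, object$norm)
  if (!is.null(object$ae)) feats <- ae_reconstruct(object$ae, feats)
  prob <- clf_forward(object$clf, feats, object$config,
                      training = FALSE)$prob
  list(prob = prob,
       label = as.integer(prob > object$config$decision_threshold))
}
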