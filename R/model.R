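# Detector architecture: per-channel shared autoencoder, concatenation,
# batch-normalized 1D convolution and dense head, plus the per-layer
# parameter / MACC complexity ledger.
#
# Two configuration profiles are provided. "shapes" (the default) uses 54
# symbols per channel, the length the LBP symbolizer emits for a 168-sample
# trial, and reproduces the published tensor shapes (54,6) -> (6,16) ->
# (96,). "counts" uses 56 symbols per channel (trial window extended to
# [0.1 s, 0.825 s], 174 samples) and reproduces the published per-layer
# parameter counts and their totals; the two sets of published figures are
# mutually inconsistent and cannot be met by a single input length.

#' Detector architecture configuration
#'
#' @param profile `"shapes"` (54 symbols/channel; published tensor shapes)
#'   or `"counts"` (56 symbols/channel; published parameter counts).
#' @param channels Number of EEG channels feeding parallel autoencoder
#'   branches (default 6).
#' @param symbols_per_channel Override the per-channel input length (else
#'   set by the profile).
#' @param ae_units Encoder/code/decoder widths of the shared autoencoder
#'   (default 16, 8, 16; the linear output layer matches the input length).
#' @param conv_filters,conv_kernel,conv_stride 1D convolution geometry
#'   (default 16 filters, kernel 8, stride 8, no padding - non-overlapping
#'   temporal filtering, roughly 100 ms per step).
#' @param dense_units Dense head widths (default 64, 64, 1).
#' @param dropout_rate Drop probability applied after the two hidden dense
#'   layers during training (default 0.4).
#' @param decision_threshold Probability threshold for the binary label;
#'   the comparison is strict (`prob > threshold`).
#' @return An object of class `network_config`.
#' @export
network_config <- function(profile = c("shapes", "counts"),
                           channels = 6L,
                           symbols_per_channel = NULL,
                           ae_units = c(16L, 8L, 16L),
                           conv_filters = 16L,
                           conv_kernel = 8L,
                           conv_stride = 8L,
                           dense_units = c(64L, 64L, 1L),
                           dropout_rate = 0.4,
                           decision_threshold = 0.5) {
  profile <- match.arg(profile)
  if (is.null(symbols_per_channel))
    symbols_per_channel <- if (profile == "shapes") 54L else 56L
  check_scalar(channels, "channels", lo = 1, integer = TRUE)
  check_scalar(symbols_per_channel, "symbols_per_channel", lo = 2,
               integer = TRUE)
  check_scalar(conv_filters, "conv_filters", lo = 1, integer = TRUE)
  check_scalar(conv_kernel, "conv_kernel", lo = 1, integer = TRUE)
  check_scalar(conv_stride, "conv_stride", lo = 1, integer = TRUE)
  check_scalar(dropout_rate, "dropout_rate", lo = 0, hi = 0.999)
  if (length(ae_units) != 3 || any(ae_units < 1))
    validation_error("'ae_units' must be three positive counts")
  if (length(dense_units) != 3 || dense_units[3] != 1)
    validation_error("'dense_units' must be three counts ending in 1")
  if (symbols_per_channel < conv_kernel)
    validation_error(
      "'symbols_per_channel' is smaller than the convolution kernel")
  steps <- conv_steps(symbols_per_channel, conv_kernel, conv_stride)

  structure(list(
    profile = profile,
    channels = as.integer(channels),
    symbols_per_channel = as.integer(symbols_per_channel),
    ae_units = as.integer(ae_units),
    conv_filters = as.integer(conv_filters),
    conv_kernel = as.integer(conv_kernel),
    conv_stride = as.integer(conv_stride),
    conv_steps = steps,
    flatten_size = steps * as.integer(conv_filters),
    dense_units = as.integer(dense_units),
    dropout_rate = dropout_rate,
    decision_threshold = decision_threshold
  ), class = "network_config")
}

#' Trial window implied by a configuration profile
#'
#' Returns the post-stimulus window (seconds) whose LBP symbolization
#' yields `symbols_per_channel` symbols: `[0.1, 0.8]` for the shapes
#' profile (168 samples, 54 symbols) and `[0.1, 0.825]` for the counts
#' profile (174 samples, 56 symbols).
#'
#' @param config A [network_config()].
#' @export
profile_window <- function(config) {
  if (config$symbols_per_channel == 56L) c(0.1, 0.825) else c(0.1, 0.8)
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> profile '%s'\n", x$profile))
  cat(sprintf("  input (%d,%d) -> shared AE %s -> conv %d@%dx%d -> (%d,%d) -> flatten %d -> dense %s\n",
              x$symbols_per_channel, x$channels,
              paste(x$ae_units, collapse = "-"),
              x$conv_filters, x$conv_kernel, x$conv_stride,
              x$conv_steps, x$conv_filters, x$flatten_size,
              paste(x$dense_units, collapse = "-")))
  invisible(x)
}

#' Build an untrained detector
#'
#' Instantiates the full architecture with randomly initialized weights:
#' input standardization (identity until fitted), one shared autoencoder
#' (dense 16 ReLU, 8 ReLU, 16 ReLU, linear output) applied to each channel
#' slice, concatenation, batch norm, non-overlapping 1D convolution + ReLU,
#' flatten, batch norm, two 64-unit ReLU dense layers with dropout, and a
#' single sigmoid unit.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `p300_detector` (untrained).
#' @export
build_detector <- function(config, seed = NULL) {
  if (!inherits(config, "network_config"))
    validation_error("'config' must be a network_config")
  with_seed(seed, {
    L <- config$symbols_per_channel
    u <- config$ae_units
    ae <- list(
      params = c(nn_rename(nn_dense_init(L, u[1]), 1),
                 nn_rename(nn_dense_init(u[1], u[2]), 2),
                 nn_rename(nn_dense_init(u[2], u[3]), 3),
                 nn_rename(nn_dense_init(u[3], L), 4)),
      frozen = FALSE, history = NULL)
    class(ae) <- "p300_autoencoder"
    det <- list(
      config = config,
      norm = list(mu = numeric(config$channels),
                  sd = rep(1, config$channels)),
      ae = ae,
      clf = clf_init(config),
      history = NULL,
      trained = FALSE)
    class(det) <- "p300_detector"
    det
  })
}

nn_rename <- function(layer, i) {
  stats::setNames(layer, paste0(c("W", "b"), i))
}

#' @export
print.p300_detector <- function(x, ...) {
  cat("<p300_detector>", if (isTRUE(x$trained)) "trained" else "untrained",
      sprintf("(profile '%s')\n", x$config$profile))
  rep_ <- count_parameters(x$config)
  tot <- attr(rep_, "totals")
  cat(sprintf("  %d parameters (%d trainable, %d frozen)\n",
              tot["total"], tot["trainable"], tot["frozen"]))
  invisible(x)
}

dense_params <- function(n_in, n_out) n_in * n_out + n_out

#' Per-layer parameter ledger
#'
#' Accounts every parameter of the architecture under the counting rules of
#' the deployment toolchain: dense = in x out + out; conv = kernel x
#' channels x filters + filters; batch norm = 4 x features, of which the 2
#' moving statistics are never trained. The shared autoencoder is counted
#' once (its weights are identical across the six channel branches) and is
#' frozen after its own training phase, so the frozen total is the
#' autoencoder plus the batch-norm moving statistics.
#'
#' @param config A [network_config()].
#' @return A `complexity_report` data frame with columns `layer`, `type`,
#'   `output_shape`, `params`, `trainable` and attribute `totals`
#'   (`total`, `trainable`, `frozen`).
#' @examples
#' rep <- count_parameters(network_config("counts"))
#' attr(rep, "totals")  # total 14857, trainable 12477, frozen 2380
#' @export
count_parameters <- function(config) {
  if (!inherits(config, "network_config"))
    validation_error("'config' must be a network_config")
  L <- config$symbols_per_channel; C <- config$channels
  u <- config$ae_units; Fn <- config$conv_filters
  S <- config$conv_steps; Fl <- config$flatten_size
  d <- config$dense_units

  shp <- function(...) {
    d <- c(...)
    if (length(d) == 1) paste0("(", d, ",)")       # tensor-style 1-D shape
    else paste0("(", paste(d, collapse = ","), ")")
  }
  rows <- list(
    list("slice",   "Slice",              shp(L),        0L, FALSE),
    list("ae_enc",  sprintf("Dense(%d)+ReLU", u[1]), shp(u[1]),
         dense_params(L, u[1]), FALSE),
    list("ae_code", sprintf("Dense(%d)+ReLU", u[2]), shp(u[2]),
         dense_params(u[1], u[2]), FALSE),
    list("ae_dec",  sprintf("Dense(%d)+ReLU", u[3]), shp(u[3]),
         dense_params(u[2], u[3]), FALSE),
    list("ae_out",  sprintf("Dense(%d)", L), shp(L),
         dense_params(u[3], L), FALSE),
    list("concat",  "Concatenate",        shp(L, C),     0L, FALSE),
    list("bn_pre",  "BatchNormalization", shp(L, C),     4L * C, NA),
    list("conv",    "Conv1D+ReLU",        shp(S, Fn),
         config$conv_kernel * C * Fn + Fn, TRUE),
    list("flatten", "Flatten",            shp(Fl),       0L, FALSE),
    list("bn_post", "BatchNormalization", shp(Fl),       4L * Fl, NA),
    list("dense1",  sprintf("Dense(%d)+ReLU", d[1]), shp(d[1]),
         dense_params(Fl, d[1]), TRUE),
    list("drop1",   sprintf("Dropout(%.1f)", config$dropout_rate), shp(d[1]),
         0L, FALSE),
    list("dense2",  sprintf("Dense(%d)+ReLU", d[2]), shp(d[2]),
         dense_params(d[1], d[2]), TRUE),
    list("drop2",   sprintf("Dropout(%.1f)", config$dropout_rate), shp(d[2]),
         0L, FALSE),
    list("dense3",  "Dense(1)+Sigmoid",   shp(1L),
         dense_params(d[2], 1L), TRUE)
  )
  rep_ <- data.frame(
    layer = vapply(rows, `[[`, "", 1),
    type = vapply(rows, `[[`, "", 2),
    output_shape = vapply(rows, `[[`, "", 3),
    params = vapply(rows, function(r) as.integer(r[[4]]), 0L),
    trainable = vapply(rows, function(r) as.logical(r[[5]]), NA),
    stringsAsFactors = FALSE
  )
  ae_rows <- grepl("^ae_", rep_$layer)
  ae_total <- sum(rep_$params[ae_rows])
  bn_rows <- rep_$type == "BatchNormalization"
  bn_frozen <- sum(rep_$params[bn_rows]) / 2L  # moving mean + variance
  total <- sum(rep_$params)
  frozen <- ae_total + bn_frozen
  structure(rep_,
            totals = c(total = as.integer(total),
                       trainable = as.integer(total - frozen),
                       frozen = as.integer(frozen),
                       autoencoder = as.integer(ae_total)),
            class = c("complexity_report", "data.frame"))
}

#' @export
print.complexity_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  tot <- attr(x, "totals")
  if (!is.null(tot)) {
    cat(sprintf("Total params: %d\n", tot["total"]))
    if ("trainable" %in% names(tot))
      cat(sprintf("Trainable params: %d\nNon-trainable (frozen) params: %d\n",
                  tot["trainable"], tot["frozen"]))
    if ("autoencoder" %in% names(tot))
      cat(sprintf("Shared autoencoder params (counted once): %d\n",
                  tot["autoencoder"]))
  }
  invisible(x)
}

#' Per-layer multiply-accumulate (MACC) ledger
#'
#' Forward-pass complexity under the conventions of embedded NN deployment
#' tools: a dense layer costs its parameter count, an activation costs one
#' operation per unit (sigmoid is charged 10 per unit), a batch norm costs
#' 2 per normalized element, and the convolution costs
#' `steps x filters x (kernel x channels + 1)` (`macc` column). The
#' `macc_toolchain` column adds one extra accumulate per convolution filter
#' - `filters x (steps x (kernel x channels + 1) + 1)` - which is the
#' convention used by the vendor code generator this architecture targets;
#' the two columns differ only on the convolution row.
#'
#' @param config A [network_config()].
#' @return A `macc_report` data frame with columns `layer`, `type`, `macc`,
#'   `macc_toolchain`, and attribute `totals`.
#' @export
count_macc <- function(config) {
  if (!inherits(config, "network_config"))
    validation_error("'config' must be a network_config")
  L <- config$symbols_per_channel; C <- config$channels
  u <- config$ae_units; Fn <- config$conv_filters
  S <- config$conv_steps; Fl <- config$flatten_size
  d <- config$dense_units
  kC1 <- config$conv_kernel * C + 1L
  conv_nat <- S * Fn * kC1
  conv_tool <- Fn * (S * kC1 + 1L)

  rows <- list(
    list("ae_enc",    sprintf("Dense(%d)", u[1]), dense_params(L, u[1])),
    list("ae_enc_a",  "ReLU",    u[1]),
    list("ae_code",   sprintf("Dense(%d)", u[2]), dense_params(u[1], u[2])),
    list("ae_code_a", "ReLU",    u[2]),
    list("ae_dec",    sprintf("Dense(%d)", u[3]), dense_params(u[2], u[3])),
    list("ae_dec_a",  "ReLU",    u[3]),
    list("ae_out",    sprintf("Dense(%d)", L), dense_params(u[3], L)),
    list("bn_pre",    "BatchNormalization", 2L * L * C),
    list("conv",      "Conv1D+ReLU", conv_nat),
    list("bn_post",   "BatchNormalization", 2L * Fl),
    list("dense1",    sprintf("Dense(%d)", d[1]), dense_params(Fl, d[1])),
    list("dense1_a",  "ReLU",    d[1]),
    list("dense2",    sprintf("Dense(%d)", d[2]), dense_params(d[1], d[2])),
    list("dense2_a",  "ReLU",    d[2]),
    list("dense3",    "Dense(1)", dense_params(d[2], 1L)),
    list("dense3_a",  "Sigmoid", 10L)
  )
  rep_ <- data.frame(
    layer = vapply(rows, `[[`, "", 1),
    type = vapply(rows, `[[`, "", 2),
    macc = vapply(rows, function(r) as.integer(r[[3]]), 0L),
    stringsAsFactors = FALSE
  )
  rep_$macc_toolchain <- rep_$macc
  rep_$macc_toolchain[rep_$layer == "conv"] <- as.integer(conv_tool)
  ae_rows <- grepl("^ae_", rep_$layer)
  structure(rep_,
            totals = c(
              autoencoder = sum(rep_$macc[ae_rows]),
              sequential = sum(rep_$macc[!ae_rows]),
              sequential_toolchain = sum(rep_$macc_toolchain[!ae_rows]),
              total = sum(rep_$macc),
              total_toolchain = sum(rep_$macc_toolchain)),
            class = c("macc_report", "data.frame"))
}

#' @export
print.macc_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  tot <- attr(x, "totals")
  cat(sprintf("Autoencoder MACC: %d | sequential: %d (toolchain %d) | total: %d (toolchain %d)\n",
              tot["autoencoder"], tot["sequential"],
              tot["sequential_toolchain"], tot["total"],
              tot["total_toolchain"]))
  invisible(x)
}
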