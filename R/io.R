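# Plain-text serialization: tab-delimited events/decisions/reports, a
# TSV + YAML-sidecar container for recordings and symbol arrays, YAML for
# thresholds and configs, JSON for detector weights. Every writer/reader
# pair round-trips exactly.

#' Write a stimulus schedule as tab-delimited text
#'
#' Columns `onset_sample`, `code`, `is_target` (plus `selection` and
#' `repetition` when present).
#'
#' @param schedule A `stimulus_schedule` data frame.
#' @param path Output path.
#' @export
write_events <- function(schedule, path) {
  cols <- intersect(c("onset_sample", "code", "is_target",
                      "selection", "repetition"), names(schedule))
  df <- as.data.frame(schedule)[, cols, drop = FALSE]
  df$is_target <- as.integer(df$is_target)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a stimulus schedule from tab-delimited text
#'
#' @param path File with header `onset_sample`, `code`, `is_target` (extra
#'   columns are kept). Malformed rows raise a parse error naming the line.
#' @return A `stimulus_schedule` data frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("no such file: %s", path))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) parse_error(sprintf(
      "cannot parse events file %s: %s", path, conditionMessage(e))))
  need <- c("onset_sample", "code", "is_target")
  if (!all(need %in% names(df)))
    parse_error(paste("events file must have columns",
                      paste(need, collapse = ", ")))
  for (col in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      parse_error(sprintf("non-numeric '%s' at line %d", col, bad[1] + 1L))
  }
  bad <- which(df$onset_sample < 0)
  if (length(bad))
    parse_error(sprintf("negative onset_sample at line %d", bad[1] + 1L))
  df$onset_sample <- as.integer(df$onset_sample)
  df$code <- as.integer(df$code)
  df$is_target <- as.logical(as.integer(df$is_target))
  class(df) <- c("stimulus_schedule", "data.frame")
  df
}

#' Write / read a recording as TSV + YAML sidecar
#'
#' `<prefix>.tsv` holds the samples x channels matrix; `<prefix>.yaml`
#' holds `fs` and the channel labels.
#'
#' @param recording An [eeg_recording()].
#' @param prefix Path prefix (without extension).
#' @export
write_recording <- function(recording, prefix) {
  utils::write.table(
    t(recording$signal), paste0(prefix, ".tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE,
    col.names = recording$channel_labels)
  yaml::write_yaml(list(fs = recording$fs,
                        channel_labels = recording$channel_labels,
                        n_samples = n_samples(recording)),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  m <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), header = TRUE,
                                   sep = "\t"))
  sig <- t(m)
  dimnames(sig) <- NULL
  eeg_recording(sig, meta$fs, meta$channel_labels)
}

#' Write / read winsorizing thresholds as YAML
#'
#' @param thresholds A [fit_winsor()] result.
#' @param path Output path.
#' @export
write_thresholds <- function(thresholds, path) {
  yaml::write_yaml(list(p_low = as.numeric(thresholds[, 1]),
                        p_high = as.numeric(thresholds[, 2])), path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  v <- yaml::read_yaml(path)
  th <- cbind(p_low = as.numeric(v$p_low), p_high = as.numeric(v$p_high))
  structure(th, class = "winsor_thresholds")
}

#' Write / read a symbolized trial set as TSV + YAML sidecar
#'
#' Trials are rows; the `L_s x C` symbol matrix of each trial is flattened
#' symbol-fastest. The sidecar records the dimensions and LBP parameters.
#'
#' @param symbols A `symbolized_trial_set`.
#' @param prefix Path prefix.
#' @export
write_symbols <- function(symbols, prefix) {
  d <- dim(symbols)
  m <- unclass(symbols)
  attributes(m) <- list(dim = d)
  dim(m) <- c(d[1], d[2] * d[3])
  utils::write.table(m, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(n_trials = d[1], symbols_per_channel = d[2],
                        channels = d[3],
                        n = attr(symbols, "n"), step = attr(symbols, "step")),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_symbols
#' @export
read_symbols <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  m <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), header = FALSE,
                                   sep = "\t"))
  arr <- array(as.integer(m),
               dim = c(meta$n_trials, meta$symbols_per_channel,
                       meta$channels))
  structure(arr, n = meta$n, step = meta$step,
            class = "symbolized_trial_set")
}

#' Serialize / restore a trained detector as JSON
#'
#' Weights, moving statistics, normalization and configuration are stored
#' in a single self-describing JSON document (plain text).
#'
#' @param detector A `p300_detector`.
#' @param path Output path.
#' @export
write_detector <- function(detector, path) {
  ser_mat <- function(p) lapply(p, function(w) {
    if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
    else list(dim = length(w), data = as.numeric(w))
  })
  obj <- list(
    config = unclass(detector$config),
    norm = detector$norm,
    clf_params = ser_mat(detector$clf$params),
    clf_moving = detector$clf$moving,
    ae_params = if (!is.null(detector$ae)) ser_mat(detector$ae$params),
    trained = isTRUE(detector$trained)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detector
#' @export
read_detector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  deser <- function(l) lapply(l, function(w) {
    if (length(w$dim) == 2) matrix(w$data, nrow = w$dim[1], ncol = w$dim[2])
    else as.numeric(w$data)
  })
  cfg <- obj$config
  config <- network_config(
    profile = cfg$profile, channels = cfg$channels,
    symbols_per_channel = cfg$symbols_per_channel,
    ae_units = cfg$ae_units, conv_filters = cfg$conv_filters,
    conv_kernel = cfg$conv_kernel, conv_stride = cfg$conv_stride,
    dense_units = cfg$dense_units, dropout_rate = cfg$dropout_rate,
    decision_threshold = cfg$decision_threshold)
  ae <- NULL
  if (!is.null(obj$ae_params))
    ae <- structure(list(params = deser(obj$ae_params),
                         norm = obj$norm, config = config, frozen = TRUE),
                    class = "p300_autoencoder")
  clf <- list(params = deser(obj$clf_params),
              moving = lapply(obj$clf_moving, as.numeric))
  structure(list(config = config,
                 norm = lapply(obj$norm, as.numeric),
                 ae = ae, clf = clf, trained = isTRUE(obj$trained)),
            class = "p300_detector")
}

#' Export a complexity report as tab-delimited text
#'
#' Per-layer rows followed by `# total` comment lines with the totals.
#'
#' @param report A [count_parameters()] or [count_macc()] result.
#' @param path Output path.
#' @export
write_complexity <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tot <- attr(report, "totals")
  lines <- sprintf("# total\t%s\t%d", names(tot), as.integer(tot))
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Export paradigm decisions as tab-delimited text
#'
#' @param decisions Data frame with `selection`, `truth`, `prediction`,
#'   `n_rep`, `correct`.
#' @param path Output path.
#' @export
write_decisions <- function(decisions, path) {
  utils::write.table(decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
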