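# Paradigm-level decision aggregation: single-trial detector outputs are
# pooled over the repetitions of one selection, and the stimulus (or
# row/column pair) with the most positive detections wins. Tie-break
# chain: positive-label count, then summed probability, then lowest code.
# An optional probability-sum mode uses accumulated probabilities as the
# primary key instead of label counts.

#' The 6x6 speller character matrix
#'
#' Rows are flashed with codes 1-6, columns with codes 7-12; a character is
#' the intersection of the winning row and column. The default grid is the
#' classic A-Z, 1-9, underscore layout.
#'
#' @param chars Optional character vector of 36 symbols, filled row-wise.
#' @return A 6x6 character matrix of class `speller_matrix`.
#' @export
speller_matrix <- function(chars = c(LETTERS, as.character(1:9), "_")) {
  if (length(chars) != 36 || anyDuplicated(chars))
    validation_error("'chars' must be 36 distinct symbols")
  structure(matrix(chars, nrow = 6, ncol = 6, byrow = TRUE),
            class = c("speller_matrix", "matrix"))
}

# Shared scoring rule: returns the winning code among `codes`.
max_occurrence <- function(block, codes, mode = c("labels", "probs")) {
  mode <- match.arg(mode)
  sub <- block[block$code %in% codes, , drop = FALSE]
  if (nrow(sub) == 0)
    validation_error(sprintf(
      "selection block has no events for codes %s",
      paste(range(codes), collapse = "-")))
  occ <- vapply(codes, function(cd) sum(sub$label[sub$code == cd]), 0)
  psum <- vapply(codes, function(cd) sum(sub$prob[sub$code == cd]), 0)
  key1 <- if (mode == "labels") occ else psum
  ord <- order(-key1, -psum, codes)
  codes[ord[1]]
}

#' Decide the attended direction of a four-choice selection block
#'
#' The direction is the code (1-4) with the most positive single-trial
#' labels; ties are broken by the highest summed probability, then by the
#' lowest code. With no positive labels at all the summed-probability key
#' decides. `mode = "probs"` uses accumulated probabilities as the primary
#' key.
#'
#' @param block Data frame with columns `code`, `prob`, `label` covering one
#'   selection (optionally `repetition`).
#' @param mode `"labels"` (default) or `"probs"`.
#' @return The winning direction code.
#' @export
decide_direction <- function(block, mode = c("labels", "probs")) {
  if (!is.data.frame(block) || nrow(block) == 0)
    validation_error("'block' must be a non-empty data frame")
  if (!all(c("code", "prob", "label") %in% names(block)))
    validation_error("'block' needs columns code, prob, label")
  max_occurrence(block, sort(unique(block$code)), match.arg(mode))
}

#' Decide the attended character of a speller selection block
#'
#' The winning row (codes 1-6) and winning column (codes 7-12) are decided
#' independently by the maximum-occurrence rule; the character is their
#' intersection in the speller matrix.
#'
#' @param block Data frame with `code`, `prob`, `label` for one character
#'   epoch.
#' @param matrix A [speller_matrix()].
#' @param mode `"labels"` (default) or `"probs"`.
#' @return Single character.
#' @export
decide_character <- function(block, matrix = speller_matrix(),
                             mode = c("labels", "probs")) {
  mode <- match.arg(mode)
  if (!is.data.frame(block) || nrow(block) == 0)
    validation_error("'block' must be a non-empty data frame")
  if (!any(block$code %in% 1:6) || !any(block$code %in% 7:12))
    validation_error("speller block must contain both row and column events")
  row <- max_occurrence(block, 1:6, mode)
  col <- max_occurrence(block, 7:12, mode)
  matrix[row, col - 6L]
}

#' Selection accuracy as a function of the number of repetitions
#'
#' For each `r` in `1..n_rep_max` the paradigm decision of every selection
#' is recomputed from scratch using only its first `r` repetitions, and
#' compared against the ground truth.
#'
#' @param predictions Data frame with one row per event: `code`, `prob`,
#'   `label`, `selection`, `repetition` (e.g. the schedule joined with
#'   [predict.p300_detector()] output).
#' @param truth The session ground truth from [generate_session()], or a
#'   vector of attended codes (four-choice) / characters (speller).
#' @param paradigm `"four_choice"` or `"speller6x6"`.
#' @param n_rep_max Largest repetition count to evaluate.
#' @param matrix [speller_matrix()] used for character decisions.
#' @param mode Decision mode, see [decide_direction()].
#' @return Data frame with columns `n_rep` and `accuracy`.
#' @export
accuracy_vs_repetitions <- function(predictions, truth,
                                    paradigm = c("four_choice", "speller6x6"),
                                    n_rep_max = NULL,
                                    matrix = speller_matrix(),
                                    mode = c("labels", "probs")) {
  paradigm <- match.arg(paradigm)
  mode <- match.arg(mode)
  need <- c("code", "prob", "label", "selection", "repetition")
  if (!all(need %in% names(predictions)))
    validation_error(paste("'predictions' needs columns",
                           paste(need, collapse = ", ")))
  avail <- max(predictions$repetition)
  if (is.null(n_rep_max)) n_rep_max <- avail
  if (n_rep_max > avail)
    validation_error(sprintf(
      "n_rep_max = %d exceeds the %d available repetitions",
      n_rep_max, avail))

  attended <- truth_attended_vector(truth, paradigm, matrix)
  sels <- sort(unique(predictions$selection))
  if (length(attended) != length(sels))
    alignment_error("truth does not cover every selection")

  acc <- vapply(seq_len(n_rep_max), function(r) {
    sub <- predictions[predictions$repetition <= r, , drop = FALSE]
    dec <- vapply(sels, function(s) {
      blk <- sub[sub$selection == s, , drop = FALSE]
      if (paradigm == "four_choice")
        as.character(decide_direction(blk, mode))
      else
        decide_character(blk, matrix, mode)
    }, "")
    mean(dec == as.character(attended))
  }, 0)
  data.frame(n_rep = seq_len(n_rep_max), accuracy = acc)
}

truth_attended_vector <- function(truth, paradigm, matrix) {
  if (inherits(truth, "ground_truth")) {
    if (truth$paradigm != paradigm)
      validation_error(sprintf(
        "truth is for paradigm '%s', not '%s'", truth$paradigm, paradigm))
    att <- truth$attended
    if (paradigm == "speller6x6") return(att$char)
    return(att)
  }
  if (is.data.frame(truth)) {
    if ("char" %in% names(truth)) return(truth$char)
    return(matrix[cbind(truth$row, truth$col - 6L)])
  }
  truth
}
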