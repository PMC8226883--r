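# Paradigm-level decision aggregation.

blk <- function(code, prob, label, repetition = 1L) {
  data.frame(code = code, prob = prob, label = label,
             repetition = repetition)
}

test_that("direction decisions follow occurrence with the documented tie-breaks", {
  b <- blk(code = c(1, 2, 3, 4), prob = c(0.1, 0.9, 0.2, 0.1),
           label = c(0, 1, 0, 0))
  expect_equal(decide_direction(b), 2)

  ties <- blk(code = rep(1:4, 2),
              prob = c(0.9, 0.1, 0.9, 0.2, 0.8, 0.1, 1.0, 0.1),
              label = c(1, 0, 1, 0, 1, 0, 1, 0))
  # codes 1 and 3: two positives each; summed prob 1.7 vs 1.9 -> 3 wins
  expect_equal(decide_direction(ties), 3)

  none <- blk(code = 1:4, prob = c(0.2, 0.4, 0.35, 0.1), label = rep(0, 4))
  expect_equal(decide_direction(none), 2)   # fallback: highest summed prob

  full_tie <- blk(code = 1:4, prob = rep(0.2, 4), label = rep(0, 4))
  expect_equal(decide_direction(full_tie), 1)  # final tie-break: lowest code

  expect_error(decide_direction(data.frame()),
               class = "p300lbp_validation_error")
})

test_that("probability mode uses accumulated probabilities as the primary key", {
  b <- blk(code = rep(1:4, 2),
           prob = c(0.6, 0.45, 0.1, 0.1, 0.55, 0.49, 0.1, 0.1),
           label = c(1, 0, 0, 0, 1, 0, 0, 0))
  expect_equal(decide_direction(b, mode = "labels"), 1)
  expect_equal(decide_direction(b, mode = "probs"), 1)
  b2 <- blk(code = c(1, 2), prob = c(0.51, 0.95), label = c(1, 1))
  expect_equal(decide_direction(b2, mode = "probs"), 2)
})

test_that("character decisions intersect the winning row and column", {
  m <- speller_matrix()
  b <- blk(code = 1:12, prob = c(0, 0, 0.9, 0, 0, 0, 0, 0, 0.8, 0, 0, 0),
           label = c(0, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0))
  expect_equal(decide_character(b, m), m[3, 9 - 6])

  # perfect oracle over many repetitions always recovers the target
  reps <- do.call(rbind, lapply(1:15, function(r)
    blk(code = 1:12, prob = as.numeric(1:12 %in% c(4, 10)),
        label = as.integer(1:12 %in% c(4, 10)), repetition = r)))
  expect_equal(decide_character(reps, m), m[4, 4])

  # marginal probabilities only epsilon above 0.5 still accumulate correctly
  marg <- do.call(rbind, lapply(1:15, function(r)
    blk(code = 1:12,
        prob = ifelse(1:12 %in% c(2, 8), 0.5 + 1e-6, 0.4),
        label = as.integer(1:12 %in% c(2, 8)), repetition = r)))
  expect_equal(decide_character(marg, m), m[2, 2])

  rows_only <- blk(code = 1:6, prob = rep(0.6, 6), label = rep(1, 6))
  expect_error(decide_character(rows_only, m),
               class = "p300lbp_validation_error")
})

test_that("the speller matrix is a bijection between row/column pairs and 36 symbols", {
  m <- speller_matrix()
  expect_equal(dim(unclass(m)), c(6L, 6L))
  expect_equal(anyDuplicated(as.character(m)), 0L)
  expect_error(speller_matrix(rep("A", 36)),
               class = "p300lbp_validation_error")
})

test_that("accuracy per repetition count is recomputed from scratch for each r", {
  ses <- generate_session(session_spec("speller6x6", n_repetitions = 5,
                                       n_selections = 8, snr = 0, seed = 55))
  sch <- ses$schedule
  # perfect oracle outputs
  preds <- cbind(as.data.frame(sch),
                 prob = as.numeric(sch$is_target),
                 label = as.integer(sch$is_target))
  acc <- accuracy_vs_repetitions(preds, ses$truth, "speller6x6")
  expect_equal(acc$accuracy, rep(1, 5))
  expect_equal(acc$n_rep, 1:5)

  expect_error(accuracy_vs_repetitions(preds, ses$truth, "speller6x6",
                                       n_rep_max = 6),
               class = "p300lbp_validation_error")
})

test_that("a chance-level detector recognizes speller characters at about 1/36", {
  with_seed(99, {
    n_sel <- 400
    truth_chars <- character(n_sel)
    correct <- logical(n_sel)
    m <- speller_matrix()
    for (s in seq_len(n_sel)) {
      row_t <- sample(1:6, 1); col_t <- sample(7:12, 1)
      truth_chars[s] <- m[row_t, col_t - 6]
      b <- blk(code = 1:12, prob = stats::runif(12),
               label = as.integer(stats::runif(12) < 0.25))
      correct[s] <- decide_character(b, m) == truth_chars[s]
    }
    expect_lt(abs(mean(correct) - 1 / 36), 3 * sqrt((1/36) * (35/36) / n_sel))
  })
})

test_that("four-choice accuracy improves with repetitions for a noisy detector", {
  ses <- generate_session(session_spec("four_choice", n_repetitions = 6,
                                       n_selections = 50, snr = 0, seed = 77))
  sch <- ses$schedule
  with_seed(3, {
    hit <- stats::runif(nrow(sch))
    prob <- ifelse(sch$is_target,
                   ifelse(hit < 0.6, 0.8, 0.2),
                   ifelse(hit < 0.1, 0.8, 0.2))
    preds <- cbind(as.data.frame(sch), prob = prob,
                   label = as.integer(prob > 0.5))
    acc <- accuracy_vs_repetitions(preds, ses$truth, "four_choice")
    expect_gt(acc$accuracy[6], acc$accuracy[1] - 0.05)
    expect_gt(acc$accuracy[6], 0.8)
  })
})
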