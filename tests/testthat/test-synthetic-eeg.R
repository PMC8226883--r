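# Synthetic odd-ball session generator: schedule structure, target ratios,
# determinism, and the statistical properties of the injected ERP.

test_that("schedules have the exact event and target counts of each paradigm", {
  ses <- generate_session(session_spec("four_choice", n_repetitions = 2,
                                       n_selections = 10, seed = 1))
  expect_equal(nrow(ses$schedule), 80)
  expect_equal(unname(event_counts(ses$schedule, ses$truth)), c(20L, 60L))

  sp <- generate_session(session_spec("speller6x6", n_repetitions = 15,
                                      n_selections = 1, seed = 2))
  expect_equal(nrow(sp$schedule), 180)
  expect_equal(unname(event_counts(sp$schedule, sp$truth)), c(30L, 150L))
})

test_that("target:non-target ratio is 1:3 (four-choice) and 1:5 (speller) for any size", {
  for (reps in c(1L, 3L)) {
    for (sels in c(1L, 4L)) {
      fc <- generate_session(session_spec("four_choice", n_repetitions = reps,
                                          n_selections = sels, seed = reps * 10 + sels))
      ec <- event_counts(fc$schedule)
      expect_equal(unname(ec["n_nontarget"] / ec["n_target"]), 3)
      sp <- generate_session(session_spec("speller6x6", n_repetitions = reps,
                                          n_selections = sels, seed = reps * 10 + sels))
      ec <- event_counts(sp$schedule)
      expect_equal(unname(ec["n_nontarget"] / ec["n_target"]), 5)
    }
  }
})

test_that("speller truth flags exactly one row and one column code per repetition", {
  sp <- generate_session(session_spec("speller6x6", n_repetitions = 3,
                                      n_selections = 5, seed = 9))
  sch <- sp$schedule
  for (s in unique(sch$selection)) {
    for (r in unique(sch$repetition)) {
      blk <- sch[sch$selection == s & sch$repetition == r, ]
      tgt <- blk$code[blk$is_target]
      expect_length(tgt, 2)
      expect_true(any(tgt <= 6) && any(tgt >= 7))
    }
  }
})

test_that("a fixed seed regenerates the session bit-identically", {
  spec <- session_spec("four_choice", n_repetitions = 2, n_selections = 5,
                       snr = 1.5, artifact_rate = 0.1, seed = 77)
  a <- generate_session(spec)
  b <- generate_session(spec)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$schedule, b$schedule)
  expect_identical(a$truth, b$truth)
  c <- generate_session(session_spec("four_choice", n_repetitions = 2,
                                     n_selections = 5, snr = 1.5,
                                     artifact_rate = 0.1, seed = 78))
  expect_false(identical(a$recording$signal, c$recording$signal))
})

test_that("invalid specs raise validation errors naming the field", {
  expect_error(session_spec("four_choice", fs = -1), "fs",
               class = "p300lbp_validation_error")
  expect_error(session_spec("four_choice", snr = -0.1), "snr",
               class = "p300lbp_validation_error")
  expect_error(session_spec("four_choice", artifact_rate = 1.5),
               "artifact_rate", class = "p300lbp_validation_error")
  expect_error(session_spec("four_choice", flash_duration = 0.3, isi = 0.2),
               "flash_duration", class = "p300lbp_validation_error")
  expect_error(session_spec("four_choice", spatial_weights = c(1, 2)),
               "spatial_weights", class = "p300lbp_validation_error")
})

test_that("at snr = 0 target and non-target trials are statistically indistinguishable", {
  ses <- generate_session(session_spec("four_choice", n_repetitions = 2,
                                       n_selections = 25, snr = 0,
                                       artifact_rate = 0, seed = 101))
  trials <- extract_trials(ses$recording, ses$schedule)
  y <- ses$schedule$is_target
  post <- apply(unclass(trials)[, , 6], 1, mean)  # mean post-stimulus amplitude
  p <- stats::t.test(post[y], post[!y])$p.value
  expect_gt(p, 0.01)
})

test_that("the target/non-target mean difference at the peak matches the injected amplitude", {
  snr <- 2; sigma <- 10
  ses <- generate_session(session_spec("four_choice", n_repetitions = 2,
                                       n_selections = 125, snr = snr,
                                       noise_sigma = sigma,
                                       artifact_rate = 0, seed = 6))
  trials <- unclass(extract_trials(ses$recording, ses$schedule))
  y <- ses$schedule$is_target
  peak_i <- round(0.25 * 240)  # 0.35 s post onset; window starts at 0.1 s
  for (ch in c(4L, 6L)) {       # full-weight (parietal-like) channels
    d <- mean(trials[y, peak_i, ch]) - mean(trials[!y, peak_i, ch])
    se <- sqrt(stats::var(trials[y, peak_i, ch]) / sum(y) +
                 stats::var(trials[!y, peak_i, ch]) / sum(!y))
    expect_lt(abs(d - snr * sigma), 3 * se)
  }
})

test_that("artifact injection produces excursions of at least 5 noise SD", {
  clean <- generate_session(session_spec("four_choice", n_repetitions = 2,
                                         n_selections = 25, snr = 0,
                                         artifact_rate = 0, seed = 13))
  arty <- generate_session(session_spec("four_choice", n_repetitions = 2,
                                        n_selections = 25, snr = 0,
                                        artifact_rate = 1, seed = 13))
  expect_lt(max(abs(clean$recording$signal)), 5 * 10 * 1.3)
  expect_gt(max(abs(arty$recording$signal)), 5 * 10)
  n_big <- sum(apply(abs(unclass(
    extract_trials(arty$recording, arty$schedule))) > 50, 1, any))
  expect_gt(n_big, 50)  # most of the 100 trials carry an excursion
})

test_that("event_counts validates schedule/truth alignment", {
  ses <- small_session()
  expect_equal(sum(event_counts(ses$schedule)), nrow(ses$schedule))
  bad <- ses$truth
  bad$is_target <- bad$is_target[-1]
  expect_error(event_counts(ses$schedule, bad),
               class = "p300lbp_alignment_error")
  empty <- ses$schedule[0, ]
  expect_equal(unname(event_counts(empty)), c(0L, 0L))
})
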