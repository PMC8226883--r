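# Preprocessing chain: band-pass, resampling, epoching, baseline
# correction, winsorizing, and the 1D-LBP symbolizer.

test_that("band-pass rejects the stop band and preserves the pass band", {
  t <- (0:4799) / 240
  rec50 <- vec_recording(sin(2 * pi * 50 * t))
  out50 <- eeg_bandpass(rec50, 0.1, 20, 8)
  expect_lt(stats::sd(out50$signal), 0.05 * stats::sd(rec50$signal))

  rec5 <- vec_recording(sin(2 * pi * 5 * t))
  out5 <- eeg_bandpass(rec5, 0.1, 20, 8)
  expect_gt(stats::sd(out5$signal), 0.9 * stats::sd(rec5$signal))
  expect_lt(stats::sd(out5$signal), 1.1 * stats::sd(rec5$signal))

  dc <- vec_recording(rep(3, 4800))
  outdc <- eeg_bandpass(dc, 0.1, 20, 8)
  expect_lt(mean(abs(outdc$signal)), 0.5)

  expect_error(eeg_bandpass(rec5, 20, 0.1), class = "p300lbp_validation_error")
  expect_error(eeg_bandpass(rec5, 0.1, 200), class = "p300lbp_validation_error")
})

test_that("resampling 250 -> 240 preserves constants, tones and duration", {
  const <- vec_recording(rep(3.7, 250), fs = 250)
  out <- resample_to_240(const)
  expect_equal(out$fs, 240)
  expect_equal(ncol(out$signal), 240)
  expect_equal(as.numeric(out$signal), rep(3.7, 240), tolerance = 1e-9)

  t <- (0:2499) / 250
  tone <- vec_recording(sin(2 * pi * 2 * t), fs = 250)
  res <- resample_to_240(tone)
  ref <- sin(2 * pi * 2 * (seq_len(ncol(res$signal)) - 1) / 240)
  expect_gte(stats::cor(as.numeric(res$signal), ref), 0.999)
  expect_lt(abs(ncol(res$signal) / 240 - ncol(tone$signal) / 250), 1 / 240)

  already <- vec_recording(stats::rnorm(480), fs = 240)
  expect_identical(resample_to_240(already), already)
  expect_error(resample_to_240(vec_recording(stats::rnorm(100), fs = 100)),
               class = "p300lbp_validation_error")
})

test_that("trial extraction returns the half-open default window of 168 samples", {
  ramp <- vec_recording(seq_len(480) - 1)   # s[i] = i (0-based value)
  tr <- extract_trial(ramp, onset_sample = 0)
  expect_equal(ncol(tr), 168)
  expect_equal(as.numeric(tr), 24:191)      # samples 24..191 inclusive
  tr2 <- extract_trial(ramp, onset_sample = 100)
  expect_equal(as.numeric(tr2), 124:291)
  expect_error(extract_trial(ramp, onset_sample = 480 - 100),
               "onset", class = "p300lbp_bounds_error")
})

test_that("baseline correction zeroes the mean of the first 12 samples per channel", {
  const <- matrix(7, nrow = 2, ncol = 168)
  expect_equal(baseline_correct(const), matrix(0, 2, 168))

  step <- matrix(12, nrow = 1, ncol = 168)
  step[1, 1:12] <- 10
  out <- baseline_correct(step)
  expect_equal(as.numeric(out[1, 1:12]), rep(0, 12))
  expect_equal(as.numeric(out[1, 13:168]), rep(2, 156))

  set.seed(3)
  rnd <- matrix(stats::rnorm(3 * 168), nrow = 3)
  out <- baseline_correct(rnd)
  expect_equal(rowMeans(out[, 1:12]), rep(0, 3), tolerance = 1e-12)
  expect_error(baseline_correct(rnd, baseline_len = 0),
               class = "p300lbp_validation_error")
})

test_that("winsor thresholds match a brute-force linear-interpolation percentile oracle", {
  grid <- matrix(1:1000, nrow = 1)          # one channel, uniform grid
  th <- suppressWarnings(fit_winsor(grid))
  # oracle: sort + linear interpolation between order statistics
  oracle <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h); x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(unname(th[1, "p_low"]), oracle(1:1000, 0.01))
  expect_equal(unname(th[1, "p_high"]), oracle(1:1000, 0.99))
  expect_equal(unname(th[1, ]), c(10.99, 990.01))

  const <- matrix(5, nrow = 1, ncol = 200)
  thc <- fit_winsor(const)
  expect_equal(unname(thc[1, ]), c(5, 5))

  sym <- matrix(c(-(1:500), 1:500), nrow = 1)
  ths <- fit_winsor(sym)
  expect_equal(unname(ths[1, "p_low"]), -unname(ths[1, "p_high"]))

  set.seed(8)
  x <- matrix(stats::rnorm(5000), nrow = 1)
  thr <- fit_winsor(x)
  expect_gte(mean(x >= thr[1, 1] & x <= thr[1, 2]), 0.98)
  expect_error(fit_winsor(array(0, dim = c(0, 10, 1))),
               class = "p300lbp_validation_error")
})

test_that("winsorizing clips to thresholds, leaves in-range samples, and is idempotent", {
  th <- structure(cbind(p_low = -1, p_high = 1), class = "winsor_thresholds")
  tr <- matrix(c(-5, -1, 0, 0.5, 1, 5), nrow = 1)
  out <- apply_winsor(tr, th)
  expect_equal(as.numeric(out), c(-1, -1, 0, 0.5, 1, 1))
  inside <- matrix(c(-0.9, 0, 0.9), nrow = 1)
  expect_equal(apply_winsor(inside, th), inside)
  expect_equal(apply_winsor(out, th), out)
  two_ch <- matrix(0, nrow = 2, ncol = 4)
  expect_error(apply_winsor(two_ch, th), class = "p300lbp_alignment_error")
})

test_that("LBP symbolization matches hand-enumerated patterns", {
  ramp <- matrix(1:168, nrow = 1)
  s <- symbolize_lbp(ramp)
  expect_equal(nrow(s), 54)
  expect_true(all(s == 8))

  const <- matrix(0, nrow = 1, ncol = 168)
  expect_true(all(symbolize_lbp(const) == 0))
  down <- matrix(168:1, nrow = 1)
  expect_true(all(symbolize_lbp(down) == 0))

  # alternating a,b,a,b,... with a < b: onset on a sees 4 larger samples in
  # the next 8, onset on b sees none; onsets step by 3 so parity alternates
  alt <- matrix(rep(c(0, 1), 84), nrow = 1)
  expect_equal(as.integer(symbolize_lbp(alt)),
               rep(c(4L, 0L), 27))
})

test_that("LBP output length follows floor((T - n - 1)/step) + 1 and stays in 0..8", {
  for (T_len in c(100L, 127L, 168L, 174L, 255L, 300L)) {
    x <- matrix(stats::rnorm(T_len), nrow = 1)
    s <- symbolize_lbp(x)
    expect_equal(nrow(s), floor((T_len - 8 - 1) / 3) + 1)
    expect_true(all(s >= 0 & s <= 8))
  }
  expect_equal(lbp_length(168), 54L)
  expect_equal(lbp_length(174), 56L)
  expect_error(symbolize_lbp(matrix(1:5, nrow = 1)),
               class = "p300lbp_validation_error")
})

test_that("LBP is invariant under strictly increasing monotone transforms", {
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(stats::rnorm(168), nrow = 1)
    base <- symbolize_lbp(x)
    expect_equal(symbolize_lbp(2.5 * x + 17), base)     # positive affine
    expect_equal(symbolize_lbp(exp(x)), base)           # nonlinear monotone
    expect_equal(symbolize_lbp(x^3), base)
  }
})

test_that("the pipeline preserves trial count and is invariant to offset and scale", {
  ses <- small_session()
  pp <- preprocess_pipeline(ses$recording, ses$schedule)
  expect_equal(dim(pp$symbols), c(80, 54, 6))
  expect_true(all(pp$symbols >= 0 & pp$symbols <= 8))

  shifted <- ses$recording
  shifted$signal <- shifted$signal + 123.4
  pp2 <- preprocess_pipeline(shifted, ses$schedule)
  expect_equal(unclass(pp2$symbols), unclass(pp$symbols))

  scaled <- ses$recording
  scaled$signal <- scaled$signal * 3.7    # thresholds refitted on scaled data
  pp3 <- preprocess_pipeline(scaled, ses$schedule)
  expect_equal(unclass(pp3$symbols), unclass(pp$symbols))

  pp4 <- preprocess_pipeline(ses$recording, ses$schedule)
  expect_identical(unclass(pp4$symbols), unclass(pp$symbols))  # determinism
})

test_that("test data are winsorized with training thresholds, not their own", {
  ses <- small_session()
  tr_half <- ses$schedule[1:40, ]
  te_half <- ses$schedule[41:80, ]
  fit <- preprocess_pipeline(ses$recording, tr_half)
  te <- preprocess_pipeline(ses$recording, te_half, thresholds = fit$thresholds)
  expect_equal(dim(te$symbols)[1], 40)
  expect_identical(te$thresholds, fit$thresholds)
})
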