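# Architecture configuration, the parameter/MACC ledgers, and the
# structural contracts of the built detector.

test_that("the counts-profile parameter ledger reproduces every published figure", {
  rep_ <- count_parameters(network_config("counts"))
  by_layer <- stats::setNames(rep_$params, rep_$layer)
  expect_equal(unname(by_layer[c("ae_enc", "ae_code", "ae_dec", "ae_out")]),
               c(912L, 136L, 144L, 952L))
  expect_equal(unname(by_layer[c("bn_pre", "conv", "bn_post",
                                 "dense1", "dense2", "dense3")]),
               c(24L, 784L, 448L, 7232L, 4160L, 65L))
  tot <- attr(rep_, "totals")
  expect_equal(unname(tot["autoencoder"]), 2144L)
  expect_equal(unname(tot["total"]), 14857L)
  expect_equal(unname(tot["trainable"]), 12477L)
  expect_equal(unname(tot["frozen"]), 2380L)
})

test_that("the shapes profile reproduces the published tensor shapes", {
  cfg <- network_config("shapes")
  expect_equal(cfg$symbols_per_channel, 54L)
  expect_equal(cfg$conv_steps, 6L)
  expect_equal(cfg$flatten_size, 96L)
  rep_ <- count_parameters(cfg)
  shp <- stats::setNames(rep_$output_shape, rep_$layer)
  expect_equal(unname(shp["concat"]), "(54,6)")
  expect_equal(unname(shp["conv"]), "(6,16)")
  expect_equal(unname(shp["flatten"]), "(96,)")
  # same counting rules at L_s = 54
  tot <- attr(rep_, "totals")
  expect_equal(unname(tot["autoencoder"]), 880L + 136L + 144L + 918L)
})

test_that("counts-profile conv geometry differs as the input length dictates", {
  cfg <- network_config("counts")
  expect_equal(cfg$symbols_per_channel, 56L)
  expect_equal(cfg$conv_steps, 7L)       # floor((56 - 8)/8) + 1
  expect_equal(cfg$flatten_size, 112L)
  expect_equal(profile_window(cfg), c(0.1, 0.825))
  expect_equal(profile_window(network_config("shapes")), c(0.1, 0.8))
})

test_that("the ledger counts exactly the weights a built detector carries", {
  for (profile in c("shapes", "counts")) {
    cfg <- network_config(profile)
    det <- build_detector(cfg, seed = 1)
    actual_ae <- sum(vapply(det$ae$params, length, 0L))
    actual_clf <- sum(vapply(det$clf$params, length, 0L)) +
      sum(vapply(det$clf$moving, length, 0L))
    tot <- attr(count_parameters(cfg), "totals")
    expect_equal(actual_ae, unname(tot["autoencoder"]))
    expect_equal(actual_ae + actual_clf, unname(tot["total"]))
  }
})

test_that("parameter and MACC totals strictly increase with the input length", {
  totals <- vapply(c(50L, 54L, 56L, 60L), function(L) {
    cfg <- network_config(symbols_per_channel = L)
    c(attr(count_parameters(cfg), "totals")["total"],
      attr(count_macc(cfg), "totals")["total"])
  }, c(total = 0, total.total = 0))
  expect_true(all(diff(totals[1, ]) > 0))
  expect_true(all(diff(totals[2, ]) > 0))
})

test_that("the MACC ledger follows the documented conventions", {
  mr <- count_macc(network_config("counts"))
  by_layer <- stats::setNames(mr$macc, mr$layer)
  expect_equal(unname(by_layer["ae_enc"]), 912L)      # dense = param count
  expect_equal(unname(by_layer["ae_enc_a"]), 16L)     # ReLU = unit count
  expect_equal(unname(by_layer["bn_pre"]), 672L)      # 2 x elements
  expect_equal(unname(by_layer["bn_post"]), 224L)
  expect_equal(unname(by_layer["conv"]), 5488L)       # 7 x 16 x 49
  tool <- stats::setNames(mr$macc_toolchain, mr$layer)
  expect_equal(unname(tool["conv"]), 5504L)           # 16 x (7 x 49 + 1)
  expect_equal(mr$macc[mr$layer != "conv"],
               mr$macc_toolchain[mr$layer != "conv"])
  tot <- attr(mr, "totals")
  expect_equal(unname(tot["autoencoder"]), 2184L)
  expect_equal(unname(tot["sequential_toolchain"]), 17995L)
  expect_equal(unname(tot["total_toolchain"]), 20179L)
})

test_that("config validation rejects inconsistent geometry", {
  expect_error(network_config(symbols_per_channel = 4),
               class = "p300lbp_validation_error")
  expect_error(network_config(dense_units = c(64, 64, 2)),
               class = "p300lbp_validation_error")
  expect_error(network_config(dropout_rate = 1.5),
               class = "p300lbp_validation_error")
})

test_that("a forward pass on zeros yields probabilities in [0, 1]", {
  det <- build_detector(network_config("shapes"), seed = 9)
  zeros <- structure(array(0L, dim = c(3, 54, 6)),
                     class = "symbolized_trial_set")
  p <- predict(det, zeros)
  expect_true(all(p$prob >= 0 & p$prob <= 1))
  bad <- structure(array(0L, dim = c(3, 40, 6)),
                   class = "symbolized_trial_set")
  expect_error(predict(det, bad), class = "p300lbp_validation_error")
})

test_that("weight initialization is reproducible under a fixed seed", {
  a <- build_detector(network_config("shapes"), seed = 123)
  b <- build_detector(network_config("shapes"), seed = 123)
  expect_identical(a$clf$params, b$clf$params)
  expect_identical(a$ae$params, b$ae$params)
})
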