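test_that("rectification is absolute value and idempotent", {
  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_equal(rectify(c(0.5, 2)), c(0.5, 2))
  x <- rnorm(100)
  expect_equal(rectify(rectify(x)), rectify(x))
  expect_error(rectify(c(1, NA)), "non-finite")
})

test_that("well-separated bursts give one epoch each, flat signals none", {
  fs <- 2000
  n <- 10 * fs
  env <- rep(0.02, n)
  for (c0 in c(1, 3, 5, 7, 9) * fs) env[c0:(c0 + 300)] <- 1
  set.seed(2)
  x <- abs(env * rnorm(n)); y <- abs(env * rnorm(n))
  ep <- extract_epochs(x, y, fs)
  expect_equal(ep$n_epochs, 5L)
  expect_equal(length(ep$x), length(ep$y))

  expect_error(extract_epochs(rep(1e-6, n), rep(1e-6, n), fs),
               "no supra-threshold", class = "mn_no_epochs")
})

test_that("coherence is 1 for identical inputs and small under independence", {
  set.seed(1)
  x <- rnorm(8000)
  sp <- ms_coherence(x, x, 2000)
  expect_true(all(sp$msc[sp$freq < 900] > 0.999))

  x <- rnorm(120000); y <- rnorm(120000)
  sp <- ms_coherence(x, y, 2000)
  expect_equal(mean(sp$msc), 1 / sp$l_hat, tolerance = 0.5)
})

test_that("a shared 20 Hz component at 0 dB SNR dominates its bin", {
  set.seed(3)
  t <- seq_len(60000) / 2000
  s <- sqrt(2) * sin(2 * pi * 20 * t)
  sp <- ms_coherence(s + rnorm(60000), s + rnorm(60000), 2000)
  expect_gt(sp$msc[which.min(abs(sp$freq - 20))], 0.8)
})

test_that("significance level matches its closed form and decreases in L", {
  expect_equal(significance_level(2), 0.95)
  expect_equal(significance_level(20), 1 - 0.05^(1 / 19))
  expect_equal(significance_level(20), 0.1459, tolerance = 1e-3)
  expect_lt(significance_level(40), significance_level(20))
  expect_error(significance_level(1), "at least 2")
})

test_that("band weights gate on significance then Fisher-z the band mean", {
  spec <- structure(
    list(freq = seq(0, 1000, by = 2000 / 4096), msc = NULL, l_hat = 10,
         significance = NULL, fs = 2000),
    class = "coherence_spectrum"
  )
  spec$msc <- rep(0.5, length(spec$freq))
  spec$significance <- 0.1
  expect_equal(band_weight(spec, "beta"), atanh(sqrt(0.5)))
  expect_equal(band_weight(spec, "beta"), 0.8814, tolerance = 1e-4)
  # uniform msc: weight invariant to band width
  expect_equal(band_weight(spec, "theta.alpha"), band_weight(spec, "gamma"))

  spec$msc <- rep(0.01, length(spec$freq))
  spec$significance <- 0.15
  expect_equal(band_weight(spec, "beta"), 0)

  spec$msc <- rep(0.5, length(spec$freq))
  expect_error(band_weight(spec, c(900, 1200)), "fs/2")
})

test_that("multiplex weights are complete, symmetric in input order and scale-invariant", {
  rec <- preprocess_semg(simulate_semg(effect_profile(), 4, seed = 21))
  net <- multiplex_weights(rec)
  expect_equal(nrow(net$edge_table), 45L)
  expect_true(all(net$edge_table$weight >= 0, na.rm = TRUE))
  for (b in names(MN_BANDS)) {
    expect_true(isSymmetric(net$layers[[b]]))
  }

  # swapping the two inputs of a pair gives the identical weight
  x <- abs(rec$samples[1, ]); y <- abs(rec$samples[4, ])
  ep <- extract_epochs(x, y, rec$fs)
  sp_xy <- ms_coherence(ep$x, ep$y, rec$fs, blocks = ep$blocks)
  sp_yx <- ms_coherence(ep$y, ep$x, rec$fs, blocks = ep$blocks)
  expect_equal(band_weight(sp_xy, "beta"), band_weight(sp_yx, "beta"))

  # multiplying one channel by a positive constant changes nothing
  scaled <- rec
  scaled$samples[3, ] <- 4.2 * scaled$samples[3, ]
  net2 <- multiplex_weights(scaled)
  expect_equal(net2$edge_table$weight, net$edge_table$weight, tolerance = 1e-8)
})

test_that("gate keeps zeroed bands zero after the Fisher transform", {
  rec <- preprocess_semg(simulate_semg(effect_profile(coupling_scale = 0),
                                       4, seed = 31))
  net <- multiplex_weights(rec)
  w <- net$edge_table$weight
  expect_true(all(w[!is.na(w)] >= 0))
  expect_true(any(w == 0, na.rm = TRUE))
})
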