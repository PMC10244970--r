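test_that("log-spaced banks hit exact geometric steps and start unadapted", {
  b <- build_channel_bank(9, 100, 25600)
  expect_equal(b$widths_ms, 100 * 2^(0:8), tolerance = 1e-12)
  expect_true(all(b$gains == 1))
  b61 <- build_channel_bank()
  ratios <- b61$widths_ms[-1] / b61$widths_ms[-61]
  expect_equal(max(ratios) / min(ratios), 1, tolerance = 1e-12)
  expect_error(build_channel_bank(5), "at least 8")
  expect_error(build_channel_bank(min_width_ms = 500, max_width_ms = 100), "<")
  expect_error(build_channel_bank(transducer = list(p = 2, q = 2.5)), "p > q")
  expect_error(build_channel_bank(transducer = list(z = 0)), "positive")
})

test_that("rectangular-window drives integrate a box against a box", {
  b <- build_channel_bank(9, 100, 25600, window_shape = "rect")
  sig <- rep(1, 800) # constant unit drive for 800 ms at 1 kHz
  L <- channel_drive(sig, b, sample_rate = 1000)
  expect_equal(L, pmin(b$widths_ms, 800) / 1000, tolerance = 0.01)
  # nested windows: non-decreasing in width for any non-negative signal
  rnd <- with_seed_local(5, stats::runif(1200))
  Lr <- channel_drive(rnd, b, sample_rate = 1000)
  expect_true(all(diff(Lr) >= -1e-12))
  # empty/zero signals
  expect_equal(channel_drive(numeric(0), b, sample_rate = 1000), rep(0, 9))
  expect_equal(channel_drive(rep(0, 500), b, sample_rate = 1000), rep(0, 9))
})

test_that("transduction obeys its limit cases", {
  b <- build_channel_bank(12, 50, 4000)
  expect_equal(transduce(rep(0, 12), b)$R, rep(0, 12))
  # with a huge saturation constant, suppression is negligible and R ~ L^p
  b_hi <- build_channel_bank(12, 50, 4000, transducer = list(z = 1e12))
  L <- seq(0.5, 6, length.out = 12)
  R <- transduce(L, b_hi)$R
  expect_equal(R / R[1], (L / L[1])^2.4, tolerance = 1e-6)
  expect_error(transduce(c(-1, rep(1, 11)), b), "non-negative")
})

test_that("derivative readout finds a logistic's centre within 2%", {
  b <- build_channel_bank()
  lw <- log(b$widths_ms)
  R <- 1 / (1 + exp(-(lw - log(800)) / 0.3))
  pop <- structure(list(R = R, widths_ms = b$widths_ms, stimulus_label = "logistic"),
                   class = "population_response")
  pk <- readout_peak(pop)
  expect_equal(pk$peak_width_ms, 800, tolerance = 0.02)
  cen <- readout_peak(pop, method = "centroid")
  expect_equal(cen$peak_width_ms, 800, tolerance = 0.05)
})

test_that("flat populations and tiny banks are readout errors", {
  b <- build_channel_bank(9, 100, 25600)
  flat <- structure(list(R = rep(2, 9), widths_ms = b$widths_ms,
                         stimulus_label = "flat"), class = "population_response")
  expect_error(readout_peak(flat), "no peak")
  tiny <- structure(list(R = c(1, 2), widths_ms = c(100, 200),
                         stimulus_label = "tiny"), class = "population_response")
  expect_error(readout_peak(tiny), "at least 3")
})

test_that("gain adaptation is proportional, bounded, and monotone in adaptor response", {
  b <- build_channel_bank(16, 50, 4000, adapt_strength = 0.6)
  mk_pop <- function(A) structure(list(R = A, widths_ms = b$widths_ms,
                                       stimulus_label = "a"),
                                  class = "population_response")
  # alpha = 0: adaptation off
  b0 <- build_channel_bank(16, 50, 4000, adapt_strength = 0)
  expect_equal(adapt_gains(b0, mk_pop(stats::runif(16)))$gains, rep(1, 16))
  # maximal channel lands exactly at 1 - alpha; bounds hold; input untouched
  for (s in 1:5) {
    A <- with_seed_local(s, stats::runif(16))
    ad <- adapt_gains(b, mk_pop(A))
    expect_equal(min(ad$gains[which.max(A)]), 1 - 0.6)
    expect_true(all(ad$gains >= 1 - 0.6 - 1e-12 & ad$gains <= 1 + 1e-12))
    # monotone: larger adaptor response => smaller gain
    expect_true(all(diff(ad$gains[order(A)]) <= 1e-12))
    expect_true(all(b$gains == 1))
  }
  # all-zero adaptor response: documented no-op
  expect_equal(adapt_gains(b, mk_pop(rep(0, 16)))$gains, rep(1, 16))
  # divisive rule satisfies the same bounds and monotonicity
  bd <- build_channel_bank(16, 50, 4000, adapt_strength = 0.6, adapt_rule = "divisive")
  A <- with_seed_local(9, stats::runif(16))
  gd <- adapt_gains(bd, mk_pop(A))$gains
  expect_true(all(gd >= 1 / 1.6 - 1e-12 & gd <= 1 + 1e-12))
  expect_true(all(diff(gd[order(A)]) <= 1e-12))
})

test_that("baseline calibration is invertible on its grid and strictly increasing", {
  m <- cached_model()
  mp <- m$mapping
  expect_true(all(diff(mp$smooth_log_width) > 0))
  dec <- decode_duration(mp, baseline_lookup(mp, mp$grid_ms))
  expect_equal(dec, mp$grid_ms, tolerance = 0.02)
  # calibration refuses an adapted bank
  ad <- adapt_bank(m$bank, flicker_adaptor(), m$filter)
  expect_error(calibrate_baseline(ad, m$filter), "unadapted")
})

test_that("without an adaptor the model decodes physical duration", {
  m <- cached_model()
  d <- c(300, 600, 1200, 1950) # calibration-grid durations: tight identity
  dec <- predict_perceived_duration(d, NULL, m$bank, m$filter, m$mapping)
  expect_equal(dec, d, tolerance = 0.005)
  # off-grid durations carry the carrier-phase wiggle the smoothing removed
  d2 <- c(612.5, 987)
  dec2 <- predict_perceived_duration(d2, NULL, m$bank, m$filter, m$mapping)
  expect_equal(dec2, d2, tolerance = 0.05)
})

test_that("zero adaptation strength produces a sub-half-point effect", {
  m <- cached_model()
  b0 <- build_channel_bank(adapt_strength = 0)
  eff <- predict_adaptation_effect(c(600, 1200), flicker_adaptor(),
                                   b0, m$filter, m$mapping)
  expect_true(all(abs(eff) < 0.5))
})

test_that("fixed-duration adaptation repels and flicker adaptation compresses", {
  m <- cached_model()
  fx <- predict_adaptation_effect(c(400, 1600), fixed_adaptor(800),
                                  m$bank, m$filter, m$mapping)
  expect_lt(fx[1], 0)
  expect_gt(fx[2], 0)
  fl <- predict_adaptation_effect(c(600, 1200), flicker_adaptor(),
                                  m$bank, m$filter, m$mapping)
  expect_true(all(fl < 0))
  expect_gt(abs(fl[1]), abs(fl[2]))
})

test_that("the model path is deterministic", {
  m1 <- cached_model()
  bank2 <- build_channel_bank()
  filt2 <- make_biphasic_filter()
  map2 <- calibrate_baseline(bank2, filt2)
  d <- c(400, 800, 1600)
  expect_identical(
    predict_perceived_duration(d, flicker_adaptor(), m1$bank, m1$filter, m1$mapping),
    predict_perceived_duration(d, flicker_adaptor(), bank2, filt2, map2)
  )
})

test_that("decoding outside the calibrated range names the offending width", {
  m <- cached_model()
  err <- tryCatch(decode_duration(m$mapping, 1e6), error = function(e) conditionMessage(e))
  expect_match(err, "outside the decodable range")
  expect_match(err, "1e\\+06|1000000")
})
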