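# Wavelet detector: Morlet parameters, amplitude response, thresholded
# detection against an independent oracle, duration estimation, threshold
# calibration.

test_that("morlet_params places the center and FWHM-matched sigma_f", {
  p <- morlet_params(12, 15)
  expect_equal(p$center_hz, 13.5)
  expect_equal(p$sigma_f_hz, 3 / (2 * sqrt(2 * log(2))))
  expect_equal(p$sigma_f_hz, 1.2740, tolerance = 1e-4)
  p2 <- morlet_params(9, 12)
  expect_equal(p2$center_hz, 10.5)
  expect_equal(p2$sigma_f_hz, p$sigma_f_hz)  # same 3 Hz band width
  expect_error(morlet_params(12, 12), "band_lo < band_hi")
})

test_that("wavelet amplitude tracks sinusoid amplitude and band edges", {
  fs <- 200
  t <- (0:(10 * fs - 1)) / fs
  cfg <- detector_config("fast")
  mid <- (3 * fs):(7 * fs)  # steady-state region
  a_center <- wavelet_amplitude(2.5 * sin(2 * pi * 13.5 * t), fs, cfg)
  expect_equal(mean(a_center[mid]), 2.5, tolerance = 0.01)
  # half-amplitude response at the band edges (FWHM definition)
  a_edge <- wavelet_amplitude(2.5 * sin(2 * pi * 15 * t), fs, cfg)
  expect_equal(mean(a_edge[mid]) / mean(a_center[mid]), 0.5,
               tolerance = 0.02)
  # zero in, zero out; linearity
  expect_equal(max(wavelet_amplitude(numeric(2000), fs, cfg)), 0)
  expect_error(wavelet_amplitude(numeric(100), fs, cfg), "too short")
})

test_that("wavelet amplitude agrees with direct time-domain convolution", {
  fs <- 200
  x <- pink1(1000, fs, seed = 5)
  cfg <- detector_config("fast")
  expect_equal(as.numeric(wavelet_amplitude(x, fs, cfg)),
               oracle_wavelet_amplitude(x, fs, 12, 15), tolerance = 1e-10)
})

test_that("detection matches the sample-wise oracle and respects min duration", {
  fs <- 200
  cfg <- detector_config("fast")
  x <- pink1(10 * fs, fs, seed = 2)
  rms <- band_rms(x, fs)
  x <- add_burst(x, fs, 4, 1.0, 13.5, 10 * rms)
  xb <- spindleloc:::narrowband_channel(x, fs, 12, 15)
  det <- detect_channel(xb, fs, cfg, "c1")
  expect_equal(nrow(det), 1)
  expect_lt(det$start_s, 5)  # overlaps the [4, 5) injection
  expect_gt(det$end_s, 4)
  runs <- oracle_detect_runs(xb, fs, 12, 15)
  expect_equal(round(det$start_s * fs) + 1, runs[, 1])
  expect_equal(round(det$end_s * fs), runs[, 2])
  expect_true(all(det$peak_amp^2 > 9 * median(
    as.numeric(wavelet_amplitude(xb, fs, cfg))^2)))
  # truncated burst: detected exactly when the oracle's run is long enough
  x2 <- add_burst(pink1(10 * fs, fs, seed = 2), fs, 4, 0.35, 13.5, 10 * rms)
  xb2 <- spindleloc:::narrowband_channel(x2, fs, 12, 15)
  runs2 <- oracle_detect_runs(xb2, fs, 12, 15)
  expect_equal(nrow(detect_channel(xb2, fs, cfg)), nrow(runs2))
  # zero signal: strict threshold on a zero median -> nothing
  expect_equal(nrow(detect_channel(numeric(2000), fs, cfg)), 0)
})

test_that("detection is scale-invariant and monotone in the threshold", {
  fs <- 200
  cfg <- detector_config("fast")
  for (seed in 1:5) {
    x <- pink1(8 * fs, fs, seed = seed)
    x <- add_burst(x, fs, 3, 1.0, 13.5, 10 * band_rms(x, fs))
    xb <- spindleloc:::narrowband_channel(x, fs, 12, 15)
    base <- detect_channel(xb, fs, cfg)
    for (c_scale in c(0.1, 1000)) {
      scaled <- detect_channel(c_scale * xb, fs, cfg)
      expect_equal(scaled$start_s, base$start_s)
      expect_equal(scaled$end_s, base$end_s)
    }
    n_prev <- Inf
    for (mult in c(3, 9, 27)) {
      cfg_m <- detector_config("fast", thresh_mult = mult)
      n_now <- nrow(detect_channel(xb, fs, cfg_m))
      expect_lte(n_now, n_prev)
      n_prev <- n_now
    }
  }
})

test_that("FWHM duration recovers the closed form for Gaussian envelopes", {
  fs <- 200
  cfg <- detector_config("fast")
  t <- (0:(6 * fs - 1)) / fs
  for (sigma_t in c(0.1, 0.2, 0.4)) {
    amp <- exp(-(t - 3)^2 / (2 * sigma_t^2))
    expected <- 2 * sqrt(2 * log(2)) * sigma_t / sqrt(2)
    expect_equal(measure_duration(amp, fs, 3, cfg), expected,
                 tolerance = 0.05)
  }
  # rectangular plateau of 0.6 s
  amp <- rep(0.1, 6 * fs)
  amp[(2 * fs + 1):(2 * fs + 120)] <- 1
  expect_equal(measure_duration(amp, fs, 2.2, cfg), 0.6,
               tolerance = 1 / fs + 1e-12)
  # peak at the series start: left side clipped to the window edge
  amp2 <- exp(-(t^2) / (2 * 0.2^2))
  d <- measure_duration(amp2, fs, 0, cfg)
  expect_equal(d, 2 * sqrt(2 * log(2)) * 0.2 / sqrt(2) / 2,
               tolerance = 0.06)
  expect_error(measure_duration(amp2, fs, 100, cfg), "outside")
})

test_that("Otsu calibration maximizes between-class variance", {
  set.seed(31)
  amps <- c(rnorm(5000, 1, 0.5), rnorm(5000, 10, 0.5))
  cal <- calibrate_threshold(amps)
  expect_gt(cal$threshold, 3)
  expect_lt(cal$threshold, 8)
  expect_false(cal$low_separation)
  expect_equal(cal$threshold, oracle_otsu(amps)$threshold, tolerance = 1e-12)
  expect_equal(cal$multiplier, cal$threshold / median(amps))
  # unimodal input: maximizer still returned, flagged as weakly separated
  uni <- rnorm(5000, 5, 1)
  cal_uni <- calibrate_threshold(uni)
  expect_true(cal_uni$low_separation)
  expect_equal(cal_uni$threshold, oracle_otsu(uni)$threshold,
               tolerance = 1e-12)
  # two point masses: any separating cut is optimal, so the threshold lies
  # strictly between them
  pm <- rep(c(2, 6), each = 100)
  cal_pm <- calibrate_threshold(pm)
  expect_gt(cal_pm$threshold, 2)
  expect_lt(cal_pm$threshold, 6)
  expect_error(calibrate_threshold(rep(1, 10)), "distinct")
})
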