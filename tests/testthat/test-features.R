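test_that("framing follows the window/hop arithmetic", {
  x <- rnorm(8000)
  fr <- frame_signal(x, 2000, frame_config())   # win 64, hop 28
  expect_equal(ncol(fr), (8000 - 64) %/% 28 + 1)  # 284
  expect_equal(nrow(fr), 64)
  tms <- attr(fr, "frame_times_s")
  expect_equal(diff(tms), rep(0.014, 283))
  # symmetric Hanning taper: frame endpoints are zeroed
  expect_true(all(fr[1, ] == 0))
  expect_true(all(fr[64, ] == 0))
  # constant input: every frame identical (shift invariance)
  frc <- frame_signal(rep(2, 200), 2000, frame_config())
  expect_true(all(apply(frc, 1, function(r) diff(range(r)) == 0)))
  expect_error(frame_signal(rnorm(10), 2000), "shorter")
})

test_that("per-band log power matches a direct DFT oracle", {
  set.seed(42)
  frame <- rnorm(64)
  bins <- emgonset:::DEFAULT_BAND_BINS_2K
  got <- subband_log_power(matrix(frame, 64, 1), 2000, frame_config())
  want <- oracle_band_log_power(frame, bins)
  expect_equal(as.numeric(got), want, tolerance = 1e-9)
})

test_that("log power is 0 dB for unit-magnitude spectra and scales by 20 log c", {
  # an impulse in the first sample has |Y_j| = 1 at every DFT bin
  imp <- matrix(c(1, rep(0, 63)), 64, 1)
  expect_equal(as.numeric(subband_log_power(imp, 2000, frame_config())),
               rep(0, 8), tolerance = 1e-12)
  set.seed(7)
  f1 <- matrix(rnorm(64), 64, 1)
  a <- subband_log_power(f1, 2000, frame_config())
  b <- subband_log_power(2 * f1, 2000, frame_config())
  expect_equal(as.numeric(b - a), rep(20 * log10(2), 8), tolerance = 1e-9)
  # sign-flip invariance
  expect_equal(subband_log_power(-f1, 2000, frame_config()), a)
  bad <- frame_config(band_bins = list(1:3, 30:40))
  expect_error(subband_log_power(f1, 2000, bad), "Nyquist")
})

test_that("all-zero frames stay finite through the log floor", {
  z <- matrix(0, 64, 2)
  v <- subband_log_power(z, 2000, frame_config())
  expect_true(all(is.finite(v)))
})

test_that("median smoothing is robust, order-statistic bounded, length stable", {
  expect_equal(median_smooth(rep(3, 10)), rep(3, 10))
  sm <- median_smooth(c(0, 0, 9, 0, 0, 0, 0))
  expect_equal(sm[3], 0)            # single spike removed
  expect_equal(median_smooth(c(1, 9, 2, 8, 3))[3], 3)
  expect_error(median_smooth(1:5, k = 4), "odd")
  set.seed(1)
  x <- rnorm(50)
  y <- median_smooth(x, 5)
  expect_length(y, 50)
  for (i in seq_along(x)) {
    win <- x[max(1, i - 2):min(50, i + 2)]
    expect_gte(y[i], min(win))
    expect_lte(y[i], max(win))
  }
})

test_that("a 100 Hz tone concentrates power in band 2", {
  t <- seq(0, 2, length.out = 4000)
  tr <- emg_trial(sin(2 * pi * 100 * t), 2000)
  env <- subband_envelope(tr)
  med <- apply(env$values, 2, median)
  expect_true(all(med[2] - med[-2] >= 6))
})

test_that("Mel band groups match the canonical table at 2 kHz and adapt elsewhere", {
  bins <- emgonset:::resolve_band_bins(frame_config(), 2000, 64)
  expect_identical(bins, emgonset:::DEFAULT_BAND_BINS_2K)
  # at 4 kHz the bands still tile 0..1 kHz below Nyquist, disjoint ascending
  bins4 <- emgonset:::resolve_band_bins(frame_config(), 4000, 128)
  flat <- unlist(bins4)
  expect_true(all(diff(flat) == 1))
  expect_equal(flat[1], 1)
  expect_lte(max(flat), 65)
})
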