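test_that("shaping filter response has the expected structure", {
  expect_equal(abs(shaping_filter_gain(0)), 0)
  # relative degree 2: magnitude rolls off far above the passband
  expect_lt(abs(shaping_filter_gain(1e6)), 1e-4 * abs(shaping_filter_gain(100)))
  f <- seq(0, 1000, by = 0.1)
  peak <- f[which.max(abs(shaping_filter_gain(f)))]
  expect_gte(peak, 60)
  expect_lte(peak, 160)
  expect_error(shaping_filter_gain(-1), "non-negative")
  expect_error(shaping_filter_gain(100, fl = -5), "fl")
  expect_error(shaping_filter_gain(100, fl = 120, fh = 80), "fh")
})

test_that("discretized shaping filter is peak-normalized and band-shaped", {
  co <- shaping_filter_coefs(2000)
  f <- seq(1, 999, by = 1)
  h <- abs(emgonset:::digital_response(co$b, co$a, f, 2000))
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_gte(f[which.max(h)], 60)
  expect_lte(f[which.max(h)], 160)
})

test_that("clean simulation gates the shaped process by the burst envelope", {
  tr <- simulate_clean_emg(4, 2000, burst_spec(1, 3), seed = 1)
  expect_length(tr$samples, 8000)
  expect_true(all(tr$samples[1:1999] == 0))
  expect_true(all(tr$samples[6002:8000] == 0))
  expect_gt(sd(tr$samples[2100:5900]), 0)
  # no bursts -> identically zero
  tr0 <- simulate_clean_emg(1, 2000, NULL, seed = 1)
  expect_true(all(tr0$samples == 0))
  expect_length(tr0$samples, 2000)
  # reproducibility: bit-identical for a fixed seed
  tr2 <- simulate_clean_emg(4, 2000, burst_spec(1, 3), seed = 1)
  expect_identical(tr$samples, tr2$samples)
  expect_error(
    simulate_clean_emg(4, 2000, data.frame(onset_s = c(1, 1.5),
                                           offset_s = c(2, 2.5))),
    "non-overlapping")
})

test_that("burst spectrum peaks where the shaping filter does", {
  # long stationary burst so the Welch estimate resolves the broad peak
  for (seed in 1:3) {
    tr <- simulate_clean_emg(30, 2000, burst_spec(1, 29), seed = seed)
    peak_hz <- welch_peak_hz(tr$samples[2001:58000], 2000)
    expect_gte(peak_hz, 60)
    expect_lte(peak_hz, 160)
  }
})

test_that("added noise realizes the requested SNR over burst intervals", {
  tr <- simulate_clean_emg(4, 2000, burst_spec(1, 3), seed = 1)
  noisy <- add_noise_for_snr(tr, 10, seed = 2)
  noise <- noisy$samples - tr$samples
  bidx <- 2001:6000
  got <- 10 * log10(mean(tr$samples[bidx]^2) / mean(noise^2))
  expect_equal(got, 10, tolerance = 0.1)
  # infinite SNR is a no-op
  expect_identical(add_noise_for_snr(tr, Inf)$samples, tr$samples)
  # no bursts with finite SNR is an error
  expect_error(add_noise_for_snr(emg_trial(rnorm(100), 2000), 10), "burst")
})

test_that("piecewise SNR schedules hold per segment", {
  bursts <- burst_spec(c(0.5, 2.5), c(1.5, 3.5))
  tr <- simulate_clean_emg(4, 2000, bursts, seed = 3)
  sched <- data.frame(start_s = c(0, 2), end_s = c(2, 4), snr_db = c(20, 2))
  noisy <- add_noise_for_snr(tr, sched, seed = 4)
  noise <- noisy$samples - tr$samples
  snr_seg <- function(b_idx, n_idx)
    10 * log10(mean(tr$samples[b_idx]^2) / mean(noise[n_idx]^2))
  expect_equal(snr_seg(1001:3000, 1:4000), 20, tolerance = 0.2)
  expect_equal(snr_seg(5001:7000, 4001:8000), 2, tolerance = 0.2)
  bad <- data.frame(start_s = c(0, 1), end_s = c(2, 4), snr_db = c(20, 2))
  expect_error(add_noise_for_snr(tr, bad, seed = 1), "overlap")
})

test_that("band-pass conditioning passes 100 Hz and rejects DC and 4 Hz", {
  fs <- 2000
  t <- seq(0, 4, length.out = 4 * fs)
  dc <- condition_signal(emg_trial(rep(1, 8000), fs))
  # steady-state rejection (the first/last samples carry the filtfilt
  # boundary transient)
  expect_lt(mean(dc$samples[1000:7000]^2), 1e-6)
  s100 <- sin(2 * pi * 100 * t)
  out100 <- condition_signal(emg_trial(s100, fs))$samples[2000:6000]
  expect_equal(sqrt(mean(out100^2)), sqrt(mean(s100^2)), tolerance = 0.05)
  s4 <- sin(2 * pi * 4 * t)
  out4 <- condition_signal(emg_trial(s4, fs))$samples[2000:6000]
  atten_db <- 20 * log10(sqrt(mean(s4^2)) / sqrt(mean(out4^2)))
  expect_gt(atten_db, 20)
  expect_error(condition_signal(emg_trial(s4, fs), high = 1000), "Nyquist")
})
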