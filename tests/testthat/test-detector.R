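test_that("votes count strict threshold exceedances per band", {
  expect_equal(votes_per_frame(rep(0, 8), rep(1, 8)), 0)
  expect_equal(votes_per_frame(rep(2, 8), rep(1, 8)), 8)
  expect_equal(votes_per_frame(c(5, 5, 5, 5, 1, 1, 1, 1), rep(3, 8)), 4)
  expect_equal(votes_per_frame(c(1, 1), c(1, 1)), 0)  # strict comparison
  expect_error(votes_per_frame(1:3, 1:4), "equal length")
})

test_that("segments are built by run-length, merge and minimum-duration rules", {
  cfg <- detection_config(vote_threshold = 4, min_segment_ms = 0,
                          min_gap_ms = 20)
  tms <- (0:7) * 0.014
  expect_equal(nrow(segments_from_votes(rep(0, 8), tms, cfg)), 0)
  one <- segments_from_votes(c(0, 0, 5, 5, 5, 0, 0, 0), tms, cfg)
  expect_equal(one$onset_s, tms[3])
  expect_equal(one$offset_s, tms[5] + 0.014)
  # a one-frame gap (14 ms < 20 ms) is merged into a single segment
  merged <- segments_from_votes(c(0, 0, 5, 5, 0, 5, 5, 0), tms, cfg)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$onset_s, tms[3])
  expect_equal(merged$offset_s, tms[7] + 0.014)
  # without merging the same votes give two segments
  cfg0 <- detection_config(vote_threshold = 4, min_segment_ms = 0,
                           min_gap_ms = 0)
  expect_equal(nrow(segments_from_votes(c(0, 0, 5, 5, 0, 5, 5, 0), tms, cfg0)), 2)
  # short runs are dropped
  cfg2 <- detection_config(vote_threshold = 4, min_segment_ms = 50,
                           min_gap_ms = 0)
  expect_equal(nrow(segments_from_votes(c(0, 5, 5, 0, 0, 0, 0, 0), tms, cfg2)), 0)
})

test_that("detection is deterministic and internally consistent", {
  tr <- simulate_clean_emg(4, 2000, burst_spec(1, 3), seed = 5)
  noisy <- condition_signal(add_noise_for_snr(tr, 10, seed = 6))
  r1 <- detect(noisy)
  r2 <- detect(noisy)
  expect_identical(r1$votes, r2$votes)
  expect_identical(r1$segments, r2$segments)
  # votes equal the independent count of threshold exceedances
  expect_equal(r1$votes,
               as.integer(rowSums(r1$envelope$values > r1$thresholds)))
  expect_true(all(r1$prob_map >= 0 & r1$prob_map <= 1))
  expect_true(sum(r1$init_frames) == 80)
})

test_that("raising the vote threshold never increases active duration", {
  tr <- simulate_clean_emg(4, 2000, burst_spec(1, 3), seed = 7)
  noisy <- condition_signal(add_noise_for_snr(tr, 10, seed = 8))
  dur <- sapply(2:6, function(v) {
    seg <- detect(noisy, detection_config(vote_threshold = v,
                                          min_segment_ms = 0,
                                          min_gap_ms = 0))$segments
    sum(seg$offset_s - seg$onset_s)
  })
  expect_true(all(diff(dur) <= 1e-9))
})

test_that("a single simulated burst is found near its true onset", {
  tr <- simulate_clean_emg(4, 2000, burst_spec(1, 3), seed = 5)
  res <- detect(condition_signal(add_noise_for_snr(tr, 10, seed = 6)))
  expect_gte(nrow(res$segments), 1)
  expect_lt(min(abs(res$segments$onset_s - 1)), 0.1)
})

test_that("too-short trials raise an informative error", {
  expect_error(detect(emg_trial(rnorm(1000), 2000)), "frames")
})
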