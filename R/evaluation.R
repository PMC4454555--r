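#' Onset detection latency
#'
#' \eqn{\tau = |t_d - t_0|}: the absolute difference between true and
#' detected onset times. Early and late detections are penalized equally.
#'
#' @param t0 True onset time (s).
#' @param td Detected onset time (s).
#' @return Latency in seconds.
#' @export
latency <- function(t0, td) {
  stopifnot(is.finite(t0), is.finite(td))
  abs(td - t0)
}

#' Match a detected segment onset to a true onset
#'
#' Returns the onset of the detected segment nearest `t0`, or `NA_real_`
#' (missed) when no detected onset lies within `max_dist_s`.
#'
#' @param segments Data frame with column `onset_s` (may have 0 rows).
#' @param t0 True onset time (s).
#' @param max_dist_s Matching window (default 0.5 s).
#' @return Detected onset time or `NA_real_`.
#' @export
match_onset <- function(segments, t0, max_dist_s = 0.5) {
  if (is.null(segments) || nrow(segments) == 0L) return(NA_real_)
  d <- abs(segments$onset_s - t0)
  i <- which.min(d)
  if (d[i] > max_dist_s) return(NA_real_)
  segments$onset_s[i]
}

#' Standard five-burst demo layout
#'
#' Five bursts of differing duration (0.5-1.5 s) and amplitude used as the
#' package's multi-burst simulation protocol. The first onset (1.5 s) falls
#' after the detector's default 80-frame initialization window.
#'
#' @return A burst table from [burst_spec()].
#' @export
five_burst_layout <- function() {
  burst_spec(onset_s = c(1.5, 4.0, 6.5, 8.5, 11.5),
             offset_s = c(2.5, 5.5, 7.0, 10.0, 12.5),
             gain = c(1.0, 1.5, 0.7, 1.2, 0.9))
}

#' Standard time-varying SNR schedule
#'
#' Five SNR levels, one per burst of [five_burst_layout()], improving from
#' 8 to 20 dB in 3 dB steps. Noise-floor decreases are tracked immediately
#' by the sequential model; sustained increases are only identifiable below
#' the `delta` constraint (a larger step up is indistinguishable from a
#' burst onset), so the standard demonstration varies the SNR upward.
#'
#' @return Data frame with columns `start_s`, `end_s`, `snr_db`.
#' @export
varying_snr_schedule <- function() {
  data.frame(start_s = c(0, 3, 5.75, 7.75, 10.75),
             end_s = c(3, 5.75, 7.75, 10.75, 14),
             snr_db = c(8, 11, 14, 17, 20))
}

#' Simulate a multi-burst trial with a time-varying SNR schedule
#'
#' Builds a clean multi-burst trial, applies piecewise noise levels per the
#' schedule (each interval's noise SD is set from the burst power inside
#' that interval) and band-pass conditions the result. Ground truth is
#' attached.
#'
#' @param schedule Data frame with `start_s`, `end_s`, `snr_db`; intervals
#'   must tile the trial without overlap.
#' @param bursts Burst table (default [five_burst_layout()]).
#' @param duration_s Trial length in seconds (default 14).
#' @param fs Sampling rate (default 2000).
#' @param seed Integer seed.
#' @param condition Apply the 20-500 Hz conditioning filter (default TRUE).
#' @return An [emg_trial()].
#' @export
varying_snr_trial <- function(schedule, bursts = five_burst_layout(),
                              duration_s = 14, fs = 2000, seed = NULL,
                              condition = TRUE) {
  clean <- simulate_clean_emg(duration_s, fs, bursts,
                              seed = derive_seed(seed %||% 0, 1))
  noisy <- add_noise_for_snr(clean, schedule,
                             seed = derive_seed(seed %||% 0, 2))
  if (condition) noisy <- condition_signal(noisy) else noisy
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-burst comparison trial
#'
#' The standard protocol for method comparison: a 4-s trial at `fs` with one
#' burst from 1 to 3 s (true onset 1 s).
#'
#' @param snr_db SNR in dB.
#' @param fs Sampling rate (default 2000).
#' @param seed Integer seed.
#' @param condition Apply the 20-500 Hz conditioning filter (default TRUE).
#' @return An [emg_trial()]; true onset is `bursts$onset_s[1]` = 1 s.
#' @export
single_burst_trial <- function(snr_db, fs = 2000, seed = NULL,
                               condition = TRUE) {
  clean <- simulate_clean_emg(4, fs, burst_spec(1, 3),
                              seed = derive_seed(seed %||% 0, 1))
  noisy <- add_noise_for_snr(clean, snr_db,
                             seed = derive_seed(seed %||% 0, 2))
  if (condition) noisy <- condition_signal(noisy) else noisy
}

#' Run one detector on a trial, returning the first-burst onset estimate
#'
#' @param trial An [emg_trial()].
#' @param method `"sgmm"`, `"amp"`, `"tkeo"` or `"bonato"`.
#' @param config A [detection_config()] (for `"sgmm"`).
#' @param baseline A [baseline_config()] (for the reference methods).
#' @param t0 True onset used for segment matching (default first annotated
#'   burst).
#' @return Detected onset time (s) or `NA_real_`.
#' @export
detect_onset <- function(trial, method = c("sgmm", "amp", "tkeo", "bonato"),
                         config = detection_config(),
                         baseline = baseline_config(),
                         t0 = NULL) {
  method <- match.arg(method)
  t0 <- t0 %||% (if (nrow(trial$bursts) > 0) trial$bursts$onset_s[1] else NA)
  if (method == "sgmm") {
    res <- detect(trial, config)
    if (is.na(t0)) {
      if (nrow(res$segments) == 0L) return(NA_real_)
      return(res$segments$onset_s[1])
    }
    return(match_onset(res$segments, t0))
  }
  baseline_detect(trial, method, baseline)
}

#' Latency sweep across SNR levels and methods
#'
#' The Fig.-5-style simulation study: for each trial a clean single-burst
#' signal (4 s, burst 1-3 s, onset 1 s) and a unit-variance noise draw are
#' generated; the same noise realization, scaled to each requested SNR, is
#' shared by all methods (and across SNR levels) for a paired comparison.
#' Trials are band-pass conditioned (20-500 Hz) before detection.
#'
#' @param methods Character vector among `"sgmm"`, `"amp"`, `"tkeo"`,
#'   `"bonato"`.
#' @param snr_db Numeric vector of SNR levels in dB
#'   (default `c(20, 15, 10, 8, 5, 4, 3, 2)`).
#' @param n_trials Trials per SNR level (default 20; 60 reproduces the full
#'   protocol).
#' @param seed Integer seed making the whole sweep reproducible.
#' @param config,baseline Detector configurations.
#' @param zero_phase Conditioning filter phase for the sweep. The default
#'   `FALSE` (causal) keeps real-time parity and avoids the anticipatory
#'   leakage of zero-phase filtering, which smears burst energy backward in
#'   time and lets hair-triggered detectors fire a few ms *before* the true
#'   onset at high SNR (inflating `|td - t0|`).
#' @return Object of class `latency_report`: data frame with columns
#'   `method`, `snr_db`, `trial`, `t0_s`, `td_s`, `latency_ms`, `detected`.
#' @export
snr_sweep <- function(methods = c("sgmm", "amp", "tkeo", "bonato"),
                      snr_db = c(20, 15, 10, 8, 5, 4, 3, 2),
                      n_trials = 20, seed = 1,
                      config = detection_config(),
                      baseline = baseline_config(), zero_phase = FALSE) {
  stopifnot(n_trials >= 2)
  bad <- setdiff(methods, c("sgmm", "amp", "tkeo", "bonato"))
  if (length(bad)) stop("unknown method name(s): ", paste(bad, collapse = ", "))
  fs <- 2000
  rows <- vector("list", length(methods) * length(snr_db) * n_trials)
  k <- 0L
  for (tr in seq_len(n_trials)) {
    clean <- simulate_clean_emg(4, fs, burst_spec(1, 3),
                                seed = derive_seed(seed, tr, 1))
    noise_unit <- with_seed(derive_seed(seed, tr, 2),
                            stats::rnorm(length(clean$samples)))
    bidx <- burst_sample_index(clean$bursts, length(clean$samples), fs)
    p_burst <- mean(clean$samples[bidx]^2)
    for (s in snr_db) {
      sigma <- sqrt(p_burst / 10^(s / 10))
      noisy <- emg_trial(clean$samples + sigma * noise_unit, fs,
                         bursts = clean$bursts, snr_db = s)
      cond <- condition_signal(noisy, zero_phase = zero_phase)
      for (mth in methods) {
        td <- detect_onset(cond, mth, config, baseline, t0 = 1)
        k <- k + 1L
        rows[[k]] <- data.frame(
          method = mth, snr_db = s, trial = tr, t0_s = 1, td_s = td,
          latency_ms = if (is.na(td)) NA_real_ else 1000 * latency(1, td),
          detected = !is.na(td))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("latency_report", "data.frame")
  out
}

#' Summarize a latency report
#'
#' @param report A `latency_report` from [snr_sweep()].
#' @return Data frame with one row per (method, snr_db): `n_trials`,
#'   `mean_ms`, `se_ms` (SD over detected trials divided by sqrt(n)),
#'   `n_missed`.
#' @export
summarize_latency <- function(report) {
  stopifnot(inherits(report, "latency_report") || is.data.frame(report))
  sp <- split(report, list(report$method, report$snr_db), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    lat <- d$latency_ms[d$detected]
    data.frame(method = d$method[1], snr_db = d$snr_db[1],
               n_trials = nrow(d),
               mean_ms = if (length(lat)) mean(lat) else NA_real_,
               se_ms = if (length(lat) > 1)
                 stats::sd(lat) / sqrt(length(lat)) else NA_real_,
               n_missed = sum(!d$detected))
  }))
  out <- out[order(out$method, -out$snr_db), ]
  rownames(out) <- NULL
  out
}
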