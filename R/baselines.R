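#' Configuration for the reference onset detectors
#'
#' @param baseline_window_s Initial interval assumed activity-free, used for
#'   noise statistics (default 0.5 s).
#' @param amp_k SD multiplier for the amplitude detector (default 3).
#' @param tkeo_k SD multiplier for the Teager-Kaiser detector (default 6).
#' @param amp_mode Threshold convention for the amplitude detector:
#'   `"sd_raw"` (default) sets the threshold to `amp_k` standard deviations
#'   of the raw baseline signal; `"envelope"` uses mean + `amp_k` SD of the
#'   smoothed rectified baseline envelope instead.
#' @param tkeo_mode Same choice for the TKE detector: `"sd_raw"` (default,
#'   `tkeo_k` SDs of the raw baseline TKE series) or `"envelope"`.
#' @param smoothing_ms Moving-average envelope smoothing length (default 50).
#' @param bonato List of double-threshold parameters: `zeta` (first
#'   threshold on the squared-pair statistic; `NULL` uses the 99% baseline
#'   quantile, i.e. a 1% per-sample false-alarm rate), `m` (observation
#'   window length in sample pairs, default 5), `r0` (required exceedances
#'   in the window, default 1), `min_active_ms` (persistence check,
#'   default 30).
#' @return Object of class `baseline_config`.
#' @export
baseline_config <- function(baseline_window_s = 0.5, amp_k = 3, tkeo_k = 6,
                            amp_mode = c("sd_raw", "envelope"),
                            tkeo_mode = c("sd_raw", "envelope"),
                            smoothing_ms = 50,
                            bonato = list(zeta = NULL, m = 5, r0 = 1,
                                          min_active_ms = 30)) {
  amp_mode <- match.arg(amp_mode)
  tkeo_mode <- match.arg(tkeo_mode)
  if (amp_k <= 0 || tkeo_k <= 0) stop("SD multipliers must be positive")
  bon <- utils::modifyList(list(zeta = NULL, m = 5, r0 = 1,
                                min_active_ms = 30), bonato)
  if (bon$r0 < 1 || bon$r0 > bon$m)
    stop("bonato parameters must satisfy 1 <= r0 <= m")
  structure(list(baseline_window_s = baseline_window_s, amp_k = amp_k,
                 tkeo_k = tkeo_k, amp_mode = amp_mode, tkeo_mode = tkeo_mode,
                 smoothing_ms = smoothing_ms, bonato = bon),
            class = "baseline_config")
}

moving_average <- function(x, n) {
  if (n <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / n, n), sides = 1, method = "convolution"))
}

# Causal moving average with the leading NA stretch filled by expanding means.
smooth_causal <- function(x, n) {
  if (n <= 1L) return(x)
  y <- moving_average(x, n)
  head_idx <- seq_len(min(n - 1L, length(x)))
  y[head_idx] <- cumsum(x[head_idx]) / head_idx
  y
}

baseline_idx <- function(trial, config) {
  nb <- round(config$baseline_window_s * trial$fs)
  if (nb < 10) stop("baseline window too short for noise statistics")
  seq_len(min(nb, length(trial$samples)))
}

#' Amplitude-threshold onset detector
#'
#' Conventional detector: the rectified signal is smoothed with a causal
#' moving average and the onset is the first time (after the baseline
#' window) the envelope exceeds the threshold: `amp_k` standard deviations
#' of the raw background noise by default, or mean + `amp_k` SD of the
#' smoothed rectified baseline with `amp_mode = "envelope"`.
#'
#' @param trial An [emg_trial()].
#' @param config A [baseline_config()].
#' @return Onset time in seconds, or `NA_real_` when never exceeded.
#' @export
amp_detect <- function(trial, config = baseline_config()) {
  stopifnot(inherits(trial, "emg_trial"))
  n_sm <- max(1L, round(config$smoothing_ms / 1000 * trial$fs))
  env <- smooth_causal(abs(trial$samples), n_sm)
  bi <- baseline_idx(trial, config)
  thr <- if (config$amp_mode == "sd_raw")
    config$amp_k * stats::sd(trial$samples[bi])
  else mean(env[bi]) + config$amp_k * stats::sd(env[bi])
  first_crossing_time(env > thr, trial$fs, from = max(bi) + 1L)
}

# First index at/after `from` where `above` holds, as a time; the baseline
# window is assumed activity-free so the search starts after it.
first_crossing_time <- function(above, fs, from = 1L) {
  above[seq_len(min(from - 1L, length(above)))] <- FALSE
  i <- which(above)[1]
  if (is.na(i)) return(NA_real_)
  (i - 1) / fs
}

#' Teager-Kaiser energy operator
#'
#' Discrete TKE: \eqn{\psi[n] = x[n]^2 - x[n-1]\,x[n+1]} for interior
#' samples; the endpoints copy their nearest interior value.
#'
#' @param x Numeric signal (length >= 3).
#' @return TKE series, same length as `x`.
#' @export
#' @examples
#' tke_operator(c(1, 2, 4))
tke_operator <- function(x) {
  n <- length(x)
  if (n < 3) stop("TKE operator needs at least 3 samples")
  psi <- numeric(n)
  idx <- 2:(n - 1)
  psi[idx] <- x[idx]^2 - x[idx - 1] * x[idx + 1]
  psi[1] <- psi[2]
  psi[n] <- psi[n - 1]
  psi
}

#' Teager-Kaiser energy onset detector
#'
#' The TKE series of the raw signal is smoothed (causal moving average) and
#' rectified; the onset is the first crossing (after the baseline window)
#' of `tkeo_k` standard deviations of the raw baseline TKE series, or of
#' mean + `tkeo_k` SD of the smoothed baseline with
#' `tkeo_mode = "envelope"`.
#'
#' @inheritParams amp_detect
#' @return Onset time in seconds, or `NA_real_`.
#' @export
tkeo_detect <- function(trial, config = baseline_config()) {
  stopifnot(inherits(trial, "emg_trial"))
  n_sm <- max(1L, round(config$smoothing_ms / 1000 * trial$fs))
  psi <- tke_operator(trial$samples)
  env <- abs(smooth_causal(psi, n_sm))
  bi <- baseline_idx(trial, config)
  thr <- if (config$tkeo_mode == "sd_raw")
    config$tkeo_k * stats::sd(psi[bi])
  else mean(env[bi]) + config$tkeo_k * stats::sd(env[bi])
  first_crossing_time(env > thr, trial$fs, from = max(bi) + 1L)
}

#' Double-threshold onset detector (Bonato style)
#'
#' The signal is normalized by the baseline standard deviation (a
#' whitening approximation) and squared sample pairs form the auxiliary
#' sequence \eqn{z[k] = y[2k-1]^2 + y[2k]^2}. A candidate onset is declared
#' when at least `r0` of `m` successive `z` values exceed the first
#' threshold `zeta`, and accepted when the exceedance fraction over the
#' following `min_active_ms` stays at or above `r0/m`. The onset time is
#' the first raw sample feeding the first supra-threshold `z` of the
#' accepted window.
#'
#' @inheritParams amp_detect
#' @return Onset time in seconds, or `NA_real_`.
#' @export
bonato_detect <- function(trial, config = baseline_config()) {
  stopifnot(inherits(trial, "emg_trial"))
  bp <- config$bonato
  x <- trial$samples
  bi <- baseline_idx(trial, config)
  s0 <- stats::sd(x[bi])
  if (s0 == 0) return(NA_real_)
  y <- x / s0
  nz <- length(y) %/% 2L
  if (nz < bp$m) stop("signal too short for the observation window")
  z <- y[seq(1, 2 * nz, by = 2)]^2 + y[seq(2, 2 * nz, by = 2)]^2
  zeta <- bp$zeta
  if (is.null(zeta)) {
    zb <- z[seq_len(max(1L, length(bi) %/% 2L))]
    zeta <- stats::quantile(zb, 0.99, names = FALSE)
  }
  above <- z > zeta
  # sliding count of exceedances over m successive z values
  cs <- cumsum(c(0, above))
  n_win <- nz - bp$m + 1L
  counts <- cs[(bp$m + 1):(nz + 1)] - cs[1:n_win]
  cand <- which(counts >= bp$r0)
  cand <- cand[cand > length(bi) %/% 2L]  # search after the baseline window
  n_act <- max(1L, round(bp$min_active_ms / 1000 * trial$fs / 2))
  for (k in cand) {
    upto <- min(nz, k + n_act - 1L)
    if (mean(above[k:upto]) >= bp$r0 / bp$m) {
      first_z <- k - 1L + which(above[k:(k + bp$m - 1L)])[1]
      return((2 * first_z - 2) / trial$fs)
    }
  }
  NA_real_
}

#' Run a named baseline detector
#'
#' @param trial An [emg_trial()].
#' @param method One of `"amp"`, `"tkeo"`, `"bonato"`.
#' @param config A [baseline_config()].
#' @return Onset time in seconds or `NA_real_`.
#' @export
baseline_detect <- function(trial, method, config = baseline_config()) {
  switch(method,
         amp = amp_detect(trial, config),
         tkeo = tkeo_detect(trial, config),
         bonato = bonato_detect(trial, config),
         stop("unknown baseline method: ", method))
}
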