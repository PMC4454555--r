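#' Shaping-filter frequency response for surface EMG simulation
#'
#' The analog shaping filter used to colour white Gaussian noise into a
#' surface-EMG-like band-limited process is
#' \deqn{H(s) = \frac{k\, s\, (2\pi f_h)^2}{(s + 2\pi f_l)(s + 2\pi f_h)^2}}
#' with low/high cut-offs `fl`, `fh` (defaults 80 and 120 Hz). This evaluates
#' \eqn{H(j 2\pi f)}.
#'
#' @param f Frequency (Hz), non-negative; vectorised.
#' @param fl,fh Low and high cut-off frequencies in Hz (`0 < fl < fh`).
#' @param k Dimensionless scaling factor (> 0).
#' @return Complex frequency response at `f`.
#' @export
#' @examples
#' abs(shaping_filter_gain(c(0, 100, 1000)))
shaping_filter_gain <- function(f, fl = 80, fh = 120, k = 1) {
  check_shaping_spec(fl, fh, k)
  if (any(f < 0)) stop("frequency `f` must be non-negative")
  s <- 2i * pi * f
  wl <- 2 * pi * fl
  wh <- 2 * pi * fh
  k * s * wh^2 / ((s + wl) * (s + wh)^2)
}

check_shaping_spec <- function(fl, fh, k) {
  if (!(is.numeric(fl) && fl > 0)) stop("`fl` must be > 0")
  if (!(is.numeric(fh) && fh > fl)) stop("`fh` must be > fl")
  if (!(is.numeric(k) && k > 0)) stop("`k` must be > 0")
  invisible(TRUE)
}

#' Discretized shaping filter coefficients
#'
#' Bilinear-transform discretization of the analog shaping filter at sampling
#' rate `fs`. With `normalize = TRUE` (default) the numerator is rescaled so
#' the peak magnitude of the digital response is 1, making simulated burst
#' amplitude depend only on the burst gain.
#'
#' @param fs Sampling rate in Hz.
#' @inheritParams shaping_filter_gain
#' @param normalize Normalize peak digital gain to 1 (overrides `k`).
#' @return List with numerator `b`, denominator `a` (`a[1] == 1`).
#' @export
shaping_filter_coefs <- function(fs, fl = 80, fh = 120, k = 1,
                                 normalize = TRUE) {
  check_shaping_spec(fl, fh, k)
  if (fh >= fs / 2) stop("`fh` must be below the Nyquist frequency")
  wl <- 2 * pi * fl
  wh <- 2 * pi * fh
  c2 <- 2 * fs
  # s -> c2 (1 - z^-1)/(1 + z^-1); multiply through by (1 + z^-1)^3
  b <- k * wh^2 * c2 * conv_poly(c(1, -1), conv_poly(c(1, 1), c(1, 1)))
  dl <- c(c2 + wl, wl - c2)
  dh <- c(c2 + wh, wh - c2)
  a <- conv_poly(dl, conv_poly(dh, dh))
  b <- b / a[1]
  a <- a / a[1]
  if (normalize) {
    fgrid <- seq(0, fs / 2, by = 0.25)
    h <- digital_response(b, a, fgrid, fs)
    b <- b / max(abs(h))
  }
  list(b = b, a = a)
}

conv_poly <- function(p, q) {
  n <- length(p) + length(q) - 1L
  out <- numeric(n)
  for (i in seq_along(p)) out[i:(i + length(q) - 1L)] <-
      out[i:(i + length(q) - 1L)] + p[i] * q
  out
}

digital_response <- function(b, a, f, fs) {
  z <- exp(-2i * pi * f / fs)
  num <- outer(z, seq_along(b) - 1L, `^`) %*% b
  den <- outer(z, seq_along(a) - 1L, `^`) %*% a
  as.vector(num / den)
}

#' Simulate a clean (noise-free) surface EMG trial
#'
#' White Gaussian noise is passed through the discretized shaping filter and
#' gated by the burst envelope: inside each burst the shaped process is
#' multiplied by the burst `gain`, outside it is exactly zero. A warm-up
#' stretch of shaped noise is generated and discarded so burst interiors are
#' stationary.
#'
#' @param duration_s Trial duration in seconds.
#' @param fs Sampling rate in Hz (2000 recommended).
#' @param bursts Burst table from [burst_spec()] (may be empty).
#' @param fl,fh,k Shaping filter parameters, see [shaping_filter_gain()].
#' @param seed Optional integer seed; fixed seed gives bit-identical trials.
#' @param warmup_s Shaped-noise warm-up discarded before gating (s).
#' @param ramp_ms Raised-cosine on/off ramp duration in ms; 0 (default) gives
#'   the rectangular gate.
#' @return An [emg_trial()] with ground-truth `bursts` attached.
#' @export
#' @examples
#' tr <- simulate_clean_emg(4, 2000, burst_spec(1, 3), seed = 1)
simulate_clean_emg <- function(duration_s, fs = 2000, bursts = NULL,
                               fl = 80, fh = 120, k = 1, seed = NULL,
                               warmup_s = 0.5, ramp_ms = 0) {
  n <- round(duration_s * fs)
  if (n < 1) stop("`duration_s` too short for the sampling rate")
  bursts <- validate_bursts(bursts, duration_s = duration_s)
  coefs <- shaping_filter_coefs(fs, fl, fh, k)
  nw <- round(warmup_s * fs)
  shaped <- with_seed(seed, {
    w <- stats::rnorm(n + nw)
    as.numeric(signal::filter(coefs$b, coefs$a, w))
  })
  shaped <- shaped[(nw + 1L):(nw + n)]
  gate <- burst_gate(bursts, n, fs, ramp_ms)
  emg_trial(shaped * gate, fs, bursts = bursts, snr_db = Inf)
}

burst_gate <- function(bursts, n, fs, ramp_ms = 0) {
  gate <- numeric(n)
  if (nrow(bursts) == 0L) return(gate)
  nr <- round(ramp_ms / 1000 * fs)
  for (i in seq_len(nrow(bursts))) {
    from <- floor(bursts$onset_s[i] * fs) + 1L
    to <- min(n, ceiling(bursts$offset_s[i] * fs))
    if (from > to) next
    seg <- rep(bursts$gain[i], to - from + 1L)
    if (nr > 0 && length(seg) > 2 * nr) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
      seg[seq_len(nr)] <- seg[seq_len(nr)] * ramp
      seg[(length(seg) - nr + 1L):length(seg)] <-
        seg[(length(seg) - nr + 1L):length(seg)] * rev(ramp)
    }
    gate[from:to] <- seg
  }
  gate
}

#' Add white Gaussian noise at a requested SNR
#'
#' Independent zero-mean white Gaussian noise is added over the whole trial.
#' The noise standard deviation is chosen so that
#' \eqn{10 \log_{10}(\bar P_\mathrm{burst} / \sigma^2)} equals `snr_db`,
#' where \eqn{\bar P_\mathrm{burst}} is the mean power of the clean signal
#' over burst intervals only. A data-frame schedule
#' (`start_s`, `end_s`, `snr_db`) applies piecewise noise levels for
#' time-varying-SNR trials; each finite-SNR segment must contain burst
#' samples.
#'
#' @param trial Clean [emg_trial()] with ground-truth bursts.
#' @param snr_db Scalar SNR in dB (`Inf` returns the trial unchanged) or a
#'   schedule data frame.
#' @param seed Optional integer seed.
#' @return A new `emg_trial` with noise added and `snr_db` recorded.
#' @export
add_noise_for_snr <- function(trial, snr_db, seed = NULL) {
  stopifnot(inherits(trial, "emg_trial"))
  n <- length(trial$samples)
  fs <- trial$fs
  if (is.data.frame(snr_db)) {
    sched <- snr_db[order(snr_db$start_s), , drop = FALSE]
    stopifnot(all(c("start_s", "end_s", "snr_db") %in% names(sched)))
    if (nrow(sched) > 1L &&
        any(sched$start_s[-1] < sched$end_s[-nrow(sched)] - 1e-9))
      stop("SNR schedule intervals must not overlap")
    noise <- with_seed(seed, stats::rnorm(n))
    sd_vec <- numeric(n)
    bidx_all <- burst_sample_index(trial$bursts, n, fs)
    for (i in seq_len(nrow(sched))) {
      from <- floor(sched$start_s[i] * fs) + 1L
      to <- min(n, ceiling(sched$end_s[i] * fs))
      if (from > to) next
      if (is.infinite(sched$snr_db[i])) next
      bidx <- intersect(bidx_all, from:to)
      if (length(bidx) == 0L)
        stop("finite SNR requested on a segment with no burst samples")
      p <- mean(trial$samples[bidx]^2)
      sd_vec[from:to] <- sqrt(p / 10^(sched$snr_db[i] / 10))
    }
    out <- trial$samples + noise * sd_vec
    return(emg_trial(out, fs, bursts = trial$bursts, snr_db = sched))
  }
  stopifnot(is.numeric(snr_db), length(snr_db) == 1L)
  if (is.infinite(snr_db) && snr_db > 0) return(trial)
  bidx <- burst_sample_index(trial$bursts, n, fs)
  if (length(bidx) == 0L)
    stop("finite `snr_db` requires a trial with at least one burst")
  p <- mean(trial$samples[bidx]^2)
  sigma <- sqrt(p / 10^(snr_db / 10))
  noise <- with_seed(seed, stats::rnorm(n, sd = sigma))
  emg_trial(trial$samples + noise, fs, bursts = trial$bursts, snr_db = snr_db)
}

#' Band-pass conditioning of an EMG trial
#'
#' Butterworth band-pass conditioning as applied to raw recordings before
#' detection. `order` is the overall band-pass filter order (must be even;
#' a 6th-order band-pass uses three poles per edge). The default is
#' zero-phase forward-backward filtering so ground-truth onsets are not
#' delayed; set `zero_phase = FALSE` for the causal variant.
#'
#' @param trial An [emg_trial()].
#' @param low,high Pass-band edges in Hz (`0 < low < high < fs/2`).
#' @param order Overall band-pass order (even, default 6).
#' @param zero_phase Apply forward-backward filtering (default `TRUE`).
#' @return Conditioned `emg_trial` (annotations preserved).
#' @export
condition_signal <- function(trial, low = 20, high = 500, order = 6,
                             zero_phase = TRUE) {
  stopifnot(inherits(trial, "emg_trial"))
  fs <- trial$fs
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("`high` must be below the Nyquist frequency fs/2")
  if (order %% 2 != 0) stop("`order` must be even for a band-pass")
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  y <- if (zero_phase) signal::filtfilt(bf, trial$samples)
       else as.numeric(signal::filter(bf, trial$samples))
  emg_trial(y, fs, bursts = trial$bursts, snr_db = trial$snr_db)
}
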