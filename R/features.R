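#' Framing and subband configuration
#'
#' Controls the short-time analysis: Hanning-windowed frames of `win_ms`
#' (default 32 ms) advanced by `hop_ms` (default 14 ms), an FFT of the window
#' length, and `n_bands` Mel-spaced subbands. At 2 kHz with a 64-point FFT the
#' canonical 1-based bin groups (bin 1 = DC) are
#' (1-3), (4-6), (7-9), (10-13), (14-17), (18-22), (23-27), (28-33),
#' nominally 0-82.1, 82.1-173.8, 173.8-276.3, 276.3-390.9, 390.9-518.8,
#' 518.8-661.8, 661.8-821.5 and 821.5-1000 Hz. At other sampling rates the
#' groups are recomputed by mapping Mel-spaced edges over
#' 0..min(1000, fs/2) Hz to the nearest FFT bins.
#'
#' @param win_ms Window length in ms.
#' @param hop_ms Frame shift in ms (must be < `win_ms`).
#' @param n_bands Number of subbands (default 8).
#' @param band_bins Optional list of 1-based inclusive bin index vectors,
#'   overriding the Mel mapping; must be disjoint and ascending.
#' @return Object of class `frame_config`.
#' @export
frame_config <- function(win_ms = 32, hop_ms = 14, n_bands = 8,
                         band_bins = NULL) {
  if (!(win_ms > hop_ms && hop_ms > 0))
    stop("need win_ms > hop_ms > 0")
  if (!is.null(band_bins)) {
    flat <- unlist(band_bins)
    if (any(diff(flat) <= 0))
      stop("`band_bins` must be disjoint and ascending")
    n_bands <- length(band_bins)
  }
  structure(list(win_ms = win_ms, hop_ms = hop_ms, n_bands = n_bands,
                 band_bins = band_bins, window = "hanning"),
            class = "frame_config")
}

# Canonical groups for the 64-point FFT at 2 kHz.
DEFAULT_BAND_BINS_2K <- list(1:3, 4:6, 7:9, 10:13, 14:17, 18:22, 23:27, 28:33)

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Resolve bin groups for a given fs / FFT length.
resolve_band_bins <- function(config, fs, nfft) {
  if (!is.null(config$band_bins)) return(config$band_bins)
  if (fs == 2000 && nfft == 64 && config$n_bands == 8)
    return(DEFAULT_BAND_BINS_2K)
  fmax <- min(1000, fs / 2)
  nb <- config$n_bands
  edges_hz <- mel_to_hz(seq(0, hz_to_mel(fmax), length.out = nb + 1))
  binw <- fs / nfft
  nyq_bin <- nfft %/% 2 + 1L
  # interior edge -> first bin of the next group; group n spans b[n]..b[n+1]-1
  b <- as.integer(round(edges_hz / binw)) + 1L
  b[1] <- 1L
  # final edge is inclusive (the top group keeps its upper-edge bin)
  b[nb + 1] <- min(as.integer(round(fmax / binw)) + 2L, nyq_bin + 1L)
  for (i in 2:(nb + 1)) b[i] <- max(b[i], b[i - 1] + 1L)
  if (b[nb + 1] - 1L > nyq_bin)
    stop("cannot place ", nb, " bands below Nyquist; reduce n_bands")
  lapply(seq_len(nb), function(i) b[i]:(b[i + 1] - 1L))
}

#' Chop a signal into Hanning-windowed frames
#'
#' @param samples Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param config A [frame_config()].
#' @return Matrix of size `win` x `n_frames`, each column a windowed frame,
#'   with attribute `frame_times_s` (frame start times).
#' @export
frame_signal <- function(samples, fs, config = frame_config()) {
  win <- round(config$win_ms / 1000 * fs)
  hop <- round(config$hop_ms / 1000 * fs)
  n <- length(samples)
  if (n < win)
    stop(sprintf("signal (%d samples) shorter than one %d-sample window",
                 n, win))
  nf <- (n - win) %/% hop + 1L
  w <- signal::hanning(win)
  starts <- (seq_len(nf) - 1L) * hop
  frames <- vapply(starts, function(s) samples[(s + 1L):(s + win)] * w,
                   numeric(win))
  frames <- matrix(frames, nrow = win, ncol = nf)
  attr(frames, "frame_times_s") <- starts / fs
  frames
}

#' Per-band logarithmic power of windowed frames
#'
#' For band \eqn{n} spanning DFT bins \eqn{f_n .. f_{n+1}-1} the log power of
#' frame \eqn{\ell} is
#' \deqn{\bar x_\ell = 10 \log_{10}\Big[\frac{1}{f_{n+1}-f_n}
#'   \sum_{j=f_n}^{f_{n+1}-1} |Y_{\ell,j}|^2\Big]}
#' with \eqn{Y_{\ell,j}} the frame's DFT. Per-bin powers are floored at
#' \eqn{10^{-12}} times the frame's maximum bin power (and at the smallest
#' positive double) so silent frames give a finite value instead of -Inf.
#'
#' @param frames Windowed frame matrix from [frame_signal()].
#' @param fs Sampling rate in Hz.
#' @param config A [frame_config()].
#' @return `n_frames` x `n_bands` matrix of log powers in dB.
#' @export
subband_log_power <- function(frames, fs, config = frame_config()) {
  win <- nrow(frames)
  nfft <- win
  bins <- resolve_band_bins(config, fs, nfft)
  if (max(unlist(bins)) > nfft %/% 2 + 1L)
    stop("band bin range extends beyond the Nyquist bin")
  y <- stats::mvfft(frames)
  p <- Mod(y)^2
  maxp <- apply(p[seq_len(nfft %/% 2 + 1L), , drop = FALSE], 2, max)
  floor_col <- pmax(1e-12 * maxp, .Machine$double.xmin)
  out <- matrix(NA_real_, ncol(frames), length(bins))
  for (b in seq_along(bins)) {
    pb <- p[bins[[b]], , drop = FALSE]
    pb <- pmax(pb, rep(floor_col, each = nrow(pb)))
    out[, b] <- 10 * log10(colMeans(pb))
  }
  colnames(out) <- paste0("band_", seq_along(bins))
  out
}

#' Running median smoother
#'
#' Five-point (by default) running median applied to each band's log-power
#' sequence. At the edges the window is truncated symmetrically (the first
#' sample uses 3 values, the second 4, etc.), preserving length.
#'
#' @param x Numeric vector.
#' @param k Odd window length (default 5).
#' @return Smoothed vector, same length as `x`.
#' @export
#' @examples
#' median_smooth(c(0, 0, 9, 0, 0))
median_smooth <- function(x, k = 5) {
  if (k %% 2 != 1) stop("`k` must be odd")
  n <- length(x)
  if (n == 0L) return(x)
  h <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Smoothed subband log-power envelopes of a trial
#'
#' Full feature front-end: framing, FFT, Mel-subband log power and per-band
#' median smoothing, yielding the envelope sequences the detector models.
#'
#' @param trial An [emg_trial()].
#' @param config A [frame_config()].
#' @param smooth_k Median smoother length (odd, default 5).
#' @return Object of class `subband_envelope`: list with `values`
#'   (`n_frames` x `n_bands` dB matrix), `frame_times_s`, `config`.
#' @export
subband_envelope <- function(trial, config = frame_config(), smooth_k = 5) {
  stopifnot(inherits(trial, "emg_trial"))
  frames <- frame_signal(trial$samples, trial$fs, config)
  raw <- subband_log_power(frames, trial$fs, config)
  sm <- apply(raw, 2, median_smooth, k = smooth_k)
  sm <- matrix(sm, nrow = nrow(raw), dimnames = dimnames(raw))
  structure(list(values = sm, raw = raw,
                 frame_times_s = attr(frames, "frame_times_s"),
                 fs = trial$fs, config = config),
            class = "subband_envelope")
}

#' @export
print.subband_envelope <- function(x, ...) {
  cat(sprintf("<subband_envelope> %d frames x %d bands (hop %g ms)\n",
              nrow(x$values), ncol(x$values), x$config$hop_ms))
  invisible(x)
}
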