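# Independent straight-line oracles used to pin down the GMM arithmetic,
# plus small fixture builders. These deliberately avoid the package's
# vectorised code paths.

# Eq-by-eq scalar posterior: w1 f1 / (w0 f0 + w1 f1).
oracle_posterior <- function(x, w0, w1, mu0, mu1, k0, k1) {
  f0 <- exp(-0.5 * (x - mu0)^2 / k0) / sqrt(2 * pi * k0)
  f1 <- exp(-0.5 * (x - mu1)^2 / k1) / sqrt(2 * pi * k1)
  w1 * f1 / (w0 * f0 + w1 * f1)
}

# Scalar first-order update followed by the constraints, written out
# longhand (posterior from the old state; updated weight and updated mean
# in the denominators of the mean/variance moments).
oracle_seq_update <- function(st, x, alpha, delta, epsilon) {
  p1 <- oracle_posterior(x, st$w0, st$w1, st$mu0, st$mu1, st$kappa0, st$kappa1)
  p0 <- 1 - p1
  w0n <- alpha * st$w0 + (1 - alpha) * p0
  w1n <- alpha * st$w1 + (1 - alpha) * p1
  mu0n <- (alpha * st$w0 * st$mu0 + (1 - alpha) * p0 * x) / w0n
  mu1n <- (alpha * st$w1 * st$mu1 + (1 - alpha) * p1 * x) / w1n
  k0n <- (alpha * st$w0 * st$kappa0 + (1 - alpha) * p0 * (x - mu0n)^2) / w0n
  k1n <- (alpha * st$w1 * st$kappa1 + (1 - alpha) * p1 * (x - mu1n)^2) / w1n
  k1n <- max(k0n, k1n)
  mu1n <- max(mu1n, mu0n + delta)
  if (w1n < epsilon) {        # virtual-component reset at the weight floor
    mu1n <- mu0n + delta
    k1n <- k0n
    w1n <- epsilon
  }
  list(w0 = 1 - w1n, w1 = w1n, mu0 = mu0n, mu1 = mu1n,
       kappa0 = k0n, kappa1 = k1n)
}

# Weighted misclassification error of the threshold rule "x > theta => burst".
oracle_bayes_error <- function(st, theta) {
  st$w1 * pnorm(theta, st$mu1, sqrt(st$kappa1)) +
    st$w0 * (1 - pnorm(theta, st$mu0, sqrt(st$kappa0)))
}

# Brute-force Bayes-error minimizer on a uniform dB grid.
oracle_grid_threshold <- function(st, step = 0.001) {
  grid <- seq(st$mu0 - 3 * sqrt(st$kappa0), st$mu1 + 3 * sqrt(st$kappa1),
              by = step)
  err <- oracle_bayes_error(st, grid)
  i <- which.min(err)
  list(theta = grid[i], err = err[i], interior = i > 1 && i < length(grid))
}

# Random constrained state with realistic band statistics.
random_constrained_state <- function() {
  mu0 <- runif(1, -30, 10)
  gap <- runif(1, 3.5, 15)
  k0 <- runif(1, 0.5, 9)
  k1 <- k0 * runif(1, 1, 4)
  w1 <- runif(1, 0.03, 0.5)
  gmm_state(w1 = w1, mu0 = mu0, mu1 = mu0 + gap, kappa0 = k0, kappa1 = k1)
}

# Direct double-loop DFT evaluation of the per-band log power of one frame.
oracle_band_log_power <- function(frame, bins) {
  n <- length(frame)
  vapply(bins, function(b) {
    pow <- vapply(b, function(j) {
      y <- sum(frame * exp(-2i * pi * (j - 1) * (seq_len(n) - 1) / n))
      Mod(y)^2
    }, numeric(1))
    10 * log10(mean(pow))
  }, numeric(1))
}

# Welch PSD: averaged Hanning-windowed periodograms, 50% overlap.
welch_peak_hz <- function(x, fs, nseg = 512) {
  w <- signal::hanning(nseg)
  hop <- nseg %/% 2
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  p <- rowMeans(vapply(starts, function(s) {
    Mod(fft(x[s:(s + nseg - 1)] * w))^2
  }, numeric(nseg)))
  half <- 2:(nseg %/% 2)      # skip DC
  freqs <- (half - 1) * fs / nseg
  freqs[which.max(p[half])]
}

# White-noise trial of the given duration with no bursts.
noise_trial <- function(duration_s, fs = 2000, seed = 1) {
  set.seed(seed)
  emg_trial(rnorm(round(duration_s * fs)), fs)
}
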