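#' Surface EMG trial container
#'
#' Bundles a sampled single-channel EMG signal with its sampling rate and
#' (optionally) ground-truth burst annotations produced by the simulator.
#'
#' @param samples Numeric vector of signal amplitudes (arbitrary units).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param bursts Optional data frame of ground-truth bursts with columns
#'   `onset_s`, `offset_s` and optionally `gain`. Bursts must be sorted,
#'   non-overlapping, with `0 <= onset_s < offset_s`.
#' @param snr_db Optional SNR label(s) in dB: a scalar, or a data frame
#'   schedule with columns `start_s`, `end_s`, `snr_db`.
#'
#' @return An object of class `emg_trial`: a list with elements `samples`,
#'   `fs`, `bursts` (data frame, possibly 0 rows) and `snr_db`.
#' @export
#' @examples
#' tr <- emg_trial(rnorm(2000), fs = 2000)
#' tr
emg_trial <- function(samples, fs, bursts = NULL, snr_db = NULL) {
  stopifnot(is.numeric(samples), length(samples) >= 1L)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  bursts <- validate_bursts(bursts, duration_s = length(samples) / fs)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         bursts = bursts, snr_db = snr_db),
    class = "emg_trial")
}

#' @export
print.emg_trial <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<emg_trial> %d samples @ %g Hz (%.3f s), %d annotated burst(s)\n",
              length(x$samples), x$fs, dur, nrow(x$bursts)))
  if (nrow(x$bursts) > 0) {
    cat("  bursts (onset_s, offset_s, gain):\n")
    print(x$bursts, row.names = FALSE)
  }
  invisible(x)
}

#' Build a burst annotation table
#'
#' @param onset_s,offset_s Numeric vectors of burst start/end times (s).
#' @param gain Linear amplitude multiplier per burst (default 1).
#' @return Data frame with columns `onset_s`, `offset_s`, `gain`.
#' @export
burst_spec <- function(onset_s, offset_s, gain = 1) {
  df <- data.frame(onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s),
                   gain = rep_len(as.numeric(gain), length(onset_s)))
  validate_bursts(df)
}

validate_bursts <- function(bursts, duration_s = Inf) {
  if (is.null(bursts) || (is.data.frame(bursts) && nrow(bursts) == 0L))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      gain = numeric(0)))
  stopifnot(is.data.frame(bursts),
            all(c("onset_s", "offset_s") %in% names(bursts)))
  if (is.null(bursts$gain)) bursts$gain <- 1
  bursts <- bursts[order(bursts$onset_s), c("onset_s", "offset_s", "gain"),
                   drop = FALSE]
  if (any(bursts$onset_s < 0) || any(bursts$offset_s <= bursts$onset_s))
    stop("bursts must satisfy 0 <= onset_s < offset_s")
  if (any(bursts$gain <= 0)) stop("burst `gain` must be positive")
  n <- nrow(bursts)
  if (n > 1L && any(bursts$onset_s[-1] < bursts$offset_s[-n]))
    stop("bursts must be non-overlapping")
  if (any(bursts$offset_s > duration_s + 1e-9))
    stop("bursts must lie within the trial duration")
  rownames(bursts) <- NULL
  bursts
}

# Indices (1-based) of samples inside any burst interval.
burst_sample_index <- function(bursts, n, fs) {
  if (nrow(bursts) == 0L) return(integer(0))
  idx <- lapply(seq_len(nrow(bursts)), function(i) {
    from <- floor(bursts$onset_s[i] * fs) + 1L
    to <- min(n, ceiling(bursts$offset_s[i] * fs))
    if (from > to) integer(0) else from:to
  })
  unique(sort(unlist(idx)))
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + p * 2654435761) %% 2147483647
  as.integer(s) + 1L
}
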