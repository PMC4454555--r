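#' Read a single-channel signal file into an EMG trial
#'
#' Supported formats: plain text (one sample per line), CSV (with a header;
#' select the sample column via `column`), and 16-bit PCM mono WAV (integer
#' samples scaled to `[-1, 1]`, sampling rate taken from the header; no R
#' WAV package is required). `fs` is mandatory for text/CSV input.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz (ignored for WAV).
#' @param format `"auto"` (by extension), `"text"`, `"csv"` or `"wav"`.
#' @param column Column name or index holding the samples (CSV only;
#'   required when the file has more than one column).
#' @return An [emg_trial()].
#' @export
read_signal <- function(path, fs = NULL,
                        format = c("auto", "text", "csv", "wav"),
                        column = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, wav = "wav", csv = "csv", "text")
  }
  if (format == "wav") {
    w <- read_wav_pcm16(path)
    return(emg_trial(w$samples, w$fs))
  }
  if (is.null(fs)) stop("`fs` is required for text/CSV input")
  if (format == "csv") {
    df <- utils::read.csv(path)
    if (is.null(column)) {
      if (ncol(df) != 1L)
        stop("CSV has ", ncol(df), " columns; specify `column`")
      column <- 1L
    }
    x <- df[[column]]
    if (is.null(x)) stop("column not found: ", column)
    x <- as.numeric(x)
    if (any(!is.finite(x)))
      stop("non-finite sample at row ", which(!is.finite(x))[1])
    return(emg_trial(x, fs))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  x <- suppressWarnings(as.numeric(lines))
  if (any(is.na(x)))
    stop("unparseable sample at line ", which(is.na(x))[1])
  emg_trial(x, fs)
}

#' Write a trial's samples to disk
#'
#' @param trial An [emg_trial()].
#' @param path Output path.
#' @param format `"text"` (one sample per line, full precision) or `"wav"`
#'   (16-bit PCM; samples are clipped to `[-1, 1]`).
#' @return `path`, invisibly.
#' @export
write_signal <- function(trial, path, format = c("text", "wav")) {
  format <- match.arg(format)
  if (format == "wav") {
    write_wav_pcm16(trial$samples, trial$fs, path)
  } else {
    writeLines(format(trial$samples, digits = 17, scientific = TRUE,
                      trim = TRUE), path)
  }
  invisible(path)
}

# Minimal RIFF/WAVE 16-bit PCM mono codec (readBin/writeBin).
read_wav_pcm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size %/% 2, 2, endian = "little",
                     signed = FALSE)
      channels <- fmt[2]
      fs <- fmt[3] + fmt[4] * 65536
      bits <- fmt[8]
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size %/% 2, 2, endian = "little",
                         signed = TRUE)
      break
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
  if (is.null(fs) || is.null(samples)) stop("malformed WAV file: ", path)
  if (!identical(as.integer(bits), 16L)) stop("only 16-bit PCM WAV supported")
  if (!identical(as.integer(channels), 1L)) stop("only mono WAV supported")
  list(samples = samples / 32767, fs = fs)
}

write_wav_pcm16 <- function(samples, fs, path) {
  x <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")          # PCM, mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 2), con, 4, endian = "little") # byte rate
  writeBin(c(2L, 16L), con, 2, endian = "little")         # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(x, con, 2, endian = "little")
  invisible(path)
}

#' Write detection results to a directory
#'
#' Writes `segments.tsv` (onset_s, offset_s), `votes.csv`
#' (frame_time_s, votes), `prob_map.csv` and `thresholds.csv`
#' (frame_time_s, band_1..band_N). Numeric fields are written with 6
#' decimals for diff-stable output.
#'
#' @param result A `detection_result` from [detect()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the written paths, invisibly.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "detection_result"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  fmt <- function(x) formatC(x, format = "f", digits = 6)
  p_seg <- file.path(out_dir, "segments.tsv")
  seg <- result$segments
  utils::write.table(
    data.frame(onset_s = fmt(seg$onset_s), offset_s = fmt(seg$offset_s)),
    p_seg, sep = "\t", quote = FALSE, row.names = FALSE)
  p_votes <- file.path(out_dir, "votes.csv")
  utils::write.csv(
    data.frame(frame_time_s = fmt(result$frame_times_s),
               votes = result$votes),
    p_votes, row.names = FALSE, quote = FALSE)
  band_df <- function(mat) {
    d <- as.data.frame(apply(mat, 2, fmt))
    names(d) <- paste0("band_", seq_len(ncol(mat)))
    cbind(data.frame(frame_time_s = fmt(result$frame_times_s)), d)
  }
  p_prob <- file.path(out_dir, "prob_map.csv")
  utils::write.csv(band_df(result$prob_map), p_prob,
                   row.names = FALSE, quote = FALSE)
  p_thr <- file.path(out_dir, "thresholds.csv")
  utils::write.csv(band_df(result$thresholds), p_thr,
                   row.names = FALSE, quote = FALSE)
  invisible(c(p_seg, p_votes, p_prob, p_thr))
}

#' Read a flat key-value configuration file
#'
#' A YAML document whose keys mirror the configuration fields (`alpha`,
#' `delta`, `epsilon`, `m_init`, `win_ms`, `hop_ms`, `n_bands`,
#' `vote_threshold`, `min_segment_ms`, `min_gap_ms`, and the baseline
#' fields `baseline_window_s`, `amp_k`, `tkeo_k`, `smoothing_ms`). Missing
#' keys default to the standard values; unknown keys raise an error naming
#' the key.
#'
#' @param path YAML file path (or `NULL` for all defaults).
#' @return List with `detection` ([detection_config()]) and `baseline`
#'   ([baseline_config()]).
#' @export
read_detection_config <- function(path = NULL) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  known_frame <- c("win_ms", "hop_ms", "n_bands")
  known_gmm <- c("alpha", "delta", "epsilon", "m_init", "em_tol",
                 "em_max_iter")
  known_det <- c("vote_threshold", "min_segment_ms", "min_gap_ms")
  known_base <- c("baseline_window_s", "amp_k", "tkeo_k", "tkeo_mode",
                  "smoothing_ms")
  unknown <- setdiff(names(vals),
                     c(known_frame, known_gmm, known_det, known_base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  frame <- do.call(frame_config, vals[intersect(names(vals), known_frame)])
  gmm <- do.call(gmm_config, vals[intersect(names(vals), known_gmm)])
  det_args <- vals[intersect(names(vals), known_det)]
  detection <- do.call(detection_config,
                       c(list(frame = frame, gmm = gmm), det_args))
  baseline <- do.call(baseline_config,
                      vals[intersect(names(vals), known_base)])
  list(detection = detection, baseline = baseline)
}
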