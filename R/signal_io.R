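#' Waveform record container
#'
#' Bundles a raw single-channel PPG trace with its sampling rate. Amplitude
#' units are arbitrary; only the timing of pulse peaks matters downstream.
#'
#' @param samples Numeric vector of PPG amplitudes.
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample, in seconds.
#' @param channel_name Optional channel label.
#' @return An object of class `waveform_record`.
#' @export
waveform_record <- function(samples, fs, start_time = 0, channel_name = "ppg") {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("samples must be a non-empty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         start_time = as.numeric(start_time), channel_name = channel_name),
    class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record: %d samples @ %g Hz (%.1f s), channel '%s'>\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$channel_name))
  invisible(x)
}

#' Duration of a waveform record in seconds
#' @param record A `waveform_record`.
#' @return Duration in seconds.
#' @export
record_duration <- function(record) length(record$samples) / record$fs

#' Beat series for one analysis window
#'
#' Holds detected pulse-peak times and the derived beat-to-beat heart rates.
#' There is one HR value per inter-beat interval: `hr[i] = 60 /
#' (peak_times[i+1] - peak_times[i])` in BPM.
#'
#' @param peak_times Strictly increasing peak times in seconds.
#' @param window_id Integer window index (0-based, first window is 0).
#' @return An object of class `beat_series` with fields `peak_times`, `hr`,
#'   `window_id`.
#' @export
beat_series <- function(peak_times, window_id = 0L) {
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) >= 2L && any(diff(peak_times) <= 0))
    stop("peak_times must be strictly increasing")
  hr <- if (length(peak_times) >= 2L) 60 / diff(peak_times) else numeric(0)
  structure(list(peak_times = peak_times, hr = hr,
                 window_id = as.integer(window_id)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series: window %d, %d beats, mean HR %.1f BPM>\n",
              x$window_id, length(x$peak_times),
              if (length(x$hr)) mean(x$hr) else NA_real_))
  invisible(x)
}

#' Read pulse-peak times from a single-column CSV
#'
#' One numeric peak time (seconds) per row; an optional non-numeric header
#' line is skipped. Times must be strictly increasing.
#'
#' @param path Path to the CSV file.
#' @return Numeric vector of strictly increasing peak times.
#' @export
read_beat_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop("empty file: ", path)
  # drop a single header line if it is not numeric
  first <- suppressWarnings(as.numeric(lines[1L]))
  if (is.na(first)) {
    lines <- lines[-1L]
    line_no <- line_no[-1L]
  }
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals))
  if (length(bad) > 0L)
    stop(sprintf("malformed peak time at line %d: '%s'",
                 line_no[bad[1L]], lines[bad[1L]]))
  if (length(vals) >= 2L && any(diff(vals) <= 0)) {
    i <- which(diff(vals) <= 0)[1L]
    stop(sprintf(
      "peak times must be strictly increasing; violation at line %d (%g after %g)",
      line_no[i + 1L], vals[i + 1L], vals[i]))
  }
  vals
}

#' Read a PPG waveform from a two-column CSV
#'
#' Expects columns `t` (seconds, uniformly sampled) and `ppg` (amplitude).
#' The sampling rate is inferred from the median time step.
#'
#' @param path Path to the CSV file.
#' @return A [waveform_record()].
#' @export
read_ppg_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("t", "ppg") %in% names(df)))
    stop("waveform CSV must have columns 't' and 'ppg'")
  if (nrow(df) < 2L) stop("waveform CSV needs at least 2 samples")
  dt <- stats::median(diff(df$t))
  if (!is.finite(dt) || dt <= 0) stop("time column must be increasing")
  waveform_record(df$ppg, fs = 1 / dt, start_time = df$t[1L])
}

#' Resample a waveform by linear interpolation
#'
#' Plumbing for rate harmonisation (e.g. 128 Hz down to 50 Hz); the detection
#' method itself only consumes peak times.
#'
#' @param record A `waveform_record`.
#' @param fs_out Target sampling rate in Hz.
#' @return A resampled `waveform_record`.
#' @export
resample_waveform <- function(record, fs_out) {
  stopifnot(inherits(record, "waveform_record"), fs_out > 0)
  t_in <- record$start_time + (seq_along(record$samples) - 1L) / record$fs
  t_out <- seq(t_in[1L], t_in[length(t_in)], by = 1 / fs_out)
  y <- stats::approx(t_in, record$samples, xout = t_out)$y
  waveform_record(y, fs = fs_out, start_time = t_in[1L],
                  channel_name = record$channel_name)
}

#' Cut peak times into consecutive non-overlapping windows
#'
#' Windows are half-open `[k*window_s, (k+1)*window_s)` so a peak landing
#' exactly on a boundary belongs to the later window. A trailing partial
#' window shorter than `window_s` is dropped; the span covered is taken from
#' the duration of the input (last peak time, or waveform duration).
#'
#' @param x Numeric vector of strictly increasing peak times (seconds), or a
#'   `waveform_record` (windowed by its duration; peaks must then be assigned
#'   by the caller).
#' @param window_s Window length in seconds (default 30).
#' @return For peak-time input, a list of [beat_series()], one per complete
#'   window (possibly with zero peaks). For a `waveform_record`, a list of
#'   `waveform_record` chunks.
#' @export
segment_windows <- function(x, window_s = 30) {
  if (window_s <= 0) stop("window_s must be positive")
  if (inherits(x, "waveform_record")) {
    n_per <- floor(window_s * x$fs)
    n_win <- length(x$samples) %/% n_per
    if (n_win == 0L) return(list())
    return(lapply(seq_len(n_win) - 1L, function(k) {
      idx <- (k * n_per + 1L):((k + 1L) * n_per)
      waveform_record(x$samples[idx], fs = x$fs,
                      start_time = x$start_time + k * n_per / x$fs,
                      channel_name = x$channel_name)
    }))
  }
  peaks <- as.numeric(x)
  if (length(peaks) == 0L) return(list())
  if (any(diff(peaks) <= 0)) stop("peak times must be strictly increasing")
  span <- peaks[length(peaks)]
  n_win <- floor(span / window_s)
  if (n_win == 0L) return(list())
  lapply(seq_len(n_win) - 1L, function(k) {
    lo <- k * window_s
    hi <- (k + 1L) * window_s
    beat_series(peaks[peaks >= lo & peaks < hi], window_id = k)
  })
}

#' Simple local-maximum pulse-peak detector
#'
#' A deterministic stand-in for a production PPG peak detector, exposed so an
#' external detector can be substituted wherever a peak list is accepted.
#' Candidate peaks are strict local maxima above an amplitude threshold
#' (midpoint between signal median and maximum); a refractory period of
#' 0.25 s (240 BPM ceiling) is enforced by keeping the taller of any two
#' conflicting candidates.
#'
#' @param record A `waveform_record` with `fs >= 25` Hz and at least 2 s of
#'   signal.
#' @param refractory_s Minimum spacing between accepted peaks (seconds).
#' @return Numeric vector of peak times (seconds). A flat (zero-variance)
#'   signal yields an empty vector with a warning.
#' @export
detect_peaks_simple <- function(record, refractory_s = 0.25) {
  stopifnot(inherits(record, "waveform_record"))
  if (record$fs < 25) stop("sampling rate must be at least 25 Hz")
  if (length(record$samples) < 2 * record$fs)
    stop("signal must be at least 2 s long")
  s <- record$samples
  if (stats::sd(s) == 0) {
    warning("flat signal: no peaks detected")
    return(numeric(0))
  }
  thr <- stats::median(s) + 0.4 * (max(s) - stats::median(s))
  n <- length(s)
  is_max <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n], FALSE)
  cand <- which(is_max & s > thr)
  if (length(cand) == 0L) return(numeric(0))
  # enforce refractory period, preferring taller peaks
  ord <- cand[order(s[cand], decreasing = TRUE)]
  min_gap <- refractory_s * record$fs
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  record$start_time + (kept - 1L) / record$fs
}

#' Beat-to-beat heart rates from peak times
#'
#' @param peak_times Strictly increasing peak times in seconds (>= 2 peaks).
#' @return Numeric vector of heart rates in BPM, `hr[i] = 60 /
#'   (peak_times[i+1] - peak_times[i])`, of length `length(peak_times) - 1`.
#' @export
compute_heart_rates <- function(peak_times) {
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) < 2L)
    stop("need at least 2 peaks to compute heart rates")
  d <- diff(peak_times)
  if (any(d <= 0)) stop("peak times must be strictly increasing")
  60 / d
}

#' Write per-window beat series to CSV
#'
#' @param windows List of [beat_series()].
#' @param path Output CSV path (columns `window_id,peak_time`).
#' @return The path, invisibly.
#' @export
write_beat_windows_csv <- function(windows, path) {
  df <- do.call(rbind, lapply(windows, function(w) {
    if (length(w$peak_times) == 0L) return(NULL)
    data.frame(window_id = w$window_id, peak_time = w$peak_times)
  }))
  if (is.null(df))
    df <- data.frame(window_id = integer(0), peak_time = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
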