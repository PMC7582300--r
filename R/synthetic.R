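#' Synthetic rhythm specification
#'
#' States the beat-interval structure of one rhythm class:
#' * `NSR`: intervals `60 / (base_hr + N(0, jitter_sd))`;
#' * `AF`: i.i.d. intervals from a broad HR distribution, uniform on
#'   `[base_hr - 30, base_hr + 40]` BPM;
#' * `BIGEMINY` / `TRIGEMINY` / `QUADRIGEMINY`: a periodic interval cycle of
#'   `cycle_normals` normal intervals at `base_hr`, one premature (coupling)
#'   interval at `base_hr + coupling_delta`, and one compensatory-pause
#'   interval at `base_hr - pause_delta`, all plus jitter.
#'
#' By default `cycle_normals` is the ectopy period minus two (0/1/2 for
#' bi/tri/quadrigeminy: ectopic every 2nd/3rd/4th beat). Fast-rate presets
#' shorten the cycle by one normal interval — at fast rates the compensatory
#' pause effectively absorbs the next sinus beat — which is what makes the
#' fast-rate quadrant trajectories one symbol shorter than their normal-rate
#' counterparts.
#'
#' @param rhythm One of `"NSR"`, `"AF"`, `"BIGEMINY"`, `"TRIGEMINY"`,
#'   `"QUADRIGEMINY"`.
#' @param base_hr Baseline heart rate in BPM (30-220).
#' @param coupling_delta HR rise of the premature interval (BPM, >= 0).
#' @param pause_delta HR drop of the compensatory-pause interval (BPM, >= 0).
#' @param jitter_sd Gaussian HR jitter in BPM (>= 0).
#' @param duration Target duration in seconds.
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @param cycle_normals Normal intervals per ectopy cycle (NULL = default
#'   for the rhythm).
#' @return An object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(rhythm = c("NSR", "AF", "BIGEMINY", "TRIGEMINY",
                                   "QUADRIGEMINY"),
                        base_hr = 70, coupling_delta = 0, pause_delta = 0,
                        jitter_sd = 0, duration = 30, seed = 1L,
                        cycle_normals = NULL) {
  rhythm <- match.arg(rhythm)
  if (base_hr < 30 || base_hr > 220)
    stop("base_hr must be in [30, 220] BPM")
  if (jitter_sd < 0 || coupling_delta < 0 || pause_delta < 0)
    stop("jitter_sd, coupling_delta and pause_delta must be >= 0")
  if (is.null(cycle_normals)) {
    cycle_normals <- switch(rhythm, BIGEMINY = 0L, TRIGEMINY = 1L,
                            QUADRIGEMINY = 2L, 0L)
  }
  structure(list(rhythm = rhythm, base_hr = base_hr,
                 coupling_delta = coupling_delta, pause_delta = pause_delta,
                 jitter_sd = jitter_sd, duration = duration,
                 seed = as.integer(seed),
                 cycle_normals = as.integer(cycle_normals)),
            class = "rhythm_spec")
}

# target HR of each interval in one ectopy cycle:
# normals..., premature, pause
.cycle_hr <- function(spec) {
  c(rep(spec$base_hr, spec$cycle_normals),
    spec$base_hr + spec$coupling_delta,
    spec$base_hr - spec$pause_delta)
}

#' Generate beat times for a synthetic rhythm
#'
#' Draws per-interval heart rates from the rhythm model stated in
#' [rhythm_spec()], converts to intervals (60/HR seconds) and accumulates
#' until `duration` is covered (the last beat may overshoot by at most one
#' interval). The first beat is at time 0.
#'
#' @param spec A [rhythm_spec()].
#' @return Numeric vector of strictly increasing beat times in seconds.
#' @export
generate_ibis <- function(spec) {
  stopifnot(inherits(spec, "rhythm_spec"))
  set.seed(spec$seed)
  # generous upper bound on the number of intervals needed
  hr_floor <- 25
  hr_max <- spec$base_hr + max(40, spec$coupling_delta) + 6 * spec$jitter_sd
  n_max <- ceiling(spec$duration * hr_max / 60) + 8L
  target <- switch(spec$rhythm,
    NSR = rep(spec$base_hr, n_max),
    AF = stats::runif(n_max, spec$base_hr - 30, spec$base_hr + 40),
    rep_len(.cycle_hr(spec), n_max))
  hr <- target + if (spec$jitter_sd > 0)
    stats::rnorm(n_max, 0, spec$jitter_sd) else 0
  if (any(hr < hr_floor))
    stop("non-physiological spec: generated HR below ", hr_floor,
         " BPM (interval too long); reduce pause_delta or jitter_sd")
  ibis <- 60 / hr
  times <- c(0, cumsum(ibis))
  keep <- which(times >= spec$duration)[1L]
  if (is.na(keep)) stop("internal: interval budget too small")
  times[seq_len(keep)]
}

.preset_table <- list(
  "bigeminy_normal"     = list(rhythm = "BIGEMINY", base_hr = 75,
                               coupling_delta = 25, pause_delta = 25,
                               cycle_normals = 0L),
  "bigeminy_fast"       = list(rhythm = "BIGEMINY", base_hr = 110,
                               coupling_delta = 2, pause_delta = 2,
                               cycle_normals = 0L),
  "trigeminy_normal"    = list(rhythm = "TRIGEMINY", base_hr = 60,
                               coupling_delta = 40, pause_delta = 3,
                               cycle_normals = 1L),
  "trigeminy_fast"      = list(rhythm = "TRIGEMINY", base_hr = 105,
                               coupling_delta = 25, pause_delta = 25,
                               cycle_normals = 0L),
  "quadrigeminy_normal" = list(rhythm = "QUADRIGEMINY", base_hr = 60,
                               coupling_delta = 40, pause_delta = 3,
                               cycle_normals = 2L),
  "quadrigeminy_fast"   = list(rhythm = "QUADRIGEMINY", base_hr = 100,
                               coupling_delta = 3, pause_delta = 20,
                               cycle_normals = 1L)
)

#' Ectopy presets reproducing the canonical trajectory patterns
#'
#' One preset per ectopy rhythm and rate class. At zero jitter each preset's
#' quadrant trajectory is exactly periodic with the signature cycle:
#'
#' | preset | trajectory cycle |
#' |---|---|
#' | bigeminy, normal HR | 2-4 |
#' | bigeminy, fast HR | 0 (indistinguishable from NSR) |
#' | trigeminy, normal HR | 1-2-3 |
#' | trigeminy, fast HR | 2-4 |
#' | quadrigeminy, normal HR | 1-2-3-0 |
#' | quadrigeminy, fast HR | 6-4-5 |
#'
#' The deltas encode the quadrant signs: an upward kite ('1-2-3') needs a
#' large coupling rise with a near-baseline pause (`pause_delta <= 5`), a
#' downward kite ('6-4-5') a small coupling rise with a large pause, '2-4'
#' both large, all-'0' both small.
#'
#' @param rhythm_name `"bigeminy"`, `"trigeminy"` or `"quadrigeminy"` (a
#'   full key like `"trigeminy_fast"` is also accepted).
#' @param rate_class `"normal"` or `"fast"`.
#' @param duration,jitter_sd,seed Passed to [rhythm_spec()].
#' @return A [rhythm_spec()].
#' @export
preset_for <- function(rhythm_name, rate_class = c("normal", "fast"),
                       duration = 30, jitter_sd = 0, seed = 1L) {
  rhythm_name <- tolower(rhythm_name)
  key <- if (rhythm_name %in% names(.preset_table)) rhythm_name
         else paste0(rhythm_name, "_", match.arg(rate_class))
  p <- .preset_table[[key]]
  if (is.null(p))
    stop("unknown preset '", key, "'; known: ",
         paste(names(.preset_table), collapse = ", "))
  rhythm_spec(rhythm = p$rhythm, base_hr = p$base_hr,
              coupling_delta = p$coupling_delta, pause_delta = p$pause_delta,
              jitter_sd = jitter_sd, duration = duration, seed = seed,
              cycle_normals = p$cycle_normals)
}

#' Names of the shipped ectopy presets
#' @return Character vector of preset keys.
#' @export
preset_names <- function() names(.preset_table)

#' Render a PPG-like waveform from beat times
#'
#' Sums one Gaussian bump per beat (peak at the beat time) plus optional
#' additive white noise. Waveform realism is a non-goal: the detection
#' method consumes only peak times, so this exists to exercise the peak
#' detector end to end.
#'
#' @param peak_times Beat times in seconds.
#' @param fs Sampling rate in Hz (>= 25).
#' @param pulse_width Gaussian sigma of one pulse in seconds.
#' @param noise_sd Additive Gaussian noise amplitude (pulse height is 1).
#' @param duration Waveform length in seconds (default: last beat + 1 s).
#' @param seed Seed for the noise.
#' @return A [waveform_record()].
#' @export
render_ppg <- function(peak_times, fs = 50, pulse_width = 0.06,
                       noise_sd = 0, duration = NULL, seed = 1L) {
  if (fs < 25) stop("fs must be at least 25 Hz")
  if (is.null(duration)) {
    duration <- if (length(peak_times)) max(peak_times) + 1 else 2
  }
  if (length(peak_times) >= 2L && min(diff(peak_times)) < 4 * pulse_width)
    warning("pulses overlap at this rate; peak amplitudes will interact")
  t <- seq(0, duration, by = 1 / fs)
  y <- numeric(length(t))
  for (pk in peak_times) {
    # only evaluate near the pulse; 5 sigma support
    idx <- which(abs(t - pk) <= 5 * pulse_width)
    y[idx] <- y[idx] + exp(-(t[idx] - pk)^2 / (2 * pulse_width^2))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  waveform_record(y, fs = fs, start_time = 0, channel_name = "synthetic_ppg")
}

#' Generate a labelled cohort of synthetic 30-s windows
#'
#' Reproducible set of windows spanning the requested classes, each carrying
#' its ground-truth label. Class names are `"NSR"`, `"AF"` or any preset key
#' from [preset_names()]; ground truth for every ectopy preset is
#' `"PACPVC"`.
#'
#' @param n_per_class Windows per class.
#' @param classes Character vector of class names.
#' @param jitter_sd HR jitter applied to every window (BPM).
#' @param seed Integer master seed; per-window seeds are derived from it.
#' @param duration Window length in seconds.
#' @return data.frame-backed list of class `rhythm_cohort` with elements
#'   `windows` (list of [beat_series()]), `truth` (ground-truth labels),
#'   `class_name` (generator class), `is_af_truth` (logical routing bits).
#' @export
generate_cohort <- function(n_per_class, classes, jitter_sd = 1, seed = 1L,
                            duration = 30) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  known <- c("NSR", "AF", preset_names())
  bad <- setdiff(classes, known)
  if (length(bad) > 0L)
    stop("unknown classes: ", paste(bad, collapse = ", "))
  windows <- list()
  truth <- character(0)
  class_name <- character(0)
  k <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      wseed <- (as.integer(seed) * 1000003L + k * 7919L) %% 2147483647L
      spec <- if (cl == "NSR") {
        rhythm_spec("NSR", base_hr = 70, jitter_sd = jitter_sd,
                    duration = duration, seed = wseed)
      } else if (cl == "AF") {
        rhythm_spec("AF", base_hr = 90, jitter_sd = jitter_sd,
                    duration = duration, seed = wseed)
      } else {
        p <- preset_for(cl, duration = duration, jitter_sd = jitter_sd,
                        seed = wseed)
        p
      }
      windows[[k]] <- beat_series(generate_ibis(spec), window_id = k - 1L)
      truth[k] <- if (cl == "NSR") "NSR" else if (cl == "AF") "AF" else "PACPVC"
      class_name[k] <- cl
    }
  }
  structure(list(windows = windows, truth = truth, class_name = class_name,
                 is_af_truth = truth == "AF"),
            class = "rhythm_cohort")
}

#' @export
print.rhythm_cohort <- function(x, ...) {
  cat(sprintf("<rhythm_cohort: %d windows (%s)>\n", length(x$windows),
              paste(sprintf("%s=%d", names(table(x$class_name)),
                            table(x$class_name)), collapse = ", ")))
  invisible(x)
}

#' Write synthetic beats or waveform to CSV with a ground-truth sidecar
#'
#' @param spec A [rhythm_spec()].
#' @param path Output CSV path. Peak-time CSV (column `t`) unless
#'   `waveform = TRUE` (columns `t,ppg`).
#' @param waveform Render a waveform instead of peak times?
#' @param fs Sampling rate for the waveform.
#' @return The path, invisibly; a `<path>.json` sidecar records the spec.
#' @export
write_synthetic_csv <- function(spec, path, waveform = FALSE, fs = 50) {
  beats <- generate_ibis(spec)
  if (waveform) {
    rec <- render_ppg(beats, fs = fs, seed = spec$seed)
    tt <- rec$start_time + (seq_along(rec$samples) - 1L) / rec$fs
    utils::write.csv(data.frame(t = tt, ppg = rec$samples), path,
                     row.names = FALSE)
  } else {
    utils::write.csv(data.frame(t = beats), path, row.names = FALSE)
  }
  sidecar <- unclass(spec)
  sidecar$truth <- if (spec$rhythm %in% c("NSR", "AF")) spec$rhythm else "PACPVC"
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
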