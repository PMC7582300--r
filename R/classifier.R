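#' @title Per-window rhythm decision rules
#' @description
#' Two decision procedures, selected by the routing bit supplied by an
#' upstream AF detector. Windows the upstream detector flagged AF go through
#' the AF-window rule (which can reclassify false-positive AF driven by
#' frequent ectopy); all other windows go through the non-AF rule, which
#' additionally uses the bigeminy ('2-4'/'4-2') and interrupted-kite edge
#' vectors. Labels are `"NSR"`, `"AF"`, `"PACPVC"` or `"UNDETERMINED"`.
#' @name rhythm-rules
NULL

RHYTHM_LABELS <- c("NSR", "AF", "PACPVC", "UNDETERMINED")

# stds with degenerate counts are forced to zero before thresholding
.kite_stds <- function(f) {
  std123 <- if (f$n123 <= 1L) 0 else f$std123
  std645 <- if (f$n645 <= 1L) 0 else f$std645
  list(std123 = std123, std645 = std645)
}

#' Classify an AF-labelled window
#'
#' Rule for windows the upstream AF detector flagged as AF. With at least
#' `min_kites` kite patterns and tight angle dispersion (both kite-angle SDs
#' at or below `std_angle_max`), the window is periodic ectopy (PACPVC);
#' with dispersed angles it stays AF only if the zero-quadrant ratio is
#' below `rzero_af`, else it is reclassified NSR. With too few kites the
#' zero-quadrant ratio alone arbitrates: below `rzero_nsr` is AF, else NSR.
#'
#' @param f A `window_features` object.
#' @param cfg A [classifier_config()].
#' @return List with `label` (character) and `rule_fired` (audit trace).
#' @export
classify_af_window <- function(f, cfg = classifier_config()) {
  if (f$n123 + f$n645 >= cfg$min_kites) {
    s <- .kite_stds(f)
    if (s$std123 <= cfg$std_angle_max && s$std645 <= cfg$std_angle_max) {
      list(label = "PACPVC", rule_fired = "af:kites/tight-angles")
    } else if (f$rzero < cfg$rzero_af) {
      list(label = "AF", rule_fired = "af:kites/dispersed/rzero<rzero_af")
    } else {
      list(label = "NSR", rule_fired = "af:kites/dispersed/rzero>=rzero_af")
    }
  } else {
    if (f$rzero < cfg$rzero_nsr) {
      list(label = "AF", rule_fired = "af:few-kites/rzero<rzero_nsr")
    } else {
      list(label = "NSR", rule_fired = "af:few-kites/rzero>=rzero_nsr")
    }
  }
}

#' Classify a non-AF-labelled window
#'
#' Rule for windows the upstream detector did not flag as AF. In order:
#' 1. `>= min_kites` kite patterns: tight kite-angle dispersion means
#'    PACPVC, dispersed means AF.
#' 2. Bigeminy: `min(n24, n42) >= min_bigeminy_pairs` with both slope-angle
#'    SDs tight means PACPVC.
#' 3. Interrupted kites: an edge family ('6-4' with '4-5', or '1-2' with
#'    '2-3') participates only if its minimum pair count strictly exceeds
#'    `min_edge_pairs_exclusive`; if at least one family participates and
#'    the maximum of the participating SDs is tight, PACPVC. (As printed,
#'    the pseudocode zeroes the SDs of scarce families, which would label a
#'    pattern-free NSR window as ectopy; requiring a participating family
#'    follows the stated "more than 3 pairs" requirement instead.)
#' 4. Otherwise AF if `rzero < rzero_nsr` or `noutside >= outside_min_af`,
#'    else NSR.
#'
#' @inheritParams classify_af_window
#' @return List with `label` and `rule_fired`.
#' @export
classify_nonaf_window <- function(f, cfg = classifier_config()) {
  if (f$n123 + f$n645 >= cfg$min_kites) {
    s <- .kite_stds(f)
    if (s$std123 <= cfg$std_angle_max && s$std645 <= cfg$std_angle_max) {
      return(list(label = "PACPVC", rule_fired = "nonaf:kites/tight-angles"))
    }
    return(list(label = "AF", rule_fired = "nonaf:kites/dispersed"))
  }
  if (min(f$n24, f$n42) >= cfg$min_bigeminy_pairs &&
      f$std24 <= cfg$std_angle_max && f$std42 <= cfg$std_angle_max) {
    return(list(label = "PACPVC", rule_fired = "nonaf:bigeminy-pairs"))
  }
  down_ok <- min(f$n64, f$n45) > cfg$min_edge_pairs_exclusive
  up_ok <- min(f$n12, f$n23) > cfg$min_edge_pairs_exclusive
  if (down_ok || up_ok) {
    stds <- c(if (up_ok) c(f$std12, f$std23),
              if (down_ok) c(f$std64, f$std45))
    if (max(stds) <= cfg$std_angle_max) {
      return(list(label = "PACPVC", rule_fired = "nonaf:edge-family"))
    }
  }
  if (f$rzero < cfg$rzero_nsr || f$noutside >= cfg$outside_min_af) {
    list(label = "AF", rule_fired = "nonaf:fallback/rzero-or-outside")
  } else {
    list(label = "NSR", rule_fired = "nonaf:fallback/nsr")
  }
}

#' Classify one 30-s window from its heart-rate series
#'
#' Extracts the full feature set and dispatches on the routing bit. Windows
#' with fewer than `cfg$min_beats` beats (HR series shorter than
#' `min_beats - 1`) are UNDETERMINED: a quadrant trajectory needs enough
#' triples to be meaningful.
#'
#' @param hr Numeric HR series in BPM for the window (one value per
#'   inter-beat interval), or a [beat_series()].
#' @param prior_af Logical: did the upstream AF detector flag this window?
#' @param cfg A [classifier_config()] (carries the quadrant geometry).
#' @param window_id Integer id attached to the decision.
#' @return An object of class `window_decision`: list with `window_id`,
#'   `label`, `features` (NULL when UNDETERMINED), `rule_fired`.
#' @export
classify_window <- function(hr, prior_af = FALSE, cfg = classifier_config(),
                            window_id = 0L) {
  if (inherits(hr, "beat_series")) {
    window_id <- hr$window_id
    hr <- hr$hr
  }
  n_beats <- length(hr) + 1L
  if (length(hr) == 0L) n_beats <- 0L
  if (n_beats < cfg$min_beats) {
    return(structure(list(window_id = as.integer(window_id),
                          label = "UNDETERMINED", features = NULL,
                          rule_fired = "gate:min-beats"),
                     class = "window_decision"))
  }
  f <- extract_features(hr, cfg$geom)
  res <- if (isTRUE(prior_af)) classify_af_window(f, cfg)
         else classify_nonaf_window(f, cfg)
  structure(list(window_id = as.integer(window_id), label = res$label,
                 features = f, rule_fired = res$rule_fired),
            class = "window_decision")
}

#' @export
print.window_decision <- function(x, ...) {
  cat(sprintf("<window %d: %s (%s)>\n", x$window_id, x$label, x$rule_fired))
  invisible(x)
}

#' Classify a list of windows
#'
#' When `prior_labels` is missing, a naive irregularity stub supplies the
#' routing bit: a window whose zero-quadrant ratio is below `cfg$rzero_nsr`
#' is treated as AF-labelled. The stub is a placeholder for a real upstream
#' AF detector and is recorded in `rule_fired`.
#'
#' @param windows List of [beat_series()] (or plain HR vectors).
#' @param prior_labels Optional logical vector, one routing bit per window.
#' @param cfg A [classifier_config()].
#' @return List of `window_decision` objects.
#' @export
classify_recording <- function(windows, prior_labels = NULL,
                               cfg = classifier_config()) {
  if (!is.null(prior_labels) && length(prior_labels) != length(windows))
    stop("prior_labels must align with windows (",
         length(prior_labels), " labels for ", length(windows), " windows)")
  out <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    hr <- if (inherits(w, "beat_series")) w$hr else as.numeric(w)
    wid <- if (inherits(w, "beat_series")) w$window_id else i - 1L
    if (is.null(prior_labels)) {
      stub_af <- length(hr) >= 3L &&
        zero_quadrant_ratio(trajectory_of(hr, cfg$geom)) < cfg$rzero_nsr
      d <- classify_window(hr, prior_af = stub_af, cfg = cfg, window_id = wid)
      d$rule_fired <- paste0("stub-routing[af=", stub_af, "]/", d$rule_fired)
    } else {
      d <- classify_window(hr, prior_af = prior_labels[i], cfg = cfg,
                           window_id = wid)
    }
    out[[i]] <- d
  }
  out
}

#' Flatten window decisions to a data.frame
#'
#' @param decisions List of `window_decision` objects.
#' @return data.frame with `window_id`, `label`, `rule_fired` and all
#'   feature columns (NA for UNDETERMINED windows).
#' @export
decisions_table <- function(decisions) {
  empty <- as.data.frame(window_features())
  rows <- lapply(decisions, function(d) {
    feats <- if (is.null(d$features)) empty * NA else as.data.frame(d$features)
    cbind(data.frame(window_id = d$window_id, label = d$label,
                     rule_fired = d$rule_fired), feats)
  })
  do.call(rbind, rows)
}
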