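#' One-vs-rest confusion counts per class
#'
#' UNDETERMINED predictions (and their truths) are excluded from the counts
#' and reported separately as coverage, mirroring the practice of reporting
#' analyzable-window coverage alongside classification performance.
#'
#' @param pred Character vector of predicted labels.
#' @param truth Character vector of ground-truth labels, same length.
#' @param classes Classes to tabulate (default: the union of observed
#'   labels, UNDETERMINED excluded).
#' @return An object of class `confusion_counts`: list with `counts` (a
#'   data.frame, one row per class: `class, tp, tn, fp, fn`), `n_decided`,
#'   `n_undetermined`.
#' @export
confusion <- function(pred, truth, classes = NULL) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  keep <- pred != "UNDETERMINED"
  n_und <- sum(!keep)
  pred <- pred[keep]
  truth <- truth[keep]
  if (is.null(classes))
    classes <- sort(unique(c(pred, truth)))
  classes <- setdiff(classes, "UNDETERMINED")
  n <- length(pred)
  rows <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    data.frame(class = cl, tp = tp, tn = n - tp - fp - fn, fp = fp, fn = fn)
  })
  structure(list(counts = do.call(rbind, rows), n_decided = n,
                 n_undetermined = n_und),
            class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)` and accuracy `(tp+tn)/(tp+tn+fp+fn)`, each as a
#' percentage at full precision. A zero denominator yields `NaN`, never a
#' silent 0. Use [format_metrics()] for the two-decimal presentation.
#'
#' @param tp,tn,fp,fn Non-negative counts; or `tp` may be a
#'   `confusion_counts` object (metrics are then computed per class).
#' @return A one-row data.frame (`sensitivity, specificity, ppv, npv,
#'   accuracy` in percent), or one row per class with a `class` column for
#'   `confusion_counts` input.
#' @export
metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (inherits(tp, "confusion_counts")) {
    cc <- tp$counts
    out <- do.call(rbind, lapply(seq_len(nrow(cc)), function(i) {
      metrics(cc$tp[i], cc$tn[i], cc$fp[i], cc$fn[i])
    }))
    return(cbind(data.frame(class = cc$class), out))
  }
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
  frac <- function(num, den) if (den == 0) NaN else num / den
  data.frame(
    sensitivity = 100 * frac(tp, tp + fn),
    specificity = 100 * frac(tn, tn + fp),
    ppv         = 100 * frac(tp, tp + fp),
    npv         = 100 * frac(tn, tn + fn),
    accuracy    = 100 * frac(tp + tn, tp + tn + fp + fn))
}

#' Round-half-up to 2 decimals, the convention of printed results tables
#'
#' Base `round()` rounds half to even; printed clinical tables round half
#' up, and the difference is visible at two decimals.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Numeric rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Present metrics at two decimals
#' @param m data.frame from [metrics()].
#' @return The same data.frame with numeric columns rounded half-up to 2
#'   decimals.
#' @export
format_metrics <- function(m) {
  num <- vapply(m, is.numeric, logical(1L))
  m[num] <- lapply(m[num], round_half_up)
  m
}

#' Evaluate a classifier run against ground truth
#'
#' @param decisions List of `window_decision` objects (or a character vector
#'   of labels).
#' @param truth Ground-truth labels.
#' @param classes Classes to tabulate.
#' @return List with `confusion` (a `confusion_counts`) and `metrics` (per
#'   class, full precision).
#' @export
evaluate_run <- function(decisions, truth, classes = c("NSR", "AF", "PACPVC")) {
  pred <- if (is.character(decisions)) decisions
          else vapply(decisions, function(d) d$label, character(1L))
  cc <- confusion(pred, truth, classes)
  list(confusion = cc, metrics = metrics(cc))
}

#' Sweep decision thresholds over a labelled cohort
#'
#' Re-runs the decision rules (features are extracted once per window) for
#' every value of every named threshold in the grid, holding the other
#' thresholds at their `base_cfg` values, and reports per-class accuracy.
#' Routing uses the cohort's ground-truth AF bits, isolating the decision
#' rules from the upstream detector.
#'
#' @param cohort A [generate_cohort()] result.
#' @param grid Named list, e.g. `list(std_angle_max = c(2, 6, 10, 14))`;
#'   names must be [classifier_config()] thresholds.
#' @param base_cfg Baseline configuration.
#' @param classes Classes to score.
#' @return data.frame with columns `threshold_name, value, class, accuracy`
#'   (accuracy in percent, full precision).
#' @export
threshold_sweep <- function(cohort, grid, base_cfg = classifier_config(),
                            classes = c("NSR", "AF", "PACPVC")) {
  if (length(grid) == 0L || any(lengths(grid) == 0L))
    stop("empty threshold grid")
  bad <- setdiff(names(grid), setdiff(names(formals(classifier_config)), "geom"))
  if (length(bad) > 0L)
    stop("unknown thresholds in grid: ", paste(bad, collapse = ", "))
  feats <- lapply(cohort$windows, function(w) {
    if (length(w$hr) + 1L < base_cfg$min_beats) NULL
    else extract_features(w$hr, base_cfg$geom)
  })
  run_once <- function(cfg) {
    vapply(seq_along(feats), function(i) {
      f <- feats[[i]]
      if (is.null(f)) return("UNDETERMINED")
      if (cohort$is_af_truth[i]) classify_af_window(f, cfg)$label
      else classify_nonaf_window(f, cfg)$label
    }, character(1L))
  }
  out <- list()
  for (nm in names(grid)) {
    for (v in grid[[nm]]) {
      args <- as.list(unclass(base_cfg))[setdiff(names(unclass(base_cfg)), "geom")]
      args[[nm]] <- v
      cfg <- do.call(classifier_config, c(args, list(geom = base_cfg$geom)))
      pred <- run_once(cfg)
      mm <- metrics(confusion(pred, cohort$truth, classes))
      out[[length(out) + 1L]] <-
        data.frame(threshold_name = nm, value = v, class = mm$class,
                   accuracy = mm$accuracy)
    }
  }
  do.call(rbind, out)
}
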