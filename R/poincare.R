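#' Nine-quadrant Poincare plot geometry
#'
#' The plot of successive heart-rate differences is divided into nine
#' regions: a central "zero" square of half-width `zero_half_width` BPM
#' (both axes), four axis-aligned arms, and four corners. The plotting field
#' spans `[-half_range, half_range]` BPM on each axis, so the arms have
#' length `arm_length = half_range - zero_half_width` BPM. Points beyond the
#' field are still classified into the outermost region; the field is a
#' plotting convention, not a validity filter.
#'
#' @param half_range Half-width of the plotting field in BPM (default 80).
#' @param zero_half_width Half-width of the central square in BPM (default 5).
#' @return An object of class `quadrant_geometry` with fields `half_range`,
#'   `zero_half_width` and the derived `arm_length`.
#' @export
quadrant_geometry <- function(half_range = 80, zero_half_width = 5) {
  if (!(half_range > zero_half_width) || zero_half_width <= 0)
    stop("need half_range > zero_half_width > 0")
  structure(list(half_range = half_range,
                 zero_half_width = zero_half_width,
                 arm_length = half_range - zero_half_width),
            class = "quadrant_geometry")
}

#' Poincare difference points from a heart-rate series
#'
#' One point per beat triple: for the triple centred on beat `n`, the x
#' coordinate is the HR change from the current to the next beat
#' (`HR[n+1] - HR[n]`) and the y coordinate is the change from the previous
#' to the current beat (`HR[n] - HR[n-1]`). Positive values mean the heart
#' is speeding up.
#'
#' @param hr Numeric HR series in BPM, length >= 3.
#' @return A data.frame with columns `beat_index` (index of the central
#'   beat's HR value), `x` and `y` (BPM differences), `length(hr) - 2` rows.
#' @export
poincare_points <- function(hr) {
  hr <- as.numeric(hr)
  if (length(hr) < 3L)
    stop("need at least 3 HR values (>= 4 beats) for Poincare points")
  d <- diff(hr)
  n <- length(hr) - 2L
  data.frame(beat_index = seq_len(n) + 1L,
             x = d[seq_len(n) + 1L],
             y = d[seq_len(n)])
}

#' Classify difference points into the nine quadrants
#'
#' Quadrant numbering follows the semantics of the beat-triple permutations:
#' 0 = centre (both changes small); arms 1 (x > w), 5 (y > w), 6 (x < -w),
#' 3 (y < -w) with the other axis small; corners 2 (x < -w, y > w),
#' 4 (x > w, y < -w), 7 (both > w), 8 (both < -w). "Small" means
#' `|d| <= zero_half_width` (closed interval). Vectorised and total: every
#' finite point receives exactly one quadrant.
#'
#' @param x,y Numeric vectors of HR differences in BPM (recycled to common
#'   length), or `x` may be the data.frame from [poincare_points()].
#' @param geom A [quadrant_geometry()].
#' @return Integer vector of quadrant indices in 0..8.
#' @export
classify_quadrant <- function(x, y = NULL, geom = quadrant_geometry()) {
  if (is.data.frame(x)) {
    y <- x$y
    x <- x$x
  }
  stopifnot(inherits(geom, "quadrant_geometry"))
  w <- geom$zero_half_width
  xs <- abs(x) <= w   # small in x
  ys <- abs(y) <= w   # small in y
  q <- integer(length(x))
  q[xs & ys] <- 0L
  q[x >  w & ys] <- 1L
  q[xs & y >  w] <- 5L
  q[x < -w & ys] <- 6L
  q[xs & y < -w] <- 3L
  q[x < -w & y >  w] <- 2L
  q[x >  w & y < -w] <- 4L
  q[x >  w & y >  w] <- 7L
  q[x < -w & y < -w] <- 8L
  q
}

#' Quadrant trajectory of a heart-rate series
#'
#' @param hr Numeric HR series in BPM, length >= 3.
#' @param geom A [quadrant_geometry()].
#' @return Integer vector of quadrant indices (0..8), one per Poincare point,
#'   in temporal order.
#' @export
trajectory_of <- function(hr, geom = quadrant_geometry()) {
  pts <- poincare_points(hr)
  classify_quadrant(pts$x, pts$y, geom)
}

#' Fraction of trajectory points in the zero quadrant
#'
#' @param traj Integer quadrant trajectory (non-empty).
#' @return Ratio in \[0, 1\].
#' @export
zero_quadrant_ratio <- function(traj) {
  if (length(traj) == 0L) stop("empty trajectory")
  sum(traj == 0L) / length(traj)
}

#' Count trajectory points outside the cross demarcation
#'
#' The cross is the union of the centre and arm quadrants (0, 1, 3, 5, 6);
#' points in the corners (2, 4, 7, 8) indicate two consecutive large HR
#' changes and accumulate under AF.
#'
#' @param traj Integer quadrant trajectory (may be empty).
#' @return Non-negative count of points in quadrants 2, 4, 7 or 8.
#' @export
count_outside_cross <- function(traj) {
  sum(traj %in% c(2L, 4L, 7L, 8L))
}

#' Export a trajectory as a plotting/debugging table
#'
#' @param hr Numeric HR series in BPM, length >= 3.
#' @param geom A [quadrant_geometry()].
#' @param path Optional CSV output path.
#' @return data.frame with columns `beat_index,x,y,quadrant` (written to
#'   `path` if given).
#' @export
trajectory_table <- function(hr, geom = quadrant_geometry(), path = NULL) {
  pts <- poincare_points(hr)
  pts$quadrant <- classify_quadrant(pts$x, pts$y, geom)
  if (!is.null(path)) utils::write.csv(pts, path, row.names = FALSE)
  pts
}

#' Plot a Poincare trajectory with the nine-quadrant grid
#'
#' @param hr Numeric HR series in BPM.
#' @param geom A [quadrant_geometry()].
#' @param ... Passed to [plot()].
#' @return Invisibly, the trajectory table.
#' @export
plot_poincare <- function(hr, geom = quadrant_geometry(), ...) {
  tab <- trajectory_table(hr, geom)
  r <- geom$half_range
  w <- geom$zero_half_width
  graphics::plot(tab$x, tab$y, xlim = c(-r, r), ylim = c(-r, r),
       xlab = "HR change, current to next (BPM)",
       ylab = "HR change, previous to current (BPM)", ...)
  graphics::abline(v = c(-w, w), h = c(-w, w), lty = 2, col = "grey40")
  graphics::lines(tab$x, tab$y, col = "grey70")
  invisible(tab)
}
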