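#' Classifier configuration (decision thresholds)
#'
#' All numeric thresholds of the two decision algorithms plus the quadrant
#' geometry. Defaults are the published operating point:
#' * `std_angle_max` (10 degrees): ceiling on the standard deviation of
#'   pattern vector angles for a window to count as periodic ectopy;
#' * `rzero_af` (0.13): zero-quadrant ratio below which an AF-labelled
#'   window with dispersed kite angles stays AF;
#' * `rzero_nsr` (0.5): zero-quadrant ratio below which a window with no
#'   qualifying patterns is called AF;
#' * `outside_min_af` (5): number of points outside the cross demarcation at
#'   or above which a non-AF window is reclassified AF;
#' * `min_kites` (3): minimum count of kite patterns (`n123 + n645`) for the
#'   kite branch;
#' * `min_bigeminy_pairs` (5): minimum of `min(n24, n42)` for the bigeminy
#'   branch;
#' * `min_edge_pairs_exclusive` (3): an edge family participates in the
#'   interrupted-kite branch only when its minimum pair count exceeds this
#'   (strictly more than 3 pairs);
#' * `min_beats` (10): windows with fewer detected beats are UNDETERMINED.
#'
#' @param std_angle_max Degrees.
#' @param rzero_af,rzero_nsr Ratios in (0, 1).
#' @param outside_min_af,min_kites,min_bigeminy_pairs,min_edge_pairs_exclusive,min_beats Counts.
#' @param geom A [quadrant_geometry()].
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(std_angle_max = 10,
                              rzero_af = 0.13,
                              rzero_nsr = 0.5,
                              outside_min_af = 5,
                              min_kites = 3,
                              min_bigeminy_pairs = 5,
                              min_edge_pairs_exclusive = 3,
                              min_beats = 10,
                              geom = quadrant_geometry()) {
  vals <- list(std_angle_max = std_angle_max, rzero_af = rzero_af,
               rzero_nsr = rzero_nsr, outside_min_af = outside_min_af,
               min_kites = min_kites, min_bigeminy_pairs = min_bigeminy_pairs,
               min_edge_pairs_exclusive = min_edge_pairs_exclusive,
               min_beats = min_beats)
  if (any(!vapply(vals, function(v) is.numeric(v) && length(v) == 1L && v > 0,
                  logical(1L))))
    stop("all thresholds must be single positive numbers")
  stopifnot(inherits(geom, "quadrant_geometry"))
  structure(c(vals, list(geom = geom)), class = "classifier_config")
}

#' Read a classifier configuration from a YAML file
#'
#' Keys must match the [classifier_config()] argument names (geometry keys
#' `half_range` and `zero_half_width` are also accepted); unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `classifier_config`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping")
  geo_keys <- c("half_range", "zero_half_width")
  cfg_keys <- setdiff(names(formals(classifier_config)), "geom")
  unknown <- setdiff(names(raw), c(cfg_keys, geo_keys))
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  geo_args <- raw[intersect(names(raw), geo_keys)]
  geom <- do.call(quadrant_geometry, geo_args)
  do.call(classifier_config,
          c(raw[intersect(names(raw), cfg_keys)], list(geom = geom)))
}

kite_kinds <- list("1-2-3" = c(1L, 2L, 3L), "6-4-5" = c(6L, 4L, 5L))
edge_kinds <- list("2-4" = c(2L, 4L), "4-2" = c(4L, 2L),
                   "1-2" = c(1L, 2L), "2-3" = c(2L, 3L),
                   "6-4" = c(6L, 4L), "4-5" = c(4L, 5L))

#' Slope angle of the segment joining two Poincare points
#'
#' Four-quadrant arctangent of the displacement, in degrees, range
#' (-180, 180].
#'
#' @param x0,y0 Coordinates of the start point (BPM).
#' @param x1,y1 Coordinates of the end point (BPM).
#' @return Angle in degrees.
#' @export
slope_angle <- function(x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  if (any(dx == 0 & dy == 0))
    stop("slope angle undefined for coincident points")
  atan2(dy, dx) * 180 / pi
}

#' Included angle at the middle vertex of three Poincare points
#'
#' Angle in degrees between the displacement vectors a->b and b->c, via the
#' normalised dot product; 0 means the trajectory continues straight, 180 a
#' full reversal.
#'
#' @param ax,ay,bx,by,cx,cy Coordinates of the three points (BPM).
#' @return Angle in \[0, 180\] degrees.
#' @export
included_angle <- function(ax, ay, bx, by, cx, cy) {
  ux <- bx - ax; uy <- by - ay
  vx <- cx - bx; vy <- cy - by
  nu <- sqrt(ux^2 + uy^2)
  nv <- sqrt(vx^2 + vy^2)
  if (any(nu == 0 | nv == 0))
    stop("included angle undefined for coincident points")
  cosang <- pmin(1, pmax(-1, (ux * vx + uy * vy) / (nu * nv)))
  acos(cosang) * 180 / pi
}

#' Find kite patterns in a quadrant trajectory
#'
#' Scans left to right for three consecutive trajectory symbols exactly
#' matching the kind ('1-2-3' upward kite or '6-4-5' downward kite); matches
#' are greedy and non-overlapping. Each instance carries the included angle
#' at its middle vertex in the Poincare plane.
#'
#' @param traj Integer quadrant trajectory.
#' @param points data.frame from [poincare_points()], aligned with `traj`.
#' @param kind `"1-2-3"` or `"6-4-5"`.
#' @return data.frame with columns `kind`, `start_index`, `angle` (degrees);
#'   zero rows when there is no match.
#' @export
find_kites <- function(traj, points, kind = c("1-2-3", "6-4-5")) {
  kind <- match.arg(kind)
  pat <- kite_kinds[[kind]]
  stopifnot(length(traj) == nrow(points))
  hits <- integer(0)
  i <- 1L
  while (i <= length(traj) - 2L) {
    if (traj[i] == pat[1L] && traj[i + 1L] == pat[2L] && traj[i + 2L] == pat[3L]) {
      hits <- c(hits, i)
      i <- i + 3L  # non-overlapping
    } else {
      i <- i + 1L
    }
  }
  if (length(hits) == 0L)
    return(data.frame(kind = character(0), start_index = integer(0),
                      angle = numeric(0)))
  ang <- vapply(hits, function(i) {
    included_angle(points$x[i], points$y[i],
                   points$x[i + 1L], points$y[i + 1L],
                   points$x[i + 2L], points$y[i + 2L])
  }, numeric(1L))
  data.frame(kind = kind, start_index = hits, angle = ang)
}

#' Find edge (vector) patterns in a quadrant trajectory
#'
#' Counts consecutive trajectory pairs matching the kind; every occurrence
#' is reported (edges may share endpoints). Each instance carries the slope
#' angle of the Poincare-plane segment between the two points.
#'
#' @param traj Integer quadrant trajectory.
#' @param points Aligned data.frame from [poincare_points()].
#' @param kind One of `"2-4"`, `"4-2"`, `"1-2"`, `"2-3"`, `"6-4"`, `"4-5"`.
#' @return data.frame with columns `kind`, `start_index`, `angle` (degrees).
#' @export
find_edges <- function(traj, points,
                       kind = c("2-4", "4-2", "1-2", "2-3", "6-4", "4-5")) {
  kind <- match.arg(kind)
  pat <- edge_kinds[[kind]]
  stopifnot(length(traj) == nrow(points))
  n <- length(traj)
  if (n < 2L)
    return(data.frame(kind = character(0), start_index = integer(0),
                      angle = numeric(0)))
  hits <- which(traj[-n] == pat[1L] & traj[-1L] == pat[2L])
  if (length(hits) == 0L)
    return(data.frame(kind = character(0), start_index = integer(0),
                      angle = numeric(0)))
  ang <- vapply(hits, function(i) {
    slope_angle(points$x[i], points$y[i], points$x[i + 1L], points$y[i + 1L])
  }, numeric(1L))
  data.frame(kind = kind, start_index = hits, angle = ang)
}

#' Dispersion of pattern vector angles
#'
#' Sample standard deviation (n - 1 denominator) of the angles; by
#' convention 0 when fewer than two angles are available, mirroring the
#' degenerate-count rule of the decision algorithms.
#'
#' @param angles Numeric vector of angles in degrees.
#' @return Standard deviation in degrees (>= 0).
#' @export
angle_std <- function(angles) {
  if (length(angles) <= 1L) return(0)
  stats::sd(angles)
}

#' Extract all decision features from one window's HR series
#'
#' Computes the full feature set consumed by the decision algorithms: counts
#' and angle dispersions of the kite patterns ('1-2-3', '6-4-5') and the six
#' edge vectors ('2-4', '4-2', '1-2', '2-3', '6-4', '4-5'), the
#' zero-quadrant ratio and the number of points outside the cross
#' demarcation.
#'
#' @param hr Numeric HR series in BPM, length >= 3.
#' @param geom A [quadrant_geometry()].
#' @return An object of class `window_features`: a named list with counts
#'   `n123, n645, n24, n42, n12, n23, n64, n45`, dispersions `std123,
#'   std645, std24, std42, std12, std23, std64, std45` (degrees), `rzero`
#'   and `noutside`, plus `n_points`.
#' @export
extract_features <- function(hr, geom = quadrant_geometry()) {
  pts <- poincare_points(hr)
  traj <- classify_quadrant(pts$x, pts$y, geom)
  f <- list()
  for (k in names(kite_kinds)) {
    inst <- find_kites(traj, pts, k)
    tag <- gsub("-", "", k)
    f[[paste0("n", tag)]] <- nrow(inst)
    f[[paste0("std", tag)]] <- angle_std(inst$angle)
  }
  for (k in names(edge_kinds)) {
    inst <- find_edges(traj, pts, k)
    tag <- gsub("-", "", k)
    f[[paste0("n", tag)]] <- nrow(inst)
    f[[paste0("std", tag)]] <- angle_std(inst$angle)
  }
  f$rzero <- zero_quadrant_ratio(traj)
  f$noutside <- count_outside_cross(traj)
  f$n_points <- length(traj)
  structure(f, class = "window_features")
}

#' Assemble a `window_features` object from raw values
#'
#' Mainly for testing the decision algorithms on hand-built feature vectors;
#' [extract_features()] is the production path.
#'
#' @param ... Named fields overriding the all-zero default (`rzero` defaults
#'   to 1).
#' @return A `window_features` object.
#' @export
window_features <- function(...) {
  f <- list(n123 = 0L, std123 = 0, n645 = 0L, std645 = 0,
            n24 = 0L, std24 = 0, n42 = 0L, std42 = 0,
            n12 = 0L, std12 = 0, n23 = 0L, std23 = 0,
            n64 = 0L, std64 = 0, n45 = 0L, std45 = 0,
            rzero = 1, noutside = 0L, n_points = 0L)
  over <- list(...)
  unknown <- setdiff(names(over), names(f))
  if (length(unknown) > 0L)
    stop("unknown feature fields: ", paste(unknown, collapse = ", "))
  f[names(over)] <- over
  structure(f, class = "window_features")
}

#' One-row data.frame of window features (fixed column order)
#'
#' @param x A `window_features` object.
#' @param ... Unused.
#' @return data.frame with columns n123, n645, n24, n42, n12, n23, n64, n45,
#'   std123, std645, std24, std42, std12, std23, std64, std45, rzero,
#'   noutside.
#' @export
as.data.frame.window_features <- function(x, ...) {
  cols <- c("n123", "n645", "n24", "n42", "n12", "n23", "n64", "n45",
            "std123", "std645", "std24", "std42", "std12", "std23",
            "std64", "std45", "rzero", "noutside")
  as.data.frame(x[cols])
}
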