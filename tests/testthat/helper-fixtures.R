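# Shared fixtures and small independent oracles.

# Beat-triple table: HR levels and the quadrant each permutation must land
# in. slow/fast/ultra-fast are representative HR levels 60/100/140 BPM so
# that every level change is a 40-BPM jump (clearly "large").
triple_quadrant_table <- function() {
  data.frame(
    triple = c("slow-slow-slow", "fast-fast-fast", "slow-slow-fast",
               "slow-fast-slow", "fast-slow-slow", "fast-slow-fast",
               "slow-fast-fast", "fast-fast-slow", "slow-fast-ultrafast",
               "ultrafast-fast-slow"),
    a = c(60, 100, 60, 60, 100, 100, 60, 100, 60, 140),
    b = c(60, 100, 60, 100, 60, 60, 100, 100, 100, 100),
    c = c(60, 100, 100, 60, 60, 100, 100, 60, 140, 60),
    quadrant = c(0L, 0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L))
}

# Independent quadrant oracle: direct case analysis on the two differences,
# written as explicit interval tests (not reusing the package's arithmetic).
oracle_quadrant <- function(x, y, w = 5) {
  sx <- if (x > w) "+" else if (x < -w) "-" else "0"
  sy <- if (y > w) "+" else if (y < -w) "-" else "0"
  key <- paste0(sx, sy)
  switch(key,
         "00" = 0L, "+0" = 1L, "0+" = 5L, "-0" = 6L, "0-" = 3L,
         "-+" = 2L, "+-" = 4L, "++" = 7L, "--" = 8L)
}

# Is `traj` eventually periodic with some rotation of `cycle`?
matches_cycle <- function(traj, cycle, min_cycles = 5) {
  k <- length(cycle)
  if (length(traj) < k * min_cycles) return(FALSE)
  for (r in seq_len(k)) {
    rot <- c(cycle[r:k], if (r > 1) cycle[seq_len(r - 1)])
    ref <- rep_len(rot, length(traj))
    if (all(traj == ref)) return(TRUE)
    # allow any starting phase: also try aligning to the first symbol
  }
  # fall back: drop up to k-1 leading symbols to find phase
  for (drop in seq_len(k - 1)) {
    sub <- traj[-seq_len(drop)]
    for (r in seq_len(k)) {
      rot <- c(cycle[r:k], if (r > 1) cycle[seq_len(r - 1)])
      if (all(sub == rep_len(rot, length(sub)))) return(TRUE)
    }
  }
  FALSE
}

# Random but structurally valid feature vector for fuzzing the decision
# rules.
random_features <- function() {
  window_features(
    n123 = sample(0:6, 1), std123 = stats::runif(1, 0, 40),
    n645 = sample(0:6, 1), std645 = stats::runif(1, 0, 40),
    n24 = sample(0:10, 1), std24 = stats::runif(1, 0, 40),
    n42 = sample(0:10, 1), std42 = stats::runif(1, 0, 40),
    n12 = sample(0:10, 1), std12 = stats::runif(1, 0, 40),
    n23 = sample(0:10, 1), std23 = stats::runif(1, 0, 40),
    n64 = sample(0:10, 1), std64 = stats::runif(1, 0, 40),
    n45 = sample(0:10, 1), std45 = stats::runif(1, 0, 40),
    rzero = stats::runif(1), noutside = sample(0:20, 1))
}

# The six canonical zero-jitter trajectory cycles.
preset_cycles <- list(
  bigeminy_normal = c(2L, 4L),
  bigeminy_fast = c(0L),
  trigeminy_normal = c(1L, 2L, 3L),
  trigeminy_fast = c(2L, 4L),
  quadrigeminy_normal = c(1L, 2L, 3L, 0L),
  quadrigeminy_fast = c(6L, 4L, 5L))
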