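test_that("slope_angle is the four-quadrant arctangent in degrees", {
  expect_equal(slope_angle(0, 0, 1, 1), 45)
  expect_equal(slope_angle(0, 0, 0, 1), 90)
  expect_equal(slope_angle(10, 40, 40, -55), atan2(-95, 30) * 180 / pi)
  expect_equal(slope_angle(0, 0, -1, 0), 180)
  expect_error(slope_angle(2, 3, 2, 3), "coincident")
})

test_that("included_angle measures the turn between displacement vectors", {
  expect_equal(included_angle(0, 0, 1, 0, 2, 0), 0)          # straight on
  expect_equal(included_angle(0, 0, 1, 0, 1, 1), 90)         # right turn
  expect_equal(included_angle(0, 0, 1, 0, 0, 0), 180)        # reversal
  expect_error(included_angle(0, 0, 0, 0, 1, 1), "coincident")
})

test_that("find_kites matches greedily, left-to-right, non-overlapping", {
  hr <- rep(c(57, 60, 100), 6)   # phase chosen so trajectory starts 1,2,3
  pts <- poincare_points(hr)
  traj <- classify_quadrant(pts$x, pts$y)
  expect_equal(traj[1:3], c(1L, 2L, 3L))

  k <- find_kites(traj[1:9], pts[1:9, ], "1-2-3")
  expect_equal(nrow(k), 3L)
  expect_equal(k$start_index, c(1L, 4L, 7L))
  # identical repeated geometry -> identical angles
  expect_equal(angle_std(k$angle), 0)

  expect_equal(nrow(find_kites(rep(0L, 4), poincare_points(rep(60, 6)),
                               "1-2-3")), 0L)

  # an interrupted downward kite is not a '6-4-5' match
  pts5 <- data.frame(beat_index = 1:5,
                     x = c(-20, 20, -20, 20, 5), y = c(5, -20, 20, -20, 20))
  traj5 <- classify_quadrant(pts5$x, pts5$y)
  expect_equal(traj5, c(6L, 4L, 2L, 4L, 5L))
  expect_equal(nrow(find_kites(traj5, pts5, "6-4-5")), 0L)

  # overlap handling: 1,2,3,2,3 yields exactly one instance
  ptso <- data.frame(beat_index = 1:5,
                     x = c(20, -20, 0, -20, 0), y = c(0, 20, -20, 20, -20))
  expect_equal(classify_quadrant(ptso$x, ptso$y), c(1L, 2L, 3L, 2L, 3L))
  expect_equal(nrow(find_kites(c(1L, 2L, 3L, 2L, 3L), ptso, "1-2-3")), 1L)
})

test_that("find_edges counts every consecutive pair occurrence", {
  hr <- rep(c(100, 50), 8)   # bigeminy: alternating 4,2 trajectory
  pts <- poincare_points(hr)
  traj <- classify_quadrant(pts$x, pts$y)
  n24 <- nrow(find_edges(traj, pts, "2-4"))
  n42 <- nrow(find_edges(traj, pts, "4-2"))
  expect_equal(abs(n24 - n42), 1L)       # alternation differs by one
  expect_equal(n24 + n42, length(traj) - 1L)

  pts5 <- data.frame(beat_index = 1:5,
                     x = c(-20, 20, -20, 20, 5), y = c(5, -20, 20, -20, 20))
  traj5 <- c(6L, 4L, 2L, 4L, 5L)
  for (kind in c("6-4", "4-5", "2-4", "4-2")) {
    expect_equal(nrow(find_edges(traj5, pts5, kind)), 1L, info = kind)
  }
  expect_equal(nrow(find_edges(traj5, pts5, "1-2")), 0L)
  expect_equal(nrow(find_edges(c(0L, 0L), pts5[1:2, ], "2-4")), 0L)
})

test_that("angle_std is the sample SD with a degenerate-count convention", {
  expect_equal(angle_std(12), 0)
  expect_equal(angle_std(numeric(0)), 0)
  expect_equal(angle_std(c(10, 10, 10)), 0)
  expect_equal(angle_std(c(0, 20)), sqrt(200))   # sample SD, n-1 denominator
  # translation invariance
  set.seed(4)
  for (i in 1:10) {
    a <- runif(6, -170, 170)
    expect_equal(angle_std(a + 7.5), angle_std(a), tolerance = 1e-9)
  }
})

test_that("extract_features assembles counts, dispersions and ratios", {
  f <- extract_features(rep(60, 29))
  nm <- c("n123", "n645", "n24", "n42", "n12", "n23", "n64", "n45")
  expect_true(all(unlist(f[nm]) == 0))
  expect_equal(f$rzero, 1)
  expect_equal(f$noutside, 0L)

  hr <- compute_heart_rates(generate_ibis(preset_for("trigeminy_normal")))
  f2 <- extract_features(hr)
  expect_gte(f2$n123, 3L)
  expect_equal(f2$std123, 0)

  expect_error(extract_features(c(60, 70)), "at least 3")
})

test_that("edge counts dominate kite counts", {
  set.seed(5)
  for (i in 1:30) {
    hr <- runif(sample(20:40, 1), 50, 150)
    f <- extract_features(hr)
    expect_gte(f$n12, f$n123)
    expect_gte(f$n23, f$n123)
    expect_gte(f$n64, f$n645)
    expect_gte(f$n45, f$n645)
  }
})

test_that("AF windows rarely sit in the zero quadrant", {
  n_low <- 0L
  for (i in 1:50) {
    spec <- rhythm_spec("AF", base_hr = 90, duration = 30, seed = 1000L + i)
    f <- extract_features(compute_heart_rates(generate_ibis(spec)))
    if (f$rzero < 0.5) n_low <- n_low + 1L
  }
  expect_gte(n_low, 48L)   # >= 95% of windows
})

test_that("window_features builder rejects unknown fields", {
  f <- window_features(n123 = 3L, std123 = 4)
  expect_s3_class(f, "window_features")
  expect_equal(f$n123, 3L)
  expect_equal(f$rzero, 1)
  expect_error(window_features(bogus = 1), "unknown feature fields")
  df <- as.data.frame(f)
  expect_equal(names(df)[1:8],
               c("n123", "n645", "n24", "n42", "n12", "n23", "n64", "n45"))
})
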