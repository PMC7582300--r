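# Table-driven enumeration of every leaf of the two decision rules.

test_that("AF-window rule follows the printed decision tree", {
  cases <- list(
    # >= 3 kites, tight angles -> PACPVC (incl. degenerate-count zeroing)
    list(f = window_features(n123 = 3L, std123 = 5, n645 = 0L), want = "PACPVC"),
    list(f = window_features(n123 = 2L, std123 = 4, n645 = 2L, std645 = 9),
         want = "PACPVC"),
    list(f = window_features(n123 = 1L, std123 = 99, n645 = 2L, std645 = 3),
         want = "PACPVC"),   # n123 <= 1 forces std123 to 0
    list(f = window_features(n123 = 4L, std123 = 10, n645 = 4L, std645 = 10),
         want = "PACPVC"),   # thresholds are inclusive
    # >= 3 kites, dispersed angles -> rzero arbitrates AF vs NSR
    list(f = window_features(n123 = 2L, std123 = 25, n645 = 2L, std645 = 1,
                             rzero = 0.05), want = "AF"),
    list(f = window_features(n123 = 2L, std123 = 25, n645 = 2L, std645 = 1,
                             rzero = 0.13), want = "NSR"),  # strict <
    list(f = window_features(n123 = 4L, std123 = 2, n645 = 2L, std645 = 30,
                             rzero = 0.5), want = "NSR"),
    # < 3 kites -> rzero against the 50% threshold
    list(f = window_features(rzero = 0.2), want = "AF"),
    list(f = window_features(rzero = 0.9), want = "NSR"),
    list(f = window_features(rzero = 0.5), want = "NSR"),
    list(f = window_features(n123 = 2L, rzero = 0.49), want = "AF"))
  for (cs in cases) {
    got <- classify_af_window(cs$f)
    expect_equal(got$label, cs$want)
    expect_true(nzchar(got$rule_fired))
  }
})

test_that("non-AF-window rule follows the printed decision tree", {
  cases <- list(
    # kite branch
    list(f = window_features(n123 = 3L, std123 = 5), want = "PACPVC"),
    list(f = window_features(n123 = 4L, std123 = 20), want = "AF"),
    list(f = window_features(n123 = 4L, std123 = 20, rzero = 0.9),
         want = "AF"),  # dispersed kites go to AF regardless of rzero
    # bigeminy branch
    list(f = window_features(n24 = 6L, std24 = 3, n42 = 6L, std42 = 4),
         want = "PACPVC"),
    list(f = window_features(n24 = 6L, std24 = 3, n42 = 4L, std42 = 4,
                             rzero = 0.9), want = "NSR"),  # min(n24,n42) < 5
    list(f = window_features(n24 = 5L, std24 = 12, n42 = 5L, std42 = 4,
                             rzero = 0.9), want = "NSR"),  # dispersed slopes
    # edge families: participate only with > 3 pairs each
    list(f = window_features(n64 = 4L, std64 = 2, n45 = 4L, std45 = 3),
         want = "PACPVC"),
    list(f = window_features(n12 = 5L, std12 = 2, n23 = 4L, std23 = 3),
         want = "PACPVC"),
    list(f = window_features(n12 = 5L, std12 = 2, n23 = 4L, std23 = 30,
                             rzero = 0.9), want = "NSR"),
    list(f = window_features(n12 = 5L, std12 = 2, n23 = 4L, std23 = 30,
                             rzero = 0.3), want = "AF"),
    # one family qualifies and is tight, the other dispersed but scarce
    list(f = window_features(n64 = 4L, std64 = 2, n45 = 4L, std45 = 3,
                             n12 = 2L, std12 = 35), want = "PACPVC"),
    # no qualifying pattern: pure NSR stays NSR (degenerate-edge amendment)
    list(f = window_features(rzero = 1.0, noutside = 0L), want = "NSR"),
    list(f = window_features(n64 = 3L, n45 = 3L, rzero = 0.9), want = "NSR"),
    # fallback: irregularity or spread reclassifies as AF
    list(f = window_features(rzero = 0.3, noutside = 6L), want = "AF"),
    list(f = window_features(rzero = 0.9, noutside = 5L), want = "AF"),
    list(f = window_features(rzero = 0.49, noutside = 0L), want = "AF"),
    list(f = window_features(rzero = 0.5, noutside = 4L), want = "NSR"))
  for (cs in cases) {
    got <- classify_nonaf_window(cs$f)
    expect_equal(got$label, cs$want)
    expect_true(nzchar(got$rule_fired))
  }
})

test_that("every feature vector receives exactly one label", {
  set.seed(6)
  labs <- c("NSR", "AF", "PACPVC")
  for (i in 1:2000) {
    f <- random_features()
    a <- classify_af_window(f)
    b <- classify_nonaf_window(f)
    expect_true(a$label %in% labs && b$label %in% labs)
    expect_true(nzchar(a$rule_fired) && nzchar(b$rule_fired))
  }
})

test_that("raising std123 through the threshold never creates PACPVC", {
  for (rz in c(0.05, 0.3, 0.8)) {
    prev <- NULL
    for (s in seq(0, 25, by = 0.5)) {
      f <- window_features(n123 = 4L, std123 = s, rzero = rz)
      lab <- classify_af_window(f)$label
      if (!is.null(prev) && prev != "PACPVC") expect_false(lab == "PACPVC")
      prev <- lab
    }
  }
})

test_that("config round-trips through YAML with the printed thresholds", {
  f <- withr::local_tempfile(lines = c(
    "std_angle_max: 10", "rzero_af: 0.13", "rzero_nsr: 0.5",
    "outside_min_af: 5", "min_kites: 3", "min_bigeminy_pairs: 5",
    "min_edge_pairs_exclusive: 3", "half_range: 80", "zero_half_width: 5"),
    fileext = ".yaml")
  cfg <- read_config_yaml(f)
  set.seed(8)
  for (i in 1:200) {
    feats <- random_features()
    expect_identical(classify_af_window(feats, cfg)$label,
                     classify_af_window(feats)$label)
    expect_identical(classify_nonaf_window(feats, cfg)$label,
                     classify_nonaf_window(feats)$label)
  }
  bad <- withr::local_tempfile(lines = "nonsense_threshold: 3",
                               fileext = ".yaml")
  expect_error(read_config_yaml(bad), "unknown config keys")
})

test_that("classify_window gates short windows and routes by prior label", {
  short <- beat_series(cumsum(rep(1, 5)))
  d <- classify_window(short)
  expect_equal(d$label, "UNDETERMINED")
  expect_null(d$features)

  hr <- compute_heart_rates(generate_ibis(preset_for("trigeminy_normal")))
  expect_equal(classify_window(hr, prior_af = FALSE)$label, "PACPVC")
  expect_equal(classify_window(hr, prior_af = TRUE)$label, "PACPVC")

  ok <- 0L
  for (i in 1:50) {
    spec <- rhythm_spec("AF", base_hr = 90, duration = 30, seed = 2000L + i)
    hr <- compute_heart_rates(generate_ibis(spec))
    if (classify_window(hr, prior_af = TRUE)$label == "AF") ok <- ok + 1L
  }
  expect_gte(ok, 48L)  # >= 95%
})

test_that("classify_recording validates alignment and records the stub", {
  w <- lapply(1:3, function(i) {
    beat_series(generate_ibis(rhythm_spec("NSR", jitter_sd = 1, seed = i)),
                window_id = i - 1L)
  })
  expect_error(classify_recording(w, prior_labels = c(TRUE, FALSE)), "align")
  expect_length(classify_recording(list()), 0L)

  dec <- classify_recording(w)
  expect_true(all(grepl("^stub-routing", vapply(dec, `[[`, "", "rule_fired"))))
  expect_equal(vapply(dec, `[[`, "", "label"), rep("NSR", 3))

  dec2 <- classify_recording(w, prior_labels = c(TRUE, FALSE, FALSE))
  expect_false(any(grepl("stub", vapply(dec2, `[[`, "", "rule_fired"))))

  tab <- decisions_table(dec)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("window_id", "label", "rule_fired", "rzero") %in% names(tab)))
})
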