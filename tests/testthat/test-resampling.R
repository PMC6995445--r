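toy_dist <- function(values, ids = paste0("p", seq_len(nrow(values))),
                     measure = "geodesic") {
  distance_matrix(values, measure = measure, row_ids = ids, col_ids = ids)
}

test_that("comparing a measure with itself gives exactly zero differences and p = 1", {
  d <- toy_dist(withr::with_seed(1, matrix(runif(16), 4, 4)))
  suppressMessages(
    res <- bootstrap_mean_differences(d, d, bootstrap_config(M = 5, B = 8, seed = 2))
  )
  expect_identical(res$delta_bars, rep(0, 8))
  expect_identical(res$p_value, 1)
})

test_that("a single-resample configuration is a plain accuracy difference", {
  dg <- toy_dist(rbind(c(0.1, 5, 5), c(5, 0.1, 5), c(5, 5, 0.1)))
  dp <- toy_dist(rbind(c(5, 0.1, 5), c(0.1, 5, 5), c(5, 5, 0.1)),
                 measure = "pearson")
  cfg <- bootstrap_config(M = 1, B = 1, seed = 3)
  suppressMessages(res <- bootstrap_mean_differences(dg, dp, cfg))
  expect_length(res$delta_bars, 1)
  # geodesic matrix identifies everyone in any resample; the pearson one
  # mislabels participants 1 and 2 whenever both are present
  expect_gte(res$delta_bars[1], 0)
})

test_that("the resampling kernel matches a plain-R reference on random index sets", {
  withr::with_seed(4, {
    d12 <- matrix(runif(36), 6, 6)
    d21 <- matrix(runif(36), 6, 6)
    idx <- matrix(sample.int(6, 20 * 6, replace = TRUE), 20, 6)
  })
  kernel <- fcgeodesic:::cpp_resample_accuracy(d12, d21, idx - 1L)
  ref <- apply(idx, 1, function(row) ref_resample_accuracy(d12, d21, row))
  expect_equal(as.numeric(kernel), ref, tolerance = 1e-12)
})

test_that("the Monte-Carlo mean difference matches exhaustive enumeration of all 27 resamples", {
  withr::with_seed(5, {
    g <- matrix(runif(9, 0.1, 1), 3, 3)
    p <- matrix(runif(9, 0.1, 1), 3, 3)
  })
  diag(g)[1] <- 0.01 # make participant 1 identifiable under g only
  dg <- toy_dist(g)
  dp <- toy_dist(p, measure = "pearson")
  # exact expectation: every multiset drawn as an ordered triple is equally
  # likely, so enumerate all 27
  grid <- expand.grid(1:3, 1:3, 1:3)
  exact <- mean(apply(grid, 1, function(idx) {
    ref_resample_accuracy(g, t(g), idx) - ref_resample_accuracy(p, t(p), idx)
  }))
  res <- bootstrap_mean_differences(
    dg, dp, bootstrap_config(M = 200, B = 200, seed = 6)
  )
  se <- stats::sd(res$delta_bars) / sqrt(length(res$delta_bars))
  expect_lte(abs(res$mean_of_means - exact), 3 * se + 1e-12)
})

test_that("bootstrap draws are reproducible and robust to changing B", {
  d <- toy_dist(withr::with_seed(7, matrix(runif(25), 5, 5)))
  d2 <- toy_dist(withr::with_seed(8, matrix(runif(25), 5, 5)),
                 measure = "pearson")
  r1 <- bootstrap_mean_differences(d, d2, bootstrap_config(M = 10, B = 12, seed = 9))
  r2 <- bootstrap_mean_differences(d, d2, bootstrap_config(M = 10, B = 12, seed = 9))
  expect_identical(r1$delta_bars, r2$delta_bars)
  # growing B keeps the earlier batches' streams
  r3 <- bootstrap_mean_differences(d, d2, bootstrap_config(M = 10, B = 20, seed = 9))
  expect_identical(r3$delta_bars[1:12], r1$delta_bars)
})

test_that("the Fisher-z t-test matches the textbook formula and honours its conventions", {
  v <- c(0.02, 0.03, 0.01, 0.04)
  z <- atanh(v)
  tt <- mean(z) / (stats::sd(z) / sqrt(4))
  p_ref <- 2 * stats::pt(abs(tt), df = 3, lower.tail = FALSE)
  expect_equal(fisher_z_ttest(v), p_ref, tolerance = 1e-12)
  # symmetric values: t = 0, p = 1
  expect_equal(fisher_z_ttest(c(-0.05, 0.05, -0.2, 0.2)), 1, tolerance = 1e-12)
  expect_message(p0 <- fisher_z_ttest(rep(0, 5)), "convention")
  expect_identical(p0, 1)
  expect_message(p1 <- fisher_z_ttest(rep(0.3, 5)), "convention")
  expect_identical(p1, 0)
  expect_error(fisher_z_ttest(0.1), "at least 2")
})

test_that("the segment-length curve reduces to full-run accuracy at full length", {
  cfg <- generator_config(n_participants = 8, n_rois = 6, n_frames = 80,
                          seed = 10)
  study <- generate_study(cfg)
  run1 <- study$timeseries$cond1$run1
  run2 <- study$timeseries$cond1$run2
  expect_warning(
    curve <- segment_length_curve(run1, run2, lengths = 80, n_segments = 50,
                                  boot_iters = 50, measure = "geodesic",
                                  seed = 11),
    "distinct start"
  )
  expect_identical(curve$n_segments, 1L)
  full <- symmetric_accuracy(
    fc_database_from_timeseries(run1),
    fc_database_from_timeseries(run2), "geodesic"
  )
  # the bootstrap mean sits near, not exactly at, the point accuracy
  expect_lte(abs(curve$mean_accuracy - full$mean_accuracy), 0.25)
  expect_error(
    segment_length_curve(run1, run2, lengths = 100, measure = "geodesic"),
    "exceeds"
  )
})

test_that("identification accuracy increases with segment length under strong signal", {
  lengths <- c(20, 60, 150)
  curves <- vapply(1:10, function(rep) {
    cfg <- generator_config(n_participants = 12, n_rois = 6, n_frames = 150,
                            seed = 100 + rep)
    study <- generate_study(cfg)
    curve <- suppressWarnings(segment_length_curve(
      study$timeseries$cond1$run1, study$timeseries$cond1$run2,
      lengths = lengths, n_segments = 8, boot_iters = 50,
      measure = "geodesic", seed = rep
    )) # full-length segments have a single valid start

    curve$mean_accuracy
  }, numeric(3))
  mean_curve <- rowMeans(curves)
  expect_gt(stats::cor(mean_curve, lengths, method = "spearman"), 0)
  expect_gt(mean_curve[3], mean_curve[1])
})
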