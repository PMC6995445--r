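test_that("correlation from time series has unit diagonal and exact +/-1 for colinear ROIs", {
  withr::with_seed(11, {
    base <- rnorm(50)
    ts_pos <- roi_timeseries(cbind(base, base))
    ts_neg <- roi_timeseries(cbind(base, -base))
    ts_rand <- roi_timeseries(matrix(rnorm(50 * 6), 50, 6))
  })
  expect_equal(correlation_from_timeseries(ts_pos)$values[1, 2], 1,
               tolerance = 1e-12)
  expect_equal(correlation_from_timeseries(ts_neg)$values[1, 2], -1,
               tolerance = 1e-12)
  q <- correlation_from_timeseries(ts_rand)
  expect_identical(diag(q$values), rep(1, 6))
  expect_identical(q$regularization_tau, 0)
  expect_no_error(validate_fc_matrix(q))
})

test_that("degenerate time series are rejected with informative errors", {
  withr::with_seed(12, x <- matrix(rnorm(40), 10, 4))
  x[, 3] <- 2.5 # flat ROI
  expect_error(correlation_from_timeseries(roi_timeseries(x)), "3")
  expect_error(roi_timeseries(x[1, , drop = FALSE]), "2 frames")
  xna <- x
  xna[2, 2] <- NA
  expect_error(roi_timeseries(xna), "missing")
})

test_that("FC matrices are positive semidefinite and the cone is closed under positive combinations", {
  for (seed in 1:5) {
    q1 <- random_corr(8, seed = seed)
    q2 <- random_corr(8, seed = seed + 100)
    # quadratic-form check: y' Q y >= 0 up to round-off
    ys <- withr::with_seed(seed, matrix(rnorm(8 * 100), 8, 100))
    expect_true(all(colSums(ys * (q1 %*% ys)) >= -1e-10))
    ab <- withr::with_seed(seed, runif(2, 0.1, 3))
    combo <- ab[1] * q1 + ab[2] * q2
    expect_gte(min(eigen(combo, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("regularization is a no-op on full-rank databases and an exact eigen-shift otherwise", {
  db_full <- toy_database(4, 6, t = 60, seed = 21)
  out <- regularize_database(db_full, tau = 1)
  expect_identical(out$matrices[[1]]$values, db_full$matrices[[1]]$values)
  expect_identical(out$matrices[[1]]$regularization_tau, 0)

  # T < R: rank-deficient sample correlations
  db_def <- withr::with_seed(22, {
    fc_database(lapply(1:4, function(i) {
      correlation_from_timeseries(
        roi_timeseries(matrix(rnorm(5 * 10), 5, 10),
                       participant_id = sprintf("p%02d", i))
      )
    }))
  })
  ev_before <- eigen(db_def$matrices[[2]]$values, symmetric = TRUE,
                     only.values = TRUE)$values
  reg <- regularize_database(db_def, tau = 1)
  ev_after <- eigen(reg$matrices[[2]]$values, symmetric = TRUE,
                    only.values = TRUE)$values
  expect_equal(ev_after, ev_before + 1, tolerance = 1e-12)
  expect_identical(reg$matrices[[2]]$regularization_tau, 1)
})

test_that("geodesic distance after regularization satisfies the metric axioms on all triples", {
  db <- withr::with_seed(23, {
    fc_database(lapply(1:10, function(i) {
      correlation_from_timeseries(
        roi_timeseries(matrix(rnorm(6 * 9), 6, 9),
                       participant_id = sprintf("p%02d", i))
      )
    }))
  })
  reg <- regularize_database(db, tau = 1)
  d <- pairwise_distances(reg, reg, measure = "geodesic")$values
  expect_equal(max(abs(diag(d))), 0, tolerance = 1e-8)
  expect_equal(max(abs(d - t(d))), 0, tolerance = 1e-8)
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-8)
  }
})

test_that("geodesic distance matches its closed forms and is affine invariant", {
  q <- random_corr(7, seed = 31)
  expect_lte(geodesic_distance(q, q), 1e-8)
  expect_equal(geodesic_distance(diag(2), diag(c(exp(2), 1))), 2,
               tolerance = 1e-12)
  # diagonal closed form sqrt(sum log^2(d2/d1))
  withr::with_seed(32, {
    d1 <- runif(5, 0.2, 4)
    d2 <- runif(5, 0.2, 4)
  })
  expect_equal(geodesic_distance(diag(d1), diag(d2)),
               sqrt(sum(log(d2 / d1)^2)), tolerance = 1e-10)
  # congruence invariance: d(A Q1 A', A Q2 A') = d(Q1, Q2)
  for (seed in 1:5) {
    q1 <- random_spd(6, seed = seed)
    q2 <- random_spd(6, seed = seed + 50)
    a <- withr::with_seed(seed + 200, matrix(rnorm(36), 6, 6))
    expect_equal(
      geodesic_distance(a %*% q1 %*% t(a), a %*% q2 %*% t(a)),
      geodesic_distance(q1, q2),
      tolerance = 1e-6
    )
  }
})

test_that("geodesic distance refuses non-positive-definite input with advice to regularize", {
  singular <- tcrossprod(c(1, 1))  # rank 1
  q <- random_corr(2, seed = 33)
  expect_error(geodesic_distance(singular, q), "regularize")
  expect_error(geodesic_distance(q, singular), "regularize")
  expect_error(geodesic_distance(random_corr(3, seed = 1), q), "mismatch")
})

test_that("pearson dissimilarity matches the scalar-formula oracle and stays in [0, 1]", {
  q <- random_corr(6, seed = 41)
  expect_equal(pearson_dissimilarity(q, q), 0, tolerance = 1e-12)
  # fixed 3x3 pair evaluated against the textbook correlation formula
  q1 <- corr_from_offdiag(c(0.5, 0.2, 0.1), 3)
  q2 <- corr_from_offdiag(c(0.1, 0.4, 0.3), 3)
  expect_equal(pearson_dissimilarity(q1, q2),
               (1 - ref_corr(as.vector(q1), as.vector(q2))) / 2,
               tolerance = 1e-12)
  for (seed in 1:10) {
    a <- random_corr(5, seed = seed)
    b <- random_corr(5, seed = seed + 500)
    dp <- pearson_dissimilarity(a, b)
    expect_gte(dp, 0)
    expect_lte(dp, 1)
    # mean-removal: adding a common constant to all entries does not change it
    expect_equal(pearson_dissimilarity(a + 0.3, b + 0.3), dp,
                 tolerance = 1e-9)
  }
})

test_that("any two distinct 2x2 correlation matrices are Pearson-indistinguishable but geodesically distinct", {
  rhos <- c(-0.9, -0.4, 0, 0.3, 0.8)
  for (r1 in rhos) for (r2 in rhos) {
    if (r1 == r2) next
    expect_equal(pearson_dissimilarity(corr2(r1), corr2(r2)), 0,
                 tolerance = 1e-12)
    expect_gt(geodesic_distance(corr2(r1), corr2(r2)), 1e-3)
  }
})

test_that("pairwise distances agree with looped single-pair calls and obey metric structure", {
  db1 <- toy_database(5, 6, seed = 51, run = 1L)
  db2 <- toy_database(5, 6, seed = 52, run = 2L)
  for (measure in c("geodesic", "pearson")) {
    d <- pairwise_distances(train = db1, test = db2, measure = measure)
    expect_identical(dim(d$values), c(5L, 5L))
    single <- if (measure == "geodesic") geodesic_distance else pearson_dissimilarity
    for (i in 1:5) for (j in 1:5) {
      expect_equal(d$values[i, j],
                   single(db2$matrices[[i]], db1$matrices[[j]]),
                   tolerance = 1e-10)
    }
  }
  # test == train under the geodesic: symmetric with zero diagonal
  dg <- pairwise_distances(db1, db1, measure = "geodesic")
  expect_equal(dg$values, t(dg$values), tolerance = 1e-8)
  expect_equal(max(abs(diag(dg$values))), 0, tolerance = 1e-8)
  # 1x1 databases give the scalar measure
  one1 <- fc_database(db1$matrices[1])
  one2 <- fc_database(db2$matrices[1])
  expect_equal(
    pairwise_distances(one1, one2, "geodesic")$values[1, 1],
    geodesic_distance(db2$matrices[[1]], db1$matrices[[1]])
  )
})

test_that("the C++ geodesic kernel agrees with the plain-R eigendecomposition route", {
  db1 <- toy_database(4, 8, seed = 61)
  db2 <- toy_database(4, 8, seed = 62)
  d <- pairwise_distances(train = db1, test = db2, measure = "geodesic")
  for (i in 1:4) for (j in 1:4) {
    expect_equal(d$values[i, j],
                 ref_geodesic(db2$matrices[[i]]$values, db1$matrices[[j]]$values),
                 tolerance = 1e-10)
  }
})
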