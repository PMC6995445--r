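make_ts <- function(t, r = 3, tr = 1, seed = 1) {
  withr::with_seed(seed, roi_timeseries(matrix(rnorm(t * r), t, r),
                                        tr_seconds = tr))
}

test_that("uncued block trimming drops the hemodynamic lag and keeps the post-block tail", {
  ts <- make_ts(40, tr = 1)
  sched <- block_schedule(onsets = 0, offsets = 20, tr_seconds = 1)
  out <- trim_task_blocks(ts, sched)
  # frames [0+4, 20+4) = 4..23 (0-based)
  expect_identical(out$data, ts$data[5:24, ])
  # clipped at run end when the tail would overhang
  ts_short <- make_ts(22, tr = 1)
  out2 <- trim_task_blocks(ts_short, sched)
  expect_identical(out2$data, ts_short$data[5:22, ])
  # original input untouched
  expect_identical(nrow(ts$data), 40L)
})

test_that("cued blocks start 12 s after cue onset and end 3 s after block end", {
  tr <- 0.8
  ts <- make_ts(100, tr = tr, seed = 3)
  sched <- block_schedule(onsets = 8, offsets = 40, has_cue = TRUE,
                          tr_seconds = tr)
  out <- trim_task_blocks(ts, sched)
  from <- ceiling((8 + 12) / tr)       # 25
  to <- ceiling(40 / tr) + round(3 / tr) # 50 + 4 = 54
  expect_identical(out$data, ts$data[(from + 1):to, ])
})

test_that("a multi-block schedule yields exactly the hand-enumerated frames", {
  tr <- 0.72
  ts <- make_ts(300, tr = tr, seed = 4)
  sched <- block_schedule(
    onsets = c(10, 60, 120), offsets = c(40, 100, 150),
    has_cue = c(TRUE, FALSE, TRUE), tr_seconds = tr
  )
  out <- trim_task_blocks(ts, sched)
  expected <- integer(0)
  for (b in 1:3) {
    if (sched$has_cue[b]) {
      from <- ceiling((sched$onsets[b] + 12) / tr)
      to <- ceiling(sched$offsets[b] / tr) + round(3 / tr)
    } else {
      from <- ceiling(sched$onsets[b] / tr) + 4
      to <- ceiling(sched$offsets[b] / tr) + 4
    }
    expected <- c(expected, seq.int(from, min(to, 300) - 1L))
  }
  expected <- unique(expected)
  expect_identical(nrow(out$data), length(expected))
  expect_identical(out$data, ts$data[expected + 1L, ])
})

test_that("trimming rejects empty schedules and blocks past the run end", {
  ts <- make_ts(30, tr = 1)
  expect_error(
    trim_task_blocks(ts, block_schedule(numeric(0), numeric(0),
                                        logical(0), tr_seconds = 1)),
    "no task frames"
  )
  expect_error(
    trim_task_blocks(ts, block_schedule(0, 45, tr_seconds = 1)),
    "past the end"
  )
})

test_that("length equating keeps the centered window, removing the odd frame at the end", {
  ts138 <- make_ts(138)
  expect_identical(equate_length(ts138, 138)$data, ts138$data)
  ts140 <- make_ts(140)
  expect_identical(equate_length(ts140, 138)$data, ts140$data[2:139, ])
  ts141 <- make_ts(141)
  expect_identical(equate_length(ts141, 138)$data, ts141$data[2:139, ])
  expect_error(equate_length(make_ts(100), 138), "fewer than target")
})

test_that("random segments have distinct starts, cover the valid range, and are seed-reproducible", {
  ts <- make_ts(1200, r = 2, seed = 7)
  segs <- sample_segments(ts, seg_len = 100, n_segments = 50, seed = 99)
  expect_length(segs, 50)
  starts <- vapply(segs, attr, integer(1), "start_frame")
  expect_false(anyDuplicated(starts) > 0)
  expect_true(all(starts >= 0 & starts <= 1100))
  expect_true(all(vapply(segs, function(s) nrow(s$data), integer(1)) == 100))
  segs2 <- sample_segments(ts, seg_len = 100, n_segments = 50, seed = 99)
  expect_identical(starts, vapply(segs2, attr, integer(1), "start_frame"))
  # full-length segment: exactly one valid start
  full <- sample_segments(ts, seg_len = 1200, n_segments = 1, seed = 1)
  expect_length(full, 1)
  expect_identical(full[[1]]$data, ts$data)
  # graceful degradation with a warning when starts run out
  expect_warning(
    short <- sample_segments(make_ts(30), seg_len = 25, n_segments = 50, seed = 1),
    "distinct start"
  )
  expect_length(short, 6)
})

test_that("the seven-subnetwork parcellation has the published sizes summing to 300", {
  parc <- cortical_parcellation_300()
  sizes <- table(factor(parc$roi_labels, levels = parc$network_names))
  expect_identical(
    as.integer(sizes),
    c(47L, 57L, 34L, 34L, 20L, 40L, 68L)
  )
  expect_identical(sum(sizes), 300L)
})

test_that("subnetwork selection takes the principal submatrix and preserves PSD", {
  parc <- cortical_parcellation_300()
  q <- fc_matrix(random_corr(300, t = 400, seed = 71))
  sub <- select_subnetworks(q, parc, c("frontoparietal", "default"))
  expect_identical(nrow(sub$values), 108L)
  # identity when all seven networks are requested
  all7 <- select_subnetworks(q, parc, parc$network_names)
  expect_identical(all7$values, q$values)
  # principal submatrices of SPD matrices stay PSD
  small_parc <- parcellation(rep(c("a", "b"), each = 6))
  for (seed in 1:20) {
    m <- fc_matrix(stats::cov2cor(random_spd(12, seed = seed)))
    s <- select_subnetworks(m, small_parc, "a")
    expect_no_error(validate_fc_matrix(s))
  }
  expect_error(select_subnetworks(q, parc, "cerebellum"), "valid names")
})

test_that("subnetwork selection on time series keeps ROI order and propagates to correlations", {
  parc <- parcellation(c("a", "b", "a", "b", "a"))
  ts <- make_ts(60, r = 5, seed = 72)
  sel <- select_subnetworks(ts, parc, "a")
  expect_identical(sel$data, ts$data[, c(1, 3, 5)])
  q_sel <- correlation_from_timeseries(sel)
  q_all <- correlation_from_timeseries(ts)
  expect_equal(q_sel$values,
               select_subnetworks(q_all, parc, "a")$values,
               tolerance = 1e-12)
})

test_that("parcellation and schedule TSV round trips preserve the objects", {
  parc <- cortical_parcellation_300()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation_tsv(parc, f)
  expect_identical(read_parcellation_tsv(f)$roi_labels, parc$roi_labels)
  sf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("onset_s\toffset_s\thas_cue", "0\t20\t0", "30\t50\t1"), sf)
  sched <- read_block_schedule_tsv(sf, tr_seconds = 0.72)
  expect_identical(sched$has_cue, c(FALSE, TRUE))
  expect_identical(sched$tr_seconds, 0.72)
})
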