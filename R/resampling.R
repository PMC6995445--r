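#' Bootstrap configuration
#'
#' The group of participants, not the individual, is the unit of inference
#' in identification experiments: whether a participant is identified
#' depends on who else is in the database.  Variability is therefore
#' assessed over bootstrap resamples of the whole group.  `M` resamples are
#' averaged into one mean score, and that process is repeated `B` times to
#' obtain the distribution of *mean* scores.
#'
#' @param M Resamples per mean (default 1000).
#' @param B Number of mean scores (default 1000).
#' @param seed Master integer seed; per-batch streams are derived from it.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(M = 1000L, B = 1000L, seed = 1L) {
  M <- as.integer(M)
  B <- as.integer(B)
  if (is.na(M) || M < 1L || is.na(B) || B < 1L) stop("'M' and 'B' must be >= 1")
  structure(list(M = M, B = B, seed = as.integer(seed)),
            class = "bootstrap_config")
}

# A distance "pair" is both run directions of one measure.  Accept either a
# list(d12, d21) of distance_matrix objects or a single (symmetric-measure)
# cross-run matrix, in which case the transpose serves the reversed
# direction.  Returns list(d12 = values, d21 = values, ids).
as_direction_pair <- function(d) {
  if (inherits(d, "distance_matrix")) {
    d <- list(d, distance_matrix(t(d$values), d$measure, d$col_ids, d$row_ids))
  }
  if (!is.list(d) || length(d) != 2L ||
      !all(vapply(d, inherits, logical(1), "distance_matrix"))) {
    stop("expected a distance_matrix or a list of two (both run directions)")
  }
  a <- d[[1L]]; b <- d[[2L]]
  if (nrow(a$values) != ncol(a$values)) {
    stop("bootstrap requires square N x N distance matrices")
  }
  if (!identical(dim(a$values), dim(b$values)) ||
      !identical(a$row_ids, b$col_ids) || !identical(a$col_ids, b$row_ids)) {
    stop("the two run directions do not share identifiers")
  }
  list(d12 = a$values, d21 = b$values, ids = a$row_ids)
}

# draw an M x N matrix of 0-based resample indices under an isolated seed
resample_indices <- function(seed, M, N) {
  withr::with_seed(seed, {
    matrix(sample.int(N, M * N, replace = TRUE) - 1L, nrow = M)
  })
}

derive_seeds <- function(master, n) {
  withr::with_seed(master, sample.int(.Machine$integer.max, n))
}

#' Symmetric 1-NN accuracy on bootstrap resamples
#'
#' For each resample — a with-replacement redraw of the `N` participants —
#' the symmetric identification accuracy is recomputed on the resampled
#' rows and columns of the *precomputed* distance matrices.  Duplicated
#' participants enter with multiplicity: each copy is a test item, and a
#' prediction is correct when the nearest train column belongs to the same
#' original participant (any copy).  No distance is ever recomputed inside
#' the resampling loop.
#'
#' @param dist A [distance_matrix()] (cross-run, symmetric measure) or a
#'   list of two for the two run directions.
#' @param cfg A [bootstrap_config()]; `M * B` resamples are drawn in `B`
#'   batches and the mean accuracy of each batch is returned.
#' @return List with `means` (length `B`) and `cfg`.
#' @export
bootstrap_accuracy <- function(dist, cfg = bootstrap_config()) {
  p <- as_direction_pair(dist)
  n <- length(p$ids)
  seeds <- derive_seeds(cfg$seed, cfg$B)
  means <- vapply(seq_len(cfg$B), function(b) {
    idx <- resample_indices(seeds[b], cfg$M, n)
    mean(cpp_resample_accuracy(p$d12, p$d21, idx))
  }, numeric(1))
  list(means = means, cfg = cfg)
}

#' Two-level bootstrap of the accuracy difference between measures
#'
#' The quantity of interest is `delta(R) = f_G(R) - f_P(R)`, the difference
#' between geodesic-based and Pearson-based symmetric identification
#' accuracy on a bootstrap resample `R` of the participant group.  `M`
#' resamples give one mean difference `delta_bar`; repeating `B` times
#' yields the distribution of mean differences, which is tested against
#' zero with [fisher_z_ttest()].  The same resampled groups are used for
#' both measures, so comparing a measure with itself gives every
#' `delta_bar` exactly 0.
#'
#' @param dist_g,dist_p Distance matrices (or direction pairs, see
#'   [bootstrap_accuracy()]) for the two measures, over the same
#'   participants.
#' @param cfg A [bootstrap_config()].
#' @param transform Fisher-z policy for the t-test: `"differences"`
#'   (default) arctanh-transforms the mean difference scores;
#'   `"accuracies"` arctanh-transforms each accuracy before differencing.
#' @return An object of class `bootstrap_result`: list with `delta_bars`
#'   (length `B`), `mean_of_means`, `p_value` and `cfg`.
#' @export
bootstrap_mean_differences <- function(dist_g, dist_p,
                                       cfg = bootstrap_config(),
                                       transform = c("differences", "accuracies")) {
  transform <- match.arg(transform)
  g <- as_direction_pair(dist_g)
  p <- as_direction_pair(dist_p)
  if (length(g$ids) != length(p$ids)) {
    stop("the two measures cover different numbers of participants")
  }
  if (!identical(g$ids, p$ids)) {
    stop("the two measures do not share participant identifiers")
  }
  n <- length(g$ids)
  seeds <- derive_seeds(cfg$seed, cfg$B)
  delta_bars <- vapply(seq_len(cfg$B), function(b) {
    idx <- resample_indices(seeds[b], cfg$M, n)
    fg <- cpp_resample_accuracy(g$d12, g$d21, idx)
    fp <- cpp_resample_accuracy(p$d12, p$d21, idx)
    if (transform == "accuracies") {
      mean(atanh(clip_unit(fg)) - atanh(clip_unit(fp)))
    } else {
      mean(fg - fp)
    }
  }, numeric(1))
  pv <- if (cfg$B < 2L) {
    NA_real_ # a single mean difference carries no variability information
  } else if (transform == "accuracies") {
    plain_ttest(delta_bars)
  } else {
    fisher_z_ttest(delta_bars)
  }
  structure(
    list(delta_bars = delta_bars, mean_of_means = mean(delta_bars),
         p_value = pv, cfg = cfg, transform = transform),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> B = %d mean differences: mean %.4f, p = %.3g\n",
    length(x$delta_bars), x$mean_of_means, x$p_value
  ))
  invisible(x)
}

clip_unit <- function(x, eps = 1e-12) pmin(pmax(x, -(1 - eps)), 1 - eps)

plain_ttest <- function(z) {
  n <- length(z)
  s <- stats::sd(z)
  if (s == 0) return(if (all(z == 0)) 1 else 0)
  tt <- mean(z) / (s / sqrt(n))
  2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE)
}

#' Fisher-z one-sample t-test on mean difference scores
#'
#' Accuracy differences are bounded percentages, so the scores are first
#' mapped through the Fisher-z (arctanh) transform (values clipped to
#' `1 - 1e-12` in magnitude) to make their distribution approximately
#' normal, then a two-tailed one-sample t-test of the null hypothesis that
#' the mean is zero is applied.  Degenerate zero-variance inputs use the
#' convention p = 1 when all values are 0 and p = 0 otherwise (with a
#' message).
#'
#' @param delta_bars Numeric vector of at least 2 mean difference scores.
#' @return The two-tailed p-value.
#' @export
fisher_z_ttest <- function(delta_bars) {
  if (length(delta_bars) < 2L) stop("need at least 2 values")
  z <- atanh(clip_unit(delta_bars))
  if (stats::sd(z) == 0) {
    if (all(delta_bars == 0)) {
      message("all difference scores are exactly 0; p = 1 by convention")
      return(1)
    }
    message("all difference scores identical and nonzero; p = 0 by convention")
    return(0)
  }
  stats::t.test(z, mu = 0, alternative = "two.sided")$p.value
}

#' Identification accuracy as a function of segment length
#'
#' For each requested length `L`, [sample_segments()] draws `n_segments`
#' random contiguous windows per run (matched window per participant within
#' a segment draw), FC matrices are built from the windows, and the
#' bootstrap mean accuracy of each segment is computed with `boot_iters`
#' resamples of the participant group.  The mean and standard error across
#' segments are reported per length.
#'
#' @param run1,run2 Lists of [roi_timeseries()] (one per participant, same
#'   order and identifiers in both runs).
#' @param lengths Integer vector of segment lengths, each `<=` the shortest
#'   run.
#' @param n_segments Segments per length (default 50).
#' @param boot_iters Bootstrap resamples per segment (default 1000).
#' @param measure `"geodesic"` or `"pearson"`.
#' @param seed Master seed.
#' @param tau,eig_tol Regularization parameters (geodesic only).
#' @return A data frame with columns `length`, `mean_accuracy`, `se` and
#'   `n_segments`.
#' @export
segment_length_curve <- function(run1, run2, lengths, n_segments = 50L,
                                 boot_iters = 1000L,
                                 measure = c("geodesic", "pearson"),
                                 seed = 1L, tau = 1, eig_tol = NULL) {
  measure <- match.arg(measure)
  t_min <- min(vapply(c(run1, run2), n_frames, integer(1)))
  if (max(lengths) > t_min) {
    stop("max segment length ", max(lengths),
         " exceeds the shortest run (", t_min, " frames)")
  }
  seeds <- derive_seeds(seed, length(lengths))
  rows <- lapply(seq_along(lengths), function(li) {
    l <- as.integer(lengths[li])
    # one start-frame draw per (segment, run): all participants share the
    # window so segments are comparable across participants
    seg_seeds <- derive_seeds(seeds[li], 2L * n_segments + n_segments)
    n_starts <- t_min - l + 1L
    k <- min(n_segments, n_starts)
    if (k < n_segments) {
      warning("length ", l, ": only ", k, " distinct start frames")
    }
    starts1 <- withr::with_seed(seg_seeds[1L], sample.int(n_starts, k) - 1L)
    starts2 <- withr::with_seed(seg_seeds[2L], sample.int(n_starts, k) - 1L)
    seg_acc <- vapply(seq_len(k), function(s) {
      db1 <- fc_database_from_timeseries(lapply(run1, function(ts) {
        replace_ts_data(ts, ts$data[starts1[s] + seq_len(l), , drop = FALSE])
      }))
      db2 <- fc_database_from_timeseries(lapply(run2, function(ts) {
        replace_ts_data(ts, ts$data[starts2[s] + seq_len(l), , drop = FALSE])
      }))
      if (measure == "geodesic") {
        reg <- regularize_database(list(db1, db2), tau = tau, eig_tol = eig_tol)
        db1 <- reg[[1L]]; db2 <- reg[[2L]]
      }
      d <- pairwise_distances(train = db1, test = db2, measure = measure)
      boot <- bootstrap_accuracy(
        d, bootstrap_config(M = boot_iters, B = 1L, seed = seg_seeds[2L + s])
      )
      boot$means[1L]
    }, numeric(1))
    data.frame(
      length = l,
      mean_accuracy = mean(seg_acc),
      se = stats::sd(seg_acc) / sqrt(length(seg_acc)),
      n_segments = length(seg_acc)
    )
  })
  do.call(rbind, rows)
}
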