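#' Synthetic study configuration
#'
#' Parameters of the multivariate-normal factor-model generator.  Each
#' (participant, condition) pair gets a ground-truth correlation matrix
#' built from factor loadings `L = L_base + s * L_i + c * L_c`, where
#' `L_base` is shared by everyone, `L_i` is the participant's perturbation
#' (shared across conditions) and `L_c` the condition's (shared across
#' participants).  `subject_effect` (`s`) therefore controls how much
#' participant-specific FC structure there is to fingerprint, and
#' `condition_effect` (`c`) how much conditions reshape it.  Runs of a pair
#' differ only by sampling noise, emulating test-retest structure.
#'
#' The defaults are the strong-signal regime used throughout the package's
#' experiments: 100 participants, 30 ROIs, 600 frames, two runs,
#' `s = 1`, `c = 0.2`, 5 factors, noise floor 0.5.
#'
#' @param n_participants,n_rois,n_frames,n_conditions,n_runs Study shape.
#' @param subject_effect,condition_effect Non-negative perturbation scales.
#' @param n_factors Rank of the shared low-dimensional structure.
#' @param noise_floor Positive diagonal noise added before rescaling to
#'   unit diagonal; keeps every ground-truth matrix strictly positive
#'   definite.
#' @param ar_coefficient Optional AR(1) coefficient for temporally
#'   autocorrelated frames (default 0: independent frames).
#' @param seed Master integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 100L, n_rois = 30L,
                             n_frames = 600L, n_conditions = 1L,
                             n_runs = 2L, subject_effect = 1.0,
                             condition_effect = 0.2, n_factors = 5L,
                             noise_floor = 0.5, ar_coefficient = 0,
                             seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_rois = as.integer(n_rois),
    n_frames = as.integer(n_frames),
    n_conditions = as.integer(n_conditions),
    n_runs = as.integer(n_runs),
    subject_effect = as.numeric(subject_effect),
    condition_effect = as.numeric(condition_effect),
    n_factors = as.integer(n_factors),
    noise_floor = as.numeric(noise_floor),
    ar_coefficient = as.numeric(ar_coefficient),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_participants < 2L) stop("'n_participants' must be >= 2")
    if (n_rois < 2L) stop("'n_rois' must be >= 2")
    if (n_frames < 2L) stop("'n_frames' must be >= 2")
    if (n_conditions < 1L) stop("'n_conditions' must be >= 1")
    if (n_runs < 1L) stop("'n_runs' must be >= 1")
    if (subject_effect < 0) stop("'subject_effect' must be >= 0")
    if (condition_effect < 0) stop("'condition_effect' must be >= 0")
    if (n_factors < 1L) stop("'n_factors' must be >= 1")
    if (noise_floor <= 0) stop("'noise_floor' must be > 0")
    if (abs(ar_coefficient) >= 1) stop("'ar_coefficient' must be in (-1, 1)")
  })
  structure(cfg, class = "generator_config")
}

participant_ids <- function(cfg) sprintf("p%03d", seq_len(cfg$n_participants))
condition_ids <- function(cfg) sprintf("cond%d", seq_len(cfg$n_conditions))

#' Ground-truth correlation matrices of a synthetic study
#'
#' Builds one strictly positive-definite correlation matrix per
#' (participant, condition) pair via the factor construction described in
#' [generator_config()]: `Sigma_raw = L L' + noise_floor * I` with
#' `L = L_base + s * L_i + c * L_c` (independent standard-normal `R x
#' n_factors` matrices scaled by `1/sqrt(n_factors)`), rescaled to unit
#' diagonal.  With `s = c = 0` all matrices are identical.  Deterministic
#' under the config seed.
#'
#' @param cfg A [generator_config()].
#' @return An object of class `ground_truth`: list with `sigma` (nested
#'   list `[[participant]][[condition]]` of `R x R` matrices), `cfg`.
#' @export
generate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  r <- cfg$n_rois
  f <- cfg$n_factors
  scale <- 1 / sqrt(f)
  withr::with_seed(cfg$seed, {
    l_base <- matrix(stats::rnorm(r * f), r, f) * scale
    l_subj <- lapply(seq_len(cfg$n_participants), function(i) {
      matrix(stats::rnorm(r * f), r, f) * scale
    })
    l_cond <- lapply(seq_len(cfg$n_conditions), function(cc) {
      matrix(stats::rnorm(r * f), r, f) * scale
    })
  })
  pid <- participant_ids(cfg)
  cid <- condition_ids(cfg)
  sigma <- lapply(seq_len(cfg$n_participants), function(i) {
    per_cond <- lapply(seq_len(cfg$n_conditions), function(cc) {
      l <- l_base + cfg$subject_effect * l_subj[[i]] +
        cfg$condition_effect * l_cond[[cc]]
      s_raw <- tcrossprod(l) + diag(cfg$noise_floor, r)
      stats::cov2cor(s_raw)
    })
    names(per_cond) <- cid
    per_cond
  })
  names(sigma) <- pid
  structure(list(sigma = sigma, cfg = cfg), class = "ground_truth")
}

#' Simulate one run from a ground-truth correlation matrix
#'
#' Draws `n_frames` frames from a zero-mean multivariate normal with the
#' given covariance, via the Cholesky transform of standard normals.  With
#' a nonzero `ar_coefficient` the underlying standard normals follow an
#' AR(1) process (stationary unit variance), giving temporally
#' autocorrelated frames with the same spatial covariance.
#'
#' @param sigma Positive-definite `R x R` covariance (or correlation)
#'   matrix.
#' @param n_frames Number of frames to draw.
#' @param seed Integer seed.
#' @param participant_id,condition,run,tr_seconds Metadata for the returned
#'   series.
#' @param ar_coefficient AR(1) coefficient in `(-1, 1)`, default 0.
#' @return An [roi_timeseries()] of `n_frames x R`.
#' @export
simulate_run <- function(sigma, n_frames, seed = 1L, participant_id = "p1",
                         condition = "cond1", run = 1L, tr_seconds = NULL,
                         ar_coefficient = 0) {
  sigma <- as.matrix(sigma)
  r <- nrow(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) {
    stop("'sigma' is not positive definite: ", conditionMessage(e),
         call. = FALSE)
  })
  z <- withr::with_seed(seed, matrix(stats::rnorm(n_frames * r), n_frames, r))
  if (ar_coefficient != 0) {
    phi <- ar_coefficient
    for (t in 2:n_frames) {
      z[t, ] <- phi * z[t - 1L, ] + sqrt(1 - phi^2) * z[t, ]
    }
  }
  roi_timeseries(z %*% ch,
    participant_id = participant_id, condition = condition,
    run = run, tr_seconds = tr_seconds
  )
}

#' Generate a full synthetic study
#'
#' For every participant, condition and run, simulates an independent run
#' from that (participant, condition) ground-truth matrix; runs of a pair
#' share the same ground truth and differ only by sampling noise.
#'
#' @param cfg A [generator_config()].
#' @param truth Optional precomputed [generate_ground_truth()] result.
#' @return An object of class `synthetic_study`: list with `timeseries`
#'   (nested list `[[condition]][[run]]` of per-participant
#'   [roi_timeseries()] lists), `truth` and `cfg`.
#' @export
generate_study <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(truth)) truth <- generate_ground_truth(cfg)
  pid <- participant_ids(cfg)
  cid <- condition_ids(cfg)
  n_units <- cfg$n_participants * cfg$n_conditions * cfg$n_runs
  run_seeds <- derive_seeds(cfg$seed + 1L, n_units)
  dim(run_seeds) <- c(cfg$n_participants, cfg$n_conditions, cfg$n_runs)
  ts <- lapply(seq_len(cfg$n_conditions), function(cc) {
    per_run <- lapply(seq_len(cfg$n_runs), function(k) {
      per_part <- lapply(seq_len(cfg$n_participants), function(i) {
        simulate_run(
          truth$sigma[[i]][[cc]], cfg$n_frames,
          seed = run_seeds[i, cc, k], participant_id = pid[i],
          condition = cid[cc], run = k,
          ar_coefficient = cfg$ar_coefficient
        )
      })
      names(per_part) <- pid
      per_part
    })
    names(per_run) <- paste0("run", seq_len(cfg$n_runs))
    per_run
  })
  names(ts) <- cid
  structure(list(timeseries = ts, truth = truth, cfg = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d participants x %d condition(s) x %d run(s), %d frames x %d ROIs\n",
    x$cfg$n_participants, x$cfg$n_conditions, x$cfg$n_runs,
    x$cfg$n_frames, x$cfg$n_rois
  ))
  invisible(x)
}

#' FC databases of a synthetic study
#'
#' Applies [correlation_from_timeseries()] to every run of a study and
#' returns the per-condition run databases in the shape expected by
#' [symmetric_accuracy()] and [transfer_matrix()].
#'
#' @param study A [generate_study()] result.
#' @return Named list: condition -> `list(run1 = fc_database, run2 = ...)`.
#' @export
study_fc_databases <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  lapply(study$timeseries, function(per_run) {
    lapply(per_run, fc_database_from_timeseries)
  })
}
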