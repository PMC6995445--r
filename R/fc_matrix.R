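#' Functional connectivity matrix
#'
#' An `fc_matrix` holds an `R x R` symmetric positive-semidefinite matrix of
#' pairwise Pearson correlations between ROI time series, plus metadata.
#' Correlation (and covariance) matrices are positive semidefinite:
#' `y' Q y >= 0` for every vector `y`, so FC matrices live on the cone of
#' positive-semidefinite matrices, which is closed under positive linear
#' combinations.  `regularization_tau` records any identity perturbation
#' `tau * I` that was added to make the matrix strictly positive definite
#' (0 means none).
#'
#' @param values Numeric `R x R` symmetric matrix.
#' @param participant_id,condition,run Metadata, as in [roi_timeseries()].
#' @param regularization_tau Non-negative scalar recording the identity
#'   perturbation already applied to `values`.
#'
#' @return An object of class `fc_matrix`.
#' @seealso [correlation_from_timeseries()], [regularize_database()],
#'   [geodesic_distance()], [pearson_dissimilarity()]
#' @export
fc_matrix <- function(values, participant_id = "p1", condition = "rest",
                      run = 1L, regularization_tau = 0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) stop("FC matrix must be square")
  if (anyNA(values)) stop("FC matrix contains missing values")
  sym_err <- max(abs(values - t(values)))
  if (sym_err > 1e-12 * max(1, max(abs(values)))) {
    stop("FC matrix is not symmetric (max asymmetry ", format(sym_err), ")")
  }
  if (regularization_tau < 0) stop("'regularization_tau' must be >= 0")
  structure(
    list(
      values = (values + t(values)) / 2,
      participant_id = as.character(participant_id),
      condition = as.character(condition),
      run = as.integer(run),
      regularization_tau = as.numeric(regularization_tau)
    ),
    class = "fc_matrix"
  )
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf(
    "<fc_matrix> participant %s, condition %s, run %d: %d x %d (tau = %g)\n",
    x$participant_id, x$condition, x$run, nrow(x$values), ncol(x$values),
    x$regularization_tau
  ))
  invisible(x)
}

#' @export
dim.fc_matrix <- function(x) dim(x$values)

#' Check the FC-matrix invariants
#'
#' Verifies symmetry (relative tolerance 1e-12), positive semidefiniteness
#' (minimum eigenvalue `>= -1e-8`), and — for unregularized correlation
#' matrices — a unit diagonal (within 1e-12).
#'
#' @param q An [fc_matrix()].
#' @param check_unit_diagonal Check the unit diagonal?  Defaults to `TRUE`
#'   when `regularization_tau == 0`.
#' @return `TRUE` invisibly; otherwise an error describing the violated
#'   invariant.
#' @export
validate_fc_matrix <- function(q, check_unit_diagonal = q$regularization_tau == 0) {
  stopifnot(inherits(q, "fc_matrix"))
  v <- q$values
  sym_err <- max(abs(v - t(v)))
  if (sym_err > 1e-12 * max(1, max(abs(v)))) {
    stop("not symmetric: max asymmetry ", format(sym_err))
  }
  ev_min <- min(eigen(v, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    stop("not positive semidefinite: min eigenvalue ", format(ev_min))
  }
  if (isTRUE(check_unit_diagonal) && max(abs(diag(v) - 1)) > 1e-12) {
    stop("diagonal differs from 1 by ", format(max(abs(diag(v) - 1))))
  }
  invisible(TRUE)
}

#' Pearson correlation matrix from an ROI time series
#'
#' Mean-centers each ROI column, scales it to unit variance (the same `1/T`
#' denominator is used for the variances and the covariances, so the
#' diagonal is exactly 1), and returns the matrix of pairwise Pearson
#' correlations `Q = (1/T) * sum_t (x_t - xbar)(x_t - xbar)'` of the
#' normalized series.
#'
#' @param ts An [roi_timeseries()].
#' @return An [fc_matrix()] with `regularization_tau = 0` and the metadata
#'   of `ts`.
#' @export
correlation_from_timeseries <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$data
  if (nrow(x) < 2L) stop("need at least 2 frames to correlate")
  # population (1/T) variances: scale-free for correlation but checked so a
  # flat ROI fails loudly with its index
  v <- colMeans(x^2) - colMeans(x)^2
  bad <- which(v <= 0 | !is.finite(v))
  if (length(bad)) {
    stop("zero-variance ROI column(s): ", paste(bad, collapse = ", "))
  }
  q <- stats::cor(x)
  diag(q) <- 1
  fc_matrix(q,
    participant_id = ts$participant_id, condition = ts$condition,
    run = ts$run, regularization_tau = 0
  )
}

#' Labeled collection of FC matrices
#'
#' An `fc_database` is the train or test side of an identification
#' experiment: an ordered list of [fc_matrix()] objects with parallel
#' participant identifiers, all of the same dimension.
#'
#' @param matrices List of [fc_matrix()] objects.
#' @param participant_ids Optional character vector of identifiers; defaults
#'   to each matrix's own `participant_id`.
#' @param condition,run Optional condition / run labels; default to the
#'   first matrix's metadata.
#' @return An object of class `fc_database`.
#' @export
fc_database <- function(matrices, participant_ids = NULL, condition = NULL,
                        run = NULL) {
  if (!length(matrices)) stop("empty database")
  ok <- vapply(matrices, inherits, logical(1), what = "fc_matrix")
  if (!all(ok)) stop("all elements must be fc_matrix objects")
  dims <- vapply(matrices, function(q) nrow(q$values), integer(1))
  if (length(unique(dims)) != 1L) {
    stop("all FC matrices in a database must have the same dimension")
  }
  if (is.null(participant_ids)) {
    participant_ids <- vapply(matrices, `[[`, character(1), "participant_id")
  }
  if (length(participant_ids) != length(matrices)) {
    stop("'participant_ids' must parallel 'matrices'")
  }
  structure(
    list(
      matrices = matrices,
      participant_ids = as.character(participant_ids),
      condition = condition %||% matrices[[1L]]$condition,
      run = run %||% matrices[[1L]]$run
    ),
    class = "fc_database"
  )
}

#' @export
print.fc_database <- function(x, ...) {
  cat(sprintf(
    "<fc_database> %d participants, condition %s, run %s, %d x %d matrices\n",
    length(x$matrices), x$condition, as.character(x$run),
    nrow(x$matrices[[1L]]$values), nrow(x$matrices[[1L]]$values)
  ))
  invisible(x)
}

#' @export
length.fc_database <- function(x) length(x$matrices)

#' Build an FC database from a list of time series
#'
#' Convenience wrapper: applies [correlation_from_timeseries()] to each run
#' and collects the results.
#'
#' @param ts_list List of [roi_timeseries()] objects (same dimension).
#' @return An [fc_database()].
#' @export
fc_database_from_timeseries <- function(ts_list) {
  fc_database(lapply(ts_list, correlation_from_timeseries))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stack of raw matrices (R x R x N array) for the C++ kernels
db_array <- function(db) {
  r <- nrow(db$matrices[[1L]]$values)
  arr <- array(0, dim = c(r, r, length(db$matrices)))
  for (i in seq_along(db$matrices)) arr[, , i] <- db$matrices[[i]]$values
  arr
}

min_eigenvalue <- function(m) {
  min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
}

#' Identity-perturbation regularization of FC databases
#'
#' Sample correlation matrices estimated from fewer frames than ROIs are
#' rank deficient, and the geodesic distance requires strictly positive
#' definite inputs.  If any matrix across the supplied databases has a
#' minimum eigenvalue below `eig_tol`, `tau * I` is added to *every* matrix
#' (recorded in each matrix's `regularization_tau`), so the distance stays
#' one consistent function across all pairs of the comparison set.
#' Otherwise the databases are returned unchanged.
#'
#' @param dbs A single [fc_database()] or a list of them (the full
#'   comparison set of one experiment).
#' @param tau Positive perturbation scale; the default 1 adds the plain
#'   identity.
#' @param eig_tol Eigenvalue threshold below which a matrix counts as
#'   non-invertible.  Default: `1e-10` times the largest eigenvalue found
#'   across the databases.
#' @return The databases in the same shape as supplied (single database in,
#'   single database out), all with minimum eigenvalue `>= eig_tol`.
#' @export
regularize_database <- function(dbs, tau = 1, eig_tol = NULL) {
  single <- inherits(dbs, "fc_database")
  if (single) dbs <- list(dbs)
  stopifnot(all(vapply(dbs, inherits, logical(1), what = "fc_database")))
  if (tau <= 0) stop("'tau' must be > 0")
  ev_min <- Inf
  ev_max <- -Inf
  for (db in dbs) {
    for (q in db$matrices) {
      ev <- eigen(q$values, symmetric = TRUE, only.values = TRUE)$values
      ev_min <- min(ev_min, ev[length(ev)])
      ev_max <- max(ev_max, ev[1L])
    }
  }
  if (is.null(eig_tol)) eig_tol <- 1e-10 * ev_max
  if (eig_tol < 0) stop("'eig_tol' must be >= 0")
  if (ev_min >= eig_tol) {
    return(if (single) dbs[[1L]] else dbs)
  }
  out <- lapply(dbs, function(db) {
    db$matrices <- lapply(db$matrices, function(q) {
      q$values <- q$values + diag(tau, nrow(q$values))
      q$regularization_tau <- q$regularization_tau + tau
      q
    })
    db
  })
  if (single) out[[1L]] else out
}
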