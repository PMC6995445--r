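#' Geodesic distance between two positive-definite FC matrices
#'
#' Length of the shortest path between `Q1` and `Q2` along the manifold of
#' positive-definite matrices under the affine-invariant metric:
#' `d_G = sqrt(sum_i log^2(lambda_i))`, where `lambda_i` are the eigenvalues
#' of `Q1^{-1/2} Q2 Q1^{-1/2}`.  Equivalently the eigenvalues of the
#' generalized problem `Q2 v = lambda Q1 v`; the eigendecomposition route is
#' used for numerical transparency, with the inner matrix explicitly
#' symmetrized before its eigendecomposition to suppress round-off
#' asymmetry.  `d_G` is a metric: non-negative, zero iff `Q1 == Q2`,
#' symmetric, and satisfying the triangle inequality; it is also invariant
#' under congruence transforms `Q -> A Q A'`.
#'
#' @param q1,q2 [fc_matrix()] objects (or plain symmetric matrices) of the
#'   same dimension, both strictly positive definite — regularize first
#'   (see [regularize_database()]) if they may be rank deficient.
#' @param eig_tol Positivity tolerance: an eigenvalue at or below
#'   `eig_tol` times the largest eigenvalue of the matrix means the input
#'   is treated as non-positive-definite.
#' @return A single non-negative number.
#' @export
geodesic_distance <- function(q1, q2, eig_tol = 1e-10) {
  m1 <- if (inherits(q1, "fc_matrix")) q1$values else as.matrix(q1)
  m2 <- if (inherits(q2, "fc_matrix")) q2$values else as.matrix(q2)
  if (!all(dim(m1) == dim(m2))) {
    stop("dimension mismatch: ", nrow(m1), "x", ncol(m1), " vs ",
         nrow(m2), "x", ncol(m2))
  }
  e1 <- eigen((m1 + t(m1)) / 2, symmetric = TRUE)
  if (min(e1$values) <= eig_tol * max(e1$values)) {
    stop("first matrix is not positive definite (min eigenvalue ",
         format(min(e1$values)),
         "); apply regularize_database() before computing geodesic distances")
  }
  inv_sqrt <- e1$vectors %*% (t(e1$vectors) / sqrt(e1$values))
  inner <- inv_sqrt %*% m2 %*% inv_sqrt
  inner <- (inner + t(inner)) / 2
  lam <- eigen(inner, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) <= eig_tol * max(lam)) {
    stop("second matrix is not positive definite; ",
         "apply regularize_database() before computing geodesic distances")
  }
  sqrt(sum(log(lam)^2))
}

#' Pearson dissimilarity between two FC matrices
#'
#' Stacks the columns of each matrix into a vector and returns
#' `(1 - corr(q1_vec, q2_vec)) / 2`, which lies in `[0, 1]`.  By default the
#' full columns are stacked, diagonal included.  Pearson dissimilarity is
#' *not* a metric (it fails the triangle inequality), and the implicit
#' mean-centering inside the correlation discards the matrices' geometry:
#' any two distinct 2x2 correlation matrices have dissimilarity exactly 0,
#' because both centered stacked vectors are positive multiples of
#' `(1, -1, -1, 1)`.
#'
#' @param q1,q2 [fc_matrix()] objects (or plain matrices) of the same
#'   dimension.
#' @param include_diagonal Stack whole columns (default) or only the
#'   off-diagonal entries.
#' @return A number in `[0, 1]`.
#' @export
pearson_dissimilarity <- function(q1, q2, include_diagonal = TRUE) {
  m1 <- if (inherits(q1, "fc_matrix")) q1$values else as.matrix(q1)
  m2 <- if (inherits(q2, "fc_matrix")) q2$values else as.matrix(q2)
  if (!all(dim(m1) == dim(m2))) {
    stop("dimension mismatch: ", nrow(m1), "x", ncol(m1), " vs ",
         nrow(m2), "x", ncol(m2))
  }
  v1 <- as.vector(m1)
  v2 <- as.vector(m2)
  if (!include_diagonal) {
    off <- as.vector(row(m1) != col(m1))
    v1 <- v1[off]
    v2 <- v2[off]
  }
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("vectorized matrix is constant; Pearson dissimilarity undefined")
  }
  (1 - stats::cor(v1, v2)) / 2
}

#' Distance matrix between two FC databases
#'
#' Entry `(i, j)` is the chosen measure between test matrix `i` and train
#' matrix `j`.  In the identification framework this `N x N` matrix is
#' computed once and every bootstrap resample works purely on its indices,
#' which is what makes the two-level bootstrap feasible.
#'
#' @param train,test [fc_database()] objects of matching dimension.  For
#'   `measure = "geodesic"` every matrix must be strictly positive definite;
#'   apply [regularize_database()] to the pair of databases first when
#'   frames are scarcer than ROIs.
#' @param measure `"geodesic"` or `"pearson"`.
#' @param eig_tol Positivity tolerance passed to the geodesic computation.
#' @param include_diagonal For `measure = "pearson"`: stack whole columns
#'   (default) or off-diagonal entries only.
#' @return An object of class `distance_matrix` with fields `values`
#'   (`N_test x N_train`), `measure`, `row_ids` (test participants) and
#'   `col_ids` (train participants).
#' @export
pairwise_distances <- function(train, test = train,
                               measure = c("geodesic", "pearson"),
                               eig_tol = 1e-10, include_diagonal = TRUE) {
  measure <- match.arg(measure)
  stopifnot(inherits(train, "fc_database"), inherits(test, "fc_database"))
  r <- nrow(train$matrices[[1L]]$values)
  if (nrow(test$matrices[[1L]]$values) != r) {
    stop("train and test databases have different ROI dimensions")
  }
  if (measure == "geodesic") {
    vals <- tryCatch(
      cpp_pairwise_geodesic(db_array(test), db_array(train), eig_tol),
      error = function(e) {
        stop("geodesic distance failed for databases (test condition ",
             test$condition, ", train condition ", train$condition, "): ",
             conditionMessage(e), call. = FALSE)
      }
    )
  } else {
    tv <- vapply(test$matrices, function(q) as.vector(q$values),
                 numeric(r * r))
    rv <- vapply(train$matrices, function(q) as.vector(q$values),
                 numeric(r * r))
    if (!include_diagonal) {
      off <- as.vector(row(diag(r)) != col(diag(r)))
      tv <- tv[off, , drop = FALSE]
      rv <- rv[off, , drop = FALSE]
    }
    sds <- c(apply(tv, 2, stats::sd), apply(rv, 2, stats::sd))
    if (any(sds == 0)) {
      ids <- c(test$participant_ids, train$participant_ids)[sds == 0]
      stop("constant vectorized FC matrix for participant(s): ",
           paste(unique(ids), collapse = ", "))
    }
    vals <- (1 - t(stats::cor(tv, rv))) / 2
    vals <- t(vals)
    # numerical guard: correlations can overshoot [-1, 1] by eps
    vals[vals < 0] <- 0
    vals[vals > 1] <- 1
  }
  distance_matrix(vals, measure = measure,
                  row_ids = test$participant_ids,
                  col_ids = train$participant_ids)
}

#' Construct a distance matrix object
#'
#' @param values Numeric `N_test x N_train` matrix, finite and `>= 0`.
#' @param measure `"geodesic"` or `"pearson"`.
#' @param row_ids,col_ids Test / train participant identifiers.
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(values, measure, row_ids, col_ids) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("distances must be finite")
  if (any(values < 0)) stop("distances must be >= 0")
  if (length(row_ids) != nrow(values) || length(col_ids) != ncol(values)) {
    stop("identifier lengths do not match the matrix")
  }
  dimnames(values) <- list(as.character(row_ids), as.character(col_ids))
  structure(
    list(values = values, measure = measure,
         row_ids = as.character(row_ids), col_ids = as.character(col_ids)),
    class = "distance_matrix"
  )
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %s, %d test x %d train\n",
              x$measure, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.distance_matrix <- function(x) dim(x$values)
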