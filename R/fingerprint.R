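#' 1-nearest-neighbour participant identification
#'
#' Labels each test FC matrix (row of the distance matrix) with the
#' identity of the closest train FC matrix (column argmin).  Ties are
#' broken in favour of the lowest column index, with a warning, so runs are
#' reproducible.
#'
#' @param dist A [distance_matrix()].
#' @return Character vector of predicted train participant identifiers, one
#'   per test row.
#' @export
identify_1nn <- function(dist) {
  stopifnot(inherits(dist, "distance_matrix"))
  v <- dist$values
  if (!length(v)) stop("empty distance matrix")
  n_ties <- 0L
  pred <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    row <- v[i, ]
    j <- which.min(row)
    if (sum(row == row[j]) > 1L) n_ties <- n_ties + 1L
    pred[i] <- dist$col_ids[j]
  }
  if (n_ties > 0L) {
    warning(n_ties, " test item(s) had tied nearest neighbours; ",
            "ties broken by lowest column index")
  }
  pred
}

#' Identification accuracy of a prediction
#'
#' Fraction of correctly labeled participants: number correct over total.
#'
#' @param predicted,truth Character vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
identification_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  mean(as.character(predicted) == as.character(truth))
}

#' Symmetric identification accuracy between two runs
#'
#' Performs 1-NN identification with run 1 as the training database and
#' run 2 as the test set, then with the roles reversed, and reports the
#' mean of the two accuracies.  Both supported measures are symmetric in
#' their arguments, so the cross-run distance matrix is computed once and
#' its transpose serves the reversed direction.
#'
#' @param run1,run2 [fc_database()] objects over the same participants
#'   (matched by identifier; `run2` may be ordered differently).
#' @param measure `"geodesic"` or `"pearson"`.
#' @param regularize Apply [regularize_database()] to the pair first (only
#'   relevant for the geodesic measure)?  Default `TRUE`.
#' @param tau,eig_tol Passed to [regularize_database()] /
#'   [pairwise_distances()]; `eig_tol = NULL` uses the regularizer's
#'   relative default and `1e-10` for the distance computation.
#' @return An object of class `identification_result`: list with
#'   `predicted_dir1` (run1 trains, run2 tests), `predicted_dir2`,
#'   `accuracy_dir1`, `accuracy_dir2`, `mean_accuracy`
#'   (`= (accuracy_dir1 + accuracy_dir2)/2`), `measure`, and `dist` (the
#'   cross-run [distance_matrix()], rows = run2 participants, columns =
#'   run1 participants).
#' @export
symmetric_accuracy <- function(run1, run2, measure = c("geodesic", "pearson"),
                               regularize = TRUE, tau = 1, eig_tol = NULL) {
  measure <- match.arg(measure)
  stopifnot(inherits(run1, "fc_database"), inherits(run2, "fc_database"))
  if (!setequal(run1$participant_ids, run2$participant_ids) ||
      anyDuplicated(run1$participant_ids) || anyDuplicated(run2$participant_ids)) {
    stop("the two runs must cover the same set of distinct participants")
  }
  # align run2 to run1's participant order
  run2 <- reorder_database(run2, run1$participant_ids)
  if (regularize && measure == "geodesic") {
    reg <- regularize_database(list(run1, run2), tau = tau, eig_tol = eig_tol)
    run1 <- reg[[1L]]
    run2 <- reg[[2L]]
  }
  d12 <- pairwise_distances(train = run1, test = run2, measure = measure,
                            eig_tol = if (is.null(eig_tol)) 1e-10 else eig_tol)
  # reversed direction: train = run2, test = run1; both measures are
  # symmetric, so this is the transpose
  d21 <- distance_matrix(t(d12$values), measure = measure,
                         row_ids = d12$col_ids, col_ids = d12$row_ids)
  pred1 <- identify_1nn(d12)
  pred2 <- identify_1nn(d21)
  acc1 <- identification_accuracy(pred1, d12$row_ids)
  acc2 <- identification_accuracy(pred2, d21$row_ids)
  structure(
    list(
      predicted_dir1 = pred1, predicted_dir2 = pred2,
      accuracy_dir1 = acc1, accuracy_dir2 = acc2,
      mean_accuracy = (acc1 + acc2) / 2,
      measure = measure, dist = d12
    ),
    class = "identification_result"
  )
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf(
    "<identification_result> %s: run1->run2 %.3f, run2->run1 %.3f, mean %.3f\n",
    x$measure, x$accuracy_dir1, x$accuracy_dir2, x$mean_accuracy
  ))
  invisible(x)
}

reorder_database <- function(db, ids) {
  pos <- match(ids, db$participant_ids)
  if (anyNA(pos)) stop("participants missing from database: ",
                       paste(ids[is.na(pos)], collapse = ", "))
  db$matrices <- db$matrices[pos]
  db$participant_ids <- db$participant_ids[pos]
  db
}

#' Cross-condition transfer of identification accuracy
#'
#' How well does a database acquired under one condition identify
#' participants scanned under another?  Entry `(test_cond, train_cond)` of
#' the returned table is the run-direction-averaged accuracy using the
#' train condition's FC matrices as the database and the test condition's
#' as queries (train run 1 vs test run 2, then train run 2 vs test run 1,
#' averaged).  Diagonal entries equal the within-condition
#' [symmetric_accuracy()].  Row and column means are computed *excluding*
#' the diagonal.  Full-length runs are used as given; equating lengths is
#' the caller's choice.
#'
#' @param dbs Named list: condition -> `list(run1 = fc_database,
#'   run2 = fc_database)`.  All conditions must share the participant set.
#' @param measure `"geodesic"` or `"pearson"`.
#' @param regularize,tau,eig_tol As in [symmetric_accuracy()]; when
#'   regularization triggers it is applied jointly across *all* conditions
#'   so every entry of the table uses the same distance function.
#' @return An object of class `transfer_result`: list with `accuracy`
#'   (test x train matrix), `row_means`, `col_means` (both excluding the
#'   diagonal, `NA` for a single condition) and `measure`.
#' @export
transfer_matrix <- function(dbs, measure = c("geodesic", "pearson"),
                            regularize = TRUE, tau = 1, eig_tol = NULL) {
  measure <- match.arg(measure)
  conds <- names(dbs)
  if (is.null(conds) || any(conds == "")) stop("'dbs' must be a named list")
  ref_ids <- sort(dbs[[1L]]$run1$participant_ids)
  for (cn in conds) {
    for (rn in c("run1", "run2")) {
      ids <- dbs[[cn]][[rn]]$participant_ids
      if (!identical(sort(ids), ref_ids)) {
        stop("condition ", cn, " ", rn,
             " does not cover the shared participant set")
      }
    }
  }
  if (regularize && measure == "geodesic") {
    flat <- unlist(lapply(dbs, function(x) list(x$run1, x$run2)),
                   recursive = FALSE)
    flat <- regularize_database(flat, tau = tau, eig_tol = eig_tol)
    k <- 0L
    for (cn in conds) {
      dbs[[cn]]$run1 <- flat[[k + 1L]]
      dbs[[cn]]$run2 <- flat[[k + 2L]]
      k <- k + 2L
    }
  }
  n <- length(conds)
  acc <- matrix(NA_real_, n, n, dimnames = list(test = conds, train = conds))
  for (te in conds) {
    for (tr in conds) {
      a1 <- one_direction_accuracy(dbs[[tr]]$run1, dbs[[te]]$run2, measure)
      a2 <- one_direction_accuracy(dbs[[tr]]$run2, dbs[[te]]$run1, measure)
      acc[te, tr] <- (a1 + a2) / 2
    }
  }
  off <- function(v, i) if (n > 1L) mean(v[-i]) else NA_real_
  row_means <- vapply(seq_len(n), function(i) off(acc[i, ], i), numeric(1))
  col_means <- vapply(seq_len(n), function(j) off(acc[, j], j), numeric(1))
  names(row_means) <- names(col_means) <- conds
  structure(
    list(accuracy = acc, row_means = row_means, col_means = col_means,
         measure = measure),
    class = "transfer_result"
  )
}

one_direction_accuracy <- function(train, test, measure) {
  d <- pairwise_distances(train = train, test = test, measure = measure)
  identification_accuracy(identify_1nn(d), d$row_ids)
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %s (rows = test condition, cols = train)\n",
              x$measure))
  print(round(x$accuracy, 3))
  invisible(x)
}
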