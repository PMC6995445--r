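#' Dissimilarity matrix for embedding
#'
#' Square symmetric matrix of pairwise dissimilarities (any measure: the
#' affine-invariant geodesic distance, Pearson dissimilarity, ...), with a
#' zero diagonal and non-negative entries.
#'
#' @param values Numeric `K x K` matrix.
#' @param item_ids Identifiers for the `K` items (default from dimnames or
#'   `"item<k>"`).
#' @return An object of class `dissimilarity_matrix`.
#' @export
dissimilarity_matrix <- function(values, item_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("dissimilarity matrix must be square")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("dissimilarities must be finite and >= 0")
  }
  if (max(abs(values - t(values))) > 1e-10 * max(1, max(values))) {
    stop("dissimilarity matrix must be symmetric")
  }
  if (any(diag(values) != 0)) stop("diagonal must be zero")
  if (is.null(item_ids)) {
    item_ids <- rownames(values) %||% paste0("item", seq_len(nrow(values)))
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(item_ids, item_ids)
  structure(list(values = values, item_ids = as.character(item_ids)),
            class = "dissimilarity_matrix")
}

#' Combined train+test dissimilarity matrix
#'
#' Concatenates two FC databases (e.g. both runs of all participants, `2N`
#' items) and computes all pairwise dissimilarities under one measure, the
#' input expected by [nonmetric_mds()].
#'
#' @param dbs List of [fc_database()] objects to concatenate.
#' @param measure `"geodesic"` or `"pearson"`.
#' @param regularize,tau,eig_tol As in [symmetric_accuracy()].
#' @return A [dissimilarity_matrix()] with item ids
#'   `<participant>.<condition>.run<k>`.
#' @export
combined_dissimilarity <- function(dbs, measure = c("geodesic", "pearson"),
                                   regularize = TRUE, tau = 1, eig_tol = NULL) {
  measure <- match.arg(measure)
  if (inherits(dbs, "fc_database")) dbs <- list(dbs)
  if (regularize && measure == "geodesic") {
    dbs <- regularize_database(dbs, tau = tau, eig_tol = eig_tol)
  }
  mats <- unlist(lapply(dbs, `[[`, "matrices"), recursive = FALSE)
  ids <- unlist(lapply(dbs, function(db) {
    sprintf("%s.%s.run%s", db$participant_ids, db$condition, db$run)
  }))
  all_db <- fc_database(mats, participant_ids = ids)
  d <- pairwise_distances(train = all_db, test = all_db, measure = measure)
  v <- d$values
  diag(v) <- 0
  dissimilarity_matrix(v, item_ids = ids)
}

lower_tri <- function(m) m[lower.tri(m)]

#' Normalized stress of an embedding
#'
#' With no disparities: `S = sum_{i<j} (d_ij - dhat_ij)^2 / sum_{i<j}
#' d_ij^2`, where `dhat_ij = ||x_i - x_j||` is the plain (unsquared)
#' Euclidean distance between embedded points.  With disparities supplied
#' (the non-metric case), the input dissimilarities are replaced by the
#' disparity values in both numerator and denominator.
#'
#' @param D A [dissimilarity_matrix()] (or plain symmetric matrix), not
#'   all zero.
#' @param X Numeric `K x dim` matrix of embedded coordinates.
#' @param disparities Optional `K x K` matrix (or vector over the lower
#'   triangle) of monotone disparities.
#' @return A single non-negative number.
#' @export
mds_stress <- function(D, X, disparities = NULL) {
  dv <- if (inherits(D, "dissimilarity_matrix")) D$values else as.matrix(D)
  X <- as.matrix(X)
  if (nrow(X) != nrow(dv)) stop("shapes disagree")
  d <- lower_tri(dv)
  dx <- lower_tri(as.matrix(stats::dist(X)))
  target <- if (is.null(disparities)) {
    d
  } else if (is.matrix(disparities)) {
    lower_tri(disparities)
  } else {
    as.numeric(disparities)
  }
  if (length(target) != length(dx)) stop("disparity length disagrees")
  denom <- sum(target^2)
  if (denom == 0) stop("all-zero dissimilarities: stress undefined")
  sum((target - dx)^2) / denom
}

# weighted pool-adjacent-violators: isotonic least-squares fit of y (already
# sorted by the predictor) with weights w
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  vals <- y
  wts <- w
  idx <- rep.int(seq_len(n), 1L)
  # block representation: vals/wts per block, sizes
  sizes <- rep.int(1L, n)
  nb <- n
  i <- 1L
  while (i < nb) {
    if (vals[i] > vals[i + 1L] + 0) {
      # merge blocks i and i+1
      tw <- wts[i] + wts[i + 1L]
      vals[i] <- (wts[i] * vals[i] + wts[i + 1L] * vals[i + 1L]) / tw
      wts[i] <- tw
      sizes[i] <- sizes[i] + sizes[i + 1L]
      vals <- vals[-(i + 1L)]
      wts <- wts[-(i + 1L)]
      sizes <- sizes[-(i + 1L)]
      nb <- nb - 1L
      if (i > 1L) i <- i - 1L
    } else {
      i <- i + 1L
    }
  }
  rep.int(vals[seq_len(nb)], sizes[seq_len(nb)])
}

# monotone regression of dx on the rank order of d, ties in d averaged:
# tied d-values form one block whose fitted value is the weighted mean of
# their dx.  Returns fitted disparities in the original pair order.
monotone_disparities <- function(d, dx) {
  ord <- order(d)
  d_s <- d[ord]
  dx_s <- dx[ord]
  grp <- cumsum(c(TRUE, diff(d_s) > 0))
  y <- as.numeric(tapply(dx_s, grp, mean))
  w <- as.numeric(tapply(rep(1, length(dx_s)), grp, sum))
  fit_blocks <- pava(y, w)
  fitted_sorted <- fit_blocks[grp]
  out <- numeric(length(d))
  out[ord] <- fitted_sorted
  out
}

# Guttman (majorization) transform: coordinates minimizing
# sum (dhat - dx)^2 over X for fixed disparities, one step
guttman_update <- function(X, dhat_m) {
  k <- nrow(X)
  dx <- as.matrix(stats::dist(X))
  ratio <- matrix(0, k, k)
  pos <- dx > 0
  ratio[pos] <- dhat_m[pos] / dx[pos]
  b <- -ratio
  diag(b) <- rowSums(ratio)
  (b %*% X) / k
}

#' Non-metric multidimensional scaling
#'
#' Embeds a dissimilarity matrix into `dim` Euclidean dimensions using only
#' the rank order of the dissimilarities.  The optimizer alternates a
#' majorization (Guttman transform) update of the coordinates holding the
#' disparities fixed with an isotonic (pool-adjacent-violators, ties
#' averaged) regression of the embedded distances onto the rank order of
#' the input dissimilarities; the disparities are rescaled to the
#' ratio-optimal norm after each fit, which makes the recorded stress
#' non-increasing at every iteration.  The first restart is initialized
#' from classical (Torgerson) scaling — the standard starting
#' configuration — and the remaining restarts from random Gaussian
#' configurations; the restart with the lowest final stress is returned.
#' Depending only on ranks, the result is invariant to uniform rescaling
#' of `D`; the whole computation is performed in a canonical (sorted
#' item-id) order, so permuting `D`'s rows/columns together with their ids
#' permutes the returned points identically.
#'
#' @param D A [dissimilarity_matrix()] with `K >= dim + 1` items.
#' @param dim Embedding dimension (default 3).
#' @param max_iter Maximum iterations per restart (default 1000).
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Number of initializations (default 4; the first is
#'   classical scaling).
#' @param rel_tol Stop when the relative stress change falls below this
#'   (default 1e-8).
#' @return An object of class `mds_embedding`: list with `points`
#'   (`K x dim`, rownames = item ids), `stress` (disparity-normalized, see
#'   [mds_stress()]), `stress_trace` of the winning restart,
#'   `n_iterations_run`, `converged` and `seed`.
#' @export
nonmetric_mds <- function(D, dim = 3L, max_iter = 1000L, seed = 1L,
                          n_restarts = 4L, rel_tol = 1e-8) {
  stopifnot(inherits(D, "dissimilarity_matrix"))
  k <- nrow(D$values)
  if (k < dim + 1L) stop("need at least dim + 1 items")
  # canonical order: computation identical under joint permutation of
  # rows/columns and ids
  can <- order(D$item_ids)
  dv <- D$values[can, can]
  d <- lower_tri(dv)
  if (all(d == 0)) stop("all-zero dissimilarities")
  if (length(unique(d)) == 1L) {
    warning("all off-diagonal dissimilarities are equal; ",
            "the rank order carries no information and the embedding is ",
            "a best effort only")
  }
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    x0 <- if (r == 1L) {
      classical_init(dv, dim)
    } else {
      withr::with_seed(seeds[r],
        matrix(stats::rnorm(k * dim, sd = stats::sd(d)), k, dim))
    }
    fit <- smacof_nonmetric(d, x0, k, max_iter, rel_tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- matrix(NA_real_, k, dim)
  pts[can, ] <- best$X
  rownames(pts) <- D$item_ids
  structure(
    list(points = pts, stress = best$stress,
         stress_trace = best$trace, n_iterations_run = best$iters,
         converged = best$converged, seed = seed),
    class = "mds_embedding"
  )
}

classical_init <- function(dv, dim) {
  k <- nrow(dv)
  fit <- stats::cmdscale(dv, k = dim)
  if (ncol(fit) < dim) {
    fit <- cbind(fit, matrix(0, k, dim - ncol(fit)))
  }
  fit
}

smacof_nonmetric <- function(d, X, k, max_iter, rel_tol) {
  lt <- lower.tri(matrix(0, k, k))
  stress_prev <- Inf
  trace <- numeric(0)
  iters <- 0L
  converged <- FALSE
  dhat <- d
  for (it in seq_len(max_iter)) {
    dx <- lower_tri(as.matrix(stats::dist(X)))
    p <- monotone_disparities(d, dx)
    # ratio-optimal rescaling: PAVA is a cone projection (<dx - p, p> = 0),
    # so dhat = p * sum(dx^2)/sum(p^2) minimizes sum(dx-dhat)^2/sum(dhat^2)
    # over the monotone cone; the recorded stress cannot increase
    sp2 <- sum(p^2)
    if (sp2 == 0) break
    dhat <- p * (sum(dx^2) / sp2)
    dhat_m <- matrix(0, k, k)
    dhat_m[lt] <- dhat
    dhat_m <- dhat_m + t(dhat_m)
    X <- guttman_update(X, dhat_m)
    dx_new <- lower_tri(as.matrix(stats::dist(X)))
    s <- sum((dhat - dx_new)^2) / sum(dhat^2)
    trace <- c(trace, s)
    iters <- it
    if (is.finite(stress_prev) &&
        abs(stress_prev - s) < rel_tol * max(stress_prev, .Machine$double.eps)) {
      converged <- TRUE
      stress_prev <- s
      break
    }
    stress_prev <- s
  }
  list(X = X, stress = stress_prev, trace = trace, iters = iters,
       converged = converged)
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf(
    "<mds_embedding> %d items in %d dimensions, stress %.3g after %d iterations%s\n",
    nrow(x$points), ncol(x$points), x$stress, x$n_iterations_run,
    if (x$converged) " (converged)" else ""
  ))
  invisible(x)
}
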