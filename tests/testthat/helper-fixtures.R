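# fixtures are built in code; all randomness goes through explicit seeds

# random strictly positive-definite matrix of dimension r
random_spd <- function(r, seed = NULL) {
  gen <- function() {
    a <- matrix(rnorm(r * r), r, r)
    crossprod(a) + diag(0.5, r)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# random correlation matrix estimated from a gaussian run of t frames
random_corr <- function(r, t = 10 * r, seed = NULL) {
  gen <- function() stats::cor(matrix(rnorm(t * r), t, r))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# 2x2 correlation matrix with off-diagonal rho
corr2 <- function(rho) matrix(c(1, rho, rho, 1), 2, 2)

# symmetric correlation matrix with given upper-triangle off-diagonals
# (column-wise order), unit diagonal
corr_from_offdiag <- function(off, r) {
  m <- diag(r)
  m[upper.tri(m)] <- off
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# small fc_database of random full-rank correlation matrices
toy_database <- function(n, r, t = 10 * r, seed = 1, condition = "rest",
                         run = 1L) {
  withr::with_seed(seed, {
    mats <- lapply(seq_len(n), function(i) {
      fc_matrix(random_corr(r, t),
        participant_id = sprintf("p%02d", i),
        condition = condition, run = run
      )
    })
    fc_database(mats)
  })
}

# plain-R reference for the geodesic distance (independent of the C++ path)
ref_geodesic <- function(m1, m2) {
  e <- eigen((m1 + t(m1)) / 2, symmetric = TRUE)
  is <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  inner <- is %*% m2 %*% is
  lam <- eigen((inner + t(inner)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(lam)^2))
}

# textbook scalar Pearson correlation (sum formula), used as the oracle for
# pearson_dissimilarity
ref_corr <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# similarity-transform alignment residual (rotation/translation/uniform
# scale): RMS coordinate discrepancy after optimal alignment of B onto A
procrustes_residual <- function(A, B) {
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  s <- svd(t(B) %*% A)
  rot <- s$u %*% t(s$v)
  sc <- sum(s$d) / sum(B^2)
  sqrt(mean((A - sc * B %*% rot)^2))
}

# symmetric 1-NN accuracy computed by plain R loops straight off a distance
# matrix (reference for the C++ resampling kernel); idx is a vector of
# original participant indices (1-based), d12 rows test/cols train
ref_resample_accuracy <- function(d12, d21, idx) {
  n <- length(idx)
  one_dir <- function(d) {
    correct <- 0L
    for (k in seq_len(n)) {
      p <- idx[k]
      j <- which.min(d[p, idx])
      if (idx[j] == p) correct <- correct + 1L
    }
    correct / n
  }
  (one_dir(d12) + one_dir(d21)) / 2
}

# minimal TSV matrix reader for checking CLI artifacts
read_matrix_tsv_for_test <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
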