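# Internal numerical helpers shared across modules.

# QR orthonormalization with the sign convention that makes iterations and
# single-round merges deterministic: the diagonal of R is forced nonnegative
# (column j of Q and row j of R are flipped together). R's qr() may pivot
# columns of near-rank-deficient input, which would silently permute the
# candidate vectors; those rare cases fall back to twice-iterated
# Gram-Schmidt, which preserves column order by construction.
.orthonormalize <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  qrx <- qr(X)
  if (!identical(qrx$pivot, seq_len(ncol(X))))
    return(.mgs(X))
  Q <- qr.Q(qrx)
  R <- qr.R(qrx)
  s <- sign(diag(R))
  s[s == 0] <- 1
  Q <- sweep(Q, 2L, s, "*")
  R <- sweep(R, 1L, s, "*")
  list(Q = Q, R = R)
}

# modified Gram-Schmidt with one re-orthogonalization pass
.mgs <- function(X) {
  k <- ncol(X)
  Q <- X
  R <- matrix(0, k, k)
  for (j in seq_len(k)) {
    v <- Q[, j]
    for (pass in 1:2) {
      for (i in seq_len(j - 1L)) {
        r <- sum(Q[, i] * v)
        R[i, j] <- R[i, j] + r
        v <- v - r * Q[, i]
      }
    }
    R[j, j] <- sqrt(sum(v^2))
    if (R[j, j] == 0)
      .stopf("rank-deficient input to orthonormalization (column %d)", j)
    Q[, j] <- v / R[j, j]
  }
  list(Q = Q, R = R)
}

.max_abs <- function(x) if (length(x)) max(abs(x)) else 0

# ||Q'Q - I||_max, the orthonormality defect used by validators.
.orthonormality_defect <- function(V) {
  .max_abs(crossprod(V) - diag(ncol(V)))
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Draws m points from N(mu, Sigma) via the Cholesky root; `jitter` regularizes
# rank-deficient covariances (single-point or collinear clouds).
.rmvnorm <- function(m, mu, Sigma, jitter = 1e-9) {
  k <- length(mu)
  L <- chol(Sigma + diag(jitter, k))
  Z <- matrix(stats::rnorm(m * k), m, k)
  sweep(Z %*% L, 2L, mu, "+")
}

# Mean silhouette width of integer/character labels in a point cloud.
# Small-n helper for batch-effect demonstrations; mirrors cluster::silhouette
# (which tests use as the independent oracle).
.mean_silhouette <- function(X, labels) {
  labels <- as.character(labels)
  n <- nrow(X)
  stopifnot(length(labels) == n, n >= 2L)
  D <- as.matrix(stats::dist(X))
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { sil[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}
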