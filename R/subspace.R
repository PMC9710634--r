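#' The result of a (federated) PCA: a k-subspace
#'
#' A `subspace` bundles the top-k eigenvectors `V` (columns, orthonormal,
#' over features) and the corresponding eigenvalues of the feature covariance
#' matrix `M = (1/n) A'A`, in nonincreasing order. All algorithms in the
#' package return this container, canonically signed (see [canonical_sign()])
#' so that identical subspaces compare byte-identically.
#'
#' @param vectors `d x k` matrix with orthonormal columns.
#' @param values `k` nonnegative, nonincreasing eigenvalues.
#' @param method Label of the producing algorithm (provenance only).
#' @param ... Further provenance fields stored on the object (e.g.
#'   `iterations`, `converged` for subspace iteration).
#' @return An object of class `subspace`.
#' @export
subspace <- function(vectors, values, method = "unknown", ...) {
  if (!is.matrix(vectors)) vectors <- as.matrix(vectors)
  k <- ncol(vectors)
  if (length(values) != k)
    .stopf("%d eigenvalues for %d eigenvectors", length(values), k)
  if (k > nrow(vectors))
    .stopf("k = %d exceeds the feature dimension d = %d", k, nrow(vectors))
  defect <- .orthonormality_defect(vectors)
  if (defect > 1e-8)
    .stopf("eigenvector columns are not orthonormal (defect %.2e)", defect)
  values <- pmax(values, 0)
  if (is.unsorted(rev(values), strictly = FALSE) &&
      any(diff(values) > 1e-8 * max(values, 1)))
    .stopf("eigenvalues must be nonincreasing")
  structure(c(list(vectors = vectors, values = as.numeric(values), k = k,
                   method = method), list(...)),
            class = "subspace")
}

#' @export
print.subspace <- function(x, ...) {
  cat(sprintf("<subspace> k = %d over %d features (%s)\n",
              x$k, nrow(x$vectors), x$method))
  cat("  eigenvalues:", paste(signif(utils::head(x$values, 6L), 4),
                              collapse = " "),
      if (x$k > 6L) "..." else "", "\n")
  if (!is.null(x$converged) && !isTRUE(x$converged))
    cat("  NOTE: iteration did not converge\n")
  invisible(x)
}

#' Centralized PCA: the reference all federated methods are compared to
#'
#' Computes the top-k eigenpairs of `M = (1/n) A'A` via the singular value
#' decomposition of the (centered) pooled matrix: the right singular vectors
#' of `A` are the eigenvectors of `M`, with eigenvalues `sigma_i^2 / n`. For
#' a centered `n x d` matrix with `d >= n` at most `n - 1` eigenvalues are
#' nonzero, which bounds the meaningful `k`.
#'
#' @param A Centered samples-by-features matrix.
#' @param k Number of components, `k <= min(n, d)`.
#' @return A [subspace()].
#' @examples
#' A <- scale(matrix(rnorm(200), 20, 10), scale = FALSE)
#' s <- centralized_pca(A, k = 3)
#' s$values
#' @export
centralized_pca <- function(A, k) {
  if (!is.matrix(A)) A <- as.matrix(A)
  n <- nrow(A); d <- ncol(A)
  if (!.is_count(k) || k > min(n, d))
    .stopf(paste("k = %s exceeds min(n, d) = %d; an n x d matrix has at most",
                 "min(n, d) eigenpairs (and a centered one at most n - 1",
                 "nonzero eigenvalues)"), deparse(k), min(n, d))
  sv <- svd(A, nu = 0, nv = k)
  V <- canonical_sign(sv$v[, seq_len(k), drop = FALSE])
  rownames(V) <- colnames(A)
  subspace(V, sv$d[seq_len(k)]^2 / n, method = "centralized")
}
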