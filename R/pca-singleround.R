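#' Local truncated SVD summary of a site block
#'
#' The client-side computation of the approximate subspace-aggregation
#' methods: the top `k'` right singular vectors and singular values of the
#' site's (centered) block `A_s`. The requested intermediate dimensionality
#' is truncated to `min(n_s, d)` with a warning — a site with 20 samples and
#' 20000 features can contribute at most 20 components.
#'
#' @param A_s Numeric site block, `n_s x d`.
#' @param k_prime Requested number of local components (`k' >= 1`).
#' @param site Optional site index, stored for provenance.
#' @return An object of class `local_summary` with fields `site`, `v`
#'   (`d x k'` orthonormal columns) and `d` (the `k'` singular values).
#' @export
local_subspace <- function(A_s, k_prime, site = NA_integer_) {
  if (!is.matrix(A_s)) A_s <- as.matrix(A_s)
  if (nrow(A_s) < 1L) .stopf("empty site block")
  if (!.is_count(k_prime)) .stopf("`k_prime` must be a positive integer")
  k_eff <- min(k_prime, nrow(A_s), ncol(A_s))
  if (k_eff < k_prime)
    .warnf("site %s: k' = %d truncated to %d (= min(n_s, d))",
           as.character(site), k_prime, k_eff)
  sv <- svd(A_s, nu = 0, nv = k_eff)
  structure(list(site = site,
                 v = sv$v[, seq_len(k_eff), drop = FALSE],
                 d = sv$d[seq_len(k_eff)]),
            class = "local_summary")
}

#' Merge local summaries into a proxy covariance matrix
#'
#' Aggregator-side reconstruction used by AP-COV: each site's truncated SVD
#' summary is expanded to a rank-k' proxy of its Gram matrix,
#' `V_s diag(sigma_s^2) V_s'`, and the proxies are summed element-wise. With
#' full local rank the proxy equals the exact summed Gram matrix.
#'
#' @param summaries List of [local_subspace()] results sharing `d`.
#' @return A `d x d` symmetric matrix (the unnormalized proxy covariance).
#' @export
merge_proxy_covariance <- function(summaries) {
  stopifnot(length(summaries) >= 1L,
            all(vapply(summaries, inherits, logical(1), "local_summary")))
  d <- nrow(summaries[[1L]]$v)
  M <- matrix(0, d, d)
  for (su in summaries) {
    if (nrow(su$v) != d)
      .stopf("summary for site %s has %d features, expected %d",
             as.character(su$site), nrow(su$v), d)
    M <- M + su$v %*% (su$d^2 * t(su$v))
  }
  (M + t(M)) / 2
}

# shared k validation for the covariance-based methods
.check_k <- function(k, n, d) {
  if (!.is_count(k) || k > min(n, d))
    .stopf(paste("k = %s exceeds min(n, d) = %d; an n x d matrix has at most",
                 "min(n, d) eigenpairs (and a centered one at most n - 1",
                 "nonzero eigenvalues)"), deparse(k), min(n, d))
}

# top-k eigenpairs of an unnormalized symmetric Gram matrix, scaled by 1/n
.gram_to_subspace <- function(M, k, n, feature_ids, method, ...) {
  eg <- eigen(M, symmetric = TRUE)
  V <- canonical_sign(eg$vectors[, seq_len(k), drop = FALSE])
  rownames(V) <- feature_ids
  subspace(V, pmax(eg$values[seq_len(k)], 0) / n, method = method, ...)
}

# one d x k broadcast of the final eigenvectors to every client
.log_broadcast <- function(log, round, S, d, k) {
  if (is.null(log)) return(invisible(NULL))
  for (s in seq_len(S))
    record_message(log, round = round, sender = .AGG, receiver = s,
                   rows = d, cols = k)
}

#' Exact federated PCA by covariance aggregation (P-COV)
#'
#' Each client computes its local Gram matrix `A_s'A_s` (`d x d`) and uploads
#' it; the aggregator sums the local matrices element-wise — which yields the
#' global `A'A` exactly — and eigendecomposes. The result equals the
#' centralized PCA up to sign for any partition, at the price of a `d x d`
#' upload per client.
#'
#' @param partition A centered [site_partition()].
#' @param k Number of components.
#' @param log Optional [comm_log()].
#' @return A [subspace()].
#' @export
p_cov <- function(partition, k, log = NULL) {
  stopifnot(inherits(partition, "site_partition"))
  d <- length(partition$feature_ids)
  n <- sum(site_sizes(partition))
  .check_k(k, n, d)
  grams <- lapply(partition$sites, crossprod)   # client-side
  if (!is.null(log))
    for (s in seq_along(grams))
      record_message(log, round = 1L, sender = s, receiver = .AGG,
                     rows = d, cols = d)
  M <- Reduce(`+`, grams)                       # aggregator
  .log_broadcast(log, 2L, n_sites(partition), d, k)
  .gram_to_subspace(M, k, n, partition$feature_ids, "p-cov")
}

# shared front end of the two approximate subspace-aggregation methods
.ap_summaries <- function(partition, k, k_prime, log) {
  stopifnot(inherits(partition, "site_partition"))
  d <- length(partition$feature_ids)
  n <- sum(site_sizes(partition))
  .check_k(k, n, d)
  if (is.null(k_prime)) k_prime <- max(2L * k, k + 5L)
  if (!.is_count(k_prime) || k < 1L || k > k_prime)
    .stopf("the target dimension k = %d must not exceed the intermediate dimension k' = %s",
           k, deparse(k_prime))
  summaries <- lapply(seq_along(partition$sites), function(s)
    local_subspace(partition$sites[[s]], k_prime, site = s))
  if (all(vapply(summaries, function(su) length(su$d), integer(1)) < k))
    .stopf("k = %d exceeds the effective k' at every site (max %d); the merged proxy cannot have rank k",
           k, max(vapply(summaries, function(su) length(su$d), integer(1))))
  if (!is.null(log))
    for (su in summaries)
      record_message(log, round = 1L, sender = su$site, receiver = .AGG,
                     rows = d + 1L, cols = length(su$d))
  list(summaries = summaries, d = d, n = n)
}

#' Approximate federated PCA via proxy covariance (AP-COV)
#'
#' Each client uploads its top-k' truncated SVD (`d x k'` eigenvectors plus
#' k' singular values); the aggregator reconstitutes a rank-k' proxy of every
#' site's Gram matrix, sums them and eigendecomposes. Transmission drops from
#' `O(d^2)` to `O(dk')`, at the price of an approximation error that shrinks
#' as k' approaches the full local rank.
#'
#' @param partition A centered [site_partition()].
#' @param k Number of components (`k <= k'`).
#' @param k_prime Intermediate dimensionality; default `max(2k, k + 5)`,
#'   truncated per site to `min(n_s, d)`.
#' @param log Optional [comm_log()].
#' @return A [subspace()].
#' @export
ap_cov <- function(partition, k, k_prime = NULL, log = NULL) {
  ap <- .ap_summaries(partition, k, k_prime, log)
  M <- merge_proxy_covariance(ap$summaries)
  .log_broadcast(log, 2L, n_sites(partition), ap$d, k)
  .gram_to_subspace(M, k, ap$n, partition$feature_ids, "ap-cov")
}

#' Approximate federated PCA via subspace stacking (AP-STACK)
#'
#' Same client payload as [ap_cov()], different merge: the aggregator stacks
#' the scaled local subspaces `diag(sigma_s) V_s'` vertically and takes the
#' SVD of the stack. Since the stack's cross-product equals the summed proxy
#' covariance, AP-STACK and AP-COV are numerically equivalent; the stacked
#' form avoids materializing the `d x d` matrix.
#'
#' @inheritParams ap_cov
#' @return A [subspace()].
#' @export
ap_stack <- function(partition, k, k_prime = NULL, log = NULL) {
  ap <- .ap_summaries(partition, k, k_prime, log)
  stack <- do.call(rbind, lapply(ap$summaries, function(su) su$d * t(su$v)))
  sv <- svd(stack, nu = 0, nv = k)
  .log_broadcast(log, 2L, n_sites(partition), ap$d, k)
  V <- canonical_sign(sv$v[, seq_len(k), drop = FALSE])
  rownames(V) <- partition$feature_ids
  subspace(V, sv$d[seq_len(k)]^2 / ap$n, method = "ap-stack")
}

#' Exact federated PCA via QR factorization (QR-PCA)
#'
#' Each client computes a QR factorization of its block and uploads only the
#' triangular factor `R_s` (`min(n_s, d) x d`). The aggregator stacks the
#' factors vertically, re-factorizes the stack, and takes the SVD of the
#' merged triangular factor; since `R''` shares the right singular vectors of
#' `A`, the result is exact for any partition.
#'
#' @inheritParams p_cov
#' @return A [subspace()].
#' @export
qr_pca <- function(partition, k, log = NULL) {
  stopifnot(inherits(partition, "site_partition"))
  d <- length(partition$feature_ids)
  n <- sum(site_sizes(partition))
  .check_k(k, n, d)
  # qr() may pivot columns on rank deficiency; restoring the original order
  # keeps the stacked factors aligned on the shared feature axis (the factor
  # then satisfies F'F = A'A, triangular up to that rare permutation)
  unpivoted_r <- function(X) {
    qrx <- qr(X)
    qr.R(qrx)[, order(qrx$pivot), drop = FALSE]
  }
  rs <- lapply(partition$sites, unpivoted_r)                 # client-side
  if (!is.null(log))
    for (s in seq_along(rs))
      record_message(log, round = 1L, sender = s, receiver = .AGG,
                     rows = nrow(rs[[s]]), cols = d)
  r_stacked <- do.call(rbind, rs)                            # aggregator
  r_merged <- unpivoted_r(r_stacked)
  sv <- svd(r_merged, nu = 0, nv = k)
  .log_broadcast(log, 2L, n_sites(partition), d, k)
  V <- canonical_sign(sv$v[, seq_len(k), drop = FALSE])
  rownames(V) <- partition$feature_ids
  subspace(V, sv$d[seq_len(k)]^2 / n, method = "qr-pca")
}
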