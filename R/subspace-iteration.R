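#' Random orthonormal starting candidate for subspace iteration
#'
#' Entries are drawn i.i.d. standard normal and the matrix is QR
#' orthonormalized (nonnegative-diagonal convention), so the candidate is a
#' deterministic function of the seed.
#'
#' @param d Feature dimension.
#' @param k Number of candidate vectors, `k <= d`.
#' @param seed Integer RNG seed.
#' @return A `d x k` matrix with orthonormal columns.
#' @export
init_candidate <- function(d, k, seed = 0L) {
  if (!.is_count(d) || !.is_count(k) || k > d)
    .stopf("need 1 <= k <= d (got k = %s, d = %s)", deparse(k), deparse(d))
  set.seed(seed)
  .orthonormalize(matrix(stats::rnorm(d * k), d, k))$Q
}

#' Client-side update of one subspace-iteration round
#'
#' Returns `A_s' (A_s V_prev)`: the local block applied to the candidate
#' twice, without ever materializing the `d x d` Gram matrix — peak extra
#' storage is `O(n_s k + d k)`. Summed over sites this equals `(A'A) V_prev`
#' exactly, which is what makes subspace iteration partition-invariant.
#'
#' @param A_s Site block, `n_s x d`.
#' @param V_prev Current candidate, `d x k`.
#' @return A `d x k` matrix.
#' @export
local_update <- function(A_s, V_prev) {
  if (!is.matrix(A_s)) A_s <- as.matrix(A_s)
  if (!is.matrix(V_prev)) V_prev <- as.matrix(V_prev)
  if (ncol(A_s) != nrow(V_prev))
    .stopf("site block has %d features but the candidate has %d rows",
           ncol(A_s), nrow(V_prev))
  crossprod(A_s, A_s %*% V_prev)
}

#' Aggregator-side merge of one subspace-iteration round
#'
#' Element-wise sum of the client updates followed by QR orthonormalization
#' (nonnegative-diagonal sign convention). An all-zero column in the sum
#' means the candidate collapsed into the data's null space and cannot be
#' orthonormalized; re-initialize with a different seed.
#'
#' @param locals List of `d x k` client updates of identical shape.
#' @return A `d x k` orthonormal matrix. The triangular factor of the merge
#'   is attached as attribute `"R"` (its diagonal holds the Rayleigh
#'   quotients of the unnormalized eigenvalues).
#' @export
aggregate_round <- function(locals) {
  stopifnot(is.list(locals), length(locals) >= 1L)
  dims <- vapply(locals, dim, integer(2))
  if (any(dims != dims[, 1L]))
    .stopf("client updates disagree in shape")
  Ssum <- Reduce(`+`, locals)
  if (any(colSums(Ssum^2) == 0))
    .stopf("aggregated update has an all-zero column (degenerate candidate); re-run with a different seed")
  o <- .orthonormalize(Ssum)
  structure(o$Q, R = o$R)
}

#' Federated subspace iteration (SUB-IT)
#'
#' Iterative exact federated PCA: the aggregator broadcasts the current
#' candidate basis, each client returns `A_s'A_s V` computed implicitly, and
#' the aggregator sums and re-orthonormalizes — a block power method on the
#' global covariance that never materializes a `d x d` matrix and exchanges
#' only `d x k` parameters per round.
#'
#' Convergence is declared when the sine of the angle between every
#' candidate column and its predecessor falls below `epsilon` (the sine is
#' computed stably as the norm of the component of the new column orthogonal
#' to the old one, so thresholds near machine precision remain meaningful).
#' Eigenvalues are Rayleigh quotients read off the final merge's triangular
#' factor, divided by `n`.
#'
#' @param partition A centered [site_partition()].
#' @param k Number of components, `k <= min(n, d)`.
#' @param epsilon Termination threshold on the per-column successive sine;
#'   default `1e-9`.
#' @param max_iter Iteration cap; default 1000. Reaching it yields a warning
#'   and `converged = FALSE` on the result.
#' @param seed Seed for the random start; default 0.
#' @param log Optional [comm_log()]; each iteration records one `d x k`
#'   broadcast and one `d x k` upload per client.
#' @return A [subspace()] with extra fields `iterations`, `converged` and
#'   `delta_history` (the per-iteration convergence diagnostic).
#' @examples
#' part <- split_by_sizes(scale(matrix(rnorm(300), 30, 10), scale = FALSE),
#'                        c(10, 20))
#' s <- sub_it(part, k = 2, seed = 1)
#' s$iterations
#' @export
sub_it <- function(partition, k, epsilon = 1e-9, max_iter = 1000L,
                   seed = 0L, log = NULL) {
  stopifnot(inherits(partition, "site_partition"))
  d <- length(partition$feature_ids)
  n <- sum(site_sizes(partition))
  .check_k(k, n, d)
  if (!(is.numeric(epsilon) && length(epsilon) == 1L && epsilon > 0))
    .stopf("`epsilon` must be a positive number")
  if (!.is_count(max_iter)) .stopf("`max_iter` must be a positive integer")
  S <- n_sites(partition)

  V_prev <- init_candidate(d, k, seed)
  deltas <- numeric(0)
  converged <- FALSE
  iter <- 0L
  R_final <- NULL
  repeat {
    iter <- iter + 1L
    if (!is.null(log))
      for (s in seq_len(S))
        record_message(log, round = 2L * iter - 1L, sender = .AGG,
                       receiver = s, rows = d, cols = k)
    locals <- lapply(partition$sites, local_update, V_prev = V_prev)
    if (!is.null(log))
      for (s in seq_len(S))
        record_message(log, round = 2L * iter, sender = s, receiver = .AGG,
                       rows = d, cols = k)
    V <- aggregate_round(locals)
    R_final <- attr(V, "R")
    attr(V, "R") <- NULL
    # per-column sine of the successive angle, stable near zero
    co <- colSums(V * V_prev)
    resid <- V - sweep(V_prev, 2L, co, "*")
    delta <- max(sqrt(colSums(resid^2)))
    deltas <- c(deltas, delta)
    V_prev <- V
    if (delta < epsilon) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    .warnf("subspace iteration stopped at max_iter = %d with delta = %.3e (epsilon = %.1e)",
           max_iter, deltas[length(deltas)], epsilon)

  # Rayleigh quotients v_j' (A'A) v_prev_j = R_jj from the final merge; at
  # convergence v_prev ~ v so this is the eigenvalue of (1/n) A'A.
  values <- diag(R_final)[seq_len(k)] / n
  ord <- order(values, decreasing = TRUE)
  V_out <- canonical_sign(V_prev[, ord, drop = FALSE])
  rownames(V_out) <- partition$feature_ids
  subspace(V_out, values[ord], method = "sub-it",
           iterations = iter, converged = converged, delta_history = deltas,
           epsilon = epsilon, seed = seed)
}
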