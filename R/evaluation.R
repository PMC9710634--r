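#' Angle between two eigenvectors, in degrees
#'
#' `acos` of the absolute normalized dot product, mapped to `[0, 90]`
#' degrees. The absolute value folds the arbitrary sign of eigenvectors: `x`
#' and `-x` span the same axis and get angle 0. The cosine is clamped to
#' `[0, 1]` before `acos` for numerical safety.
#'
#' @param x,y Nonzero numeric vectors of equal length.
#' @return Angle in degrees, in `[0, 90]`.
#' @examples
#' angle_degrees(c(1, 1), c(1, 0))  # 45
#' angle_degrees(c(1, 0), c(-1, 0)) # 0: sign is arbitrary
#' @export
angle_degrees <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) .stopf("angle with a zero vector is undefined")
  co <- min(1, abs(sum(x * y)) / (nx * ny))
  acos(co) * 180 / pi
}

#' Data reconstruction error of a subspace
#'
#' Frobenius norm of `A V V' - A`: the distance between the data and its
#' reconstruction from the k-dimensional projection. By the Eckart-Young
#' theorem the centralized top-k subspace minimizes this quantity.
#'
#' @param A Data matrix, `n x d`.
#' @param V `d x k` matrix with orthonormal columns (a [subspace()] is also
#'   accepted). Non-orthonormal input yields a warning, not an error.
#' @return Nonnegative scalar.
#' @export
reconstruction_error <- function(A, V) {
  if (inherits(V, "subspace")) V <- V$vectors
  if (!is.matrix(A)) A <- as.matrix(A)
  if (ncol(A) != nrow(V))
    .stopf("A has %d features but V has %d rows", ncol(A), nrow(V))
  if (.orthonormality_defect(V) > 1e-6)
    .warnf("V is not orthonormal; the reconstruction error is still computed")
  P <- A %*% V
  sqrt(sum((P %*% t(V) - A)^2))
}

#' Ratio of federated to reference reconstruction error
#'
#' `reconstruction_error(A, V_fed) / reconstruction_error(A, V_ref)`. When
#' the reference is the centralized optimum the ratio is at least 1 (up to
#' rounding); exact federated methods give exactly 1. A zero reference error
#' with a nonzero federated error is reported as `Inf`.
#'
#' @param A Data matrix.
#' @param V_fed,V_ref Subspaces (or orthonormal matrices) of equal k.
#' @return Scalar ratio.
#' @export
reconstruction_ratio <- function(A, V_fed, V_ref) {
  if (inherits(V_fed, "subspace")) V_fed <- V_fed$vectors
  if (inherits(V_ref, "subspace")) V_ref <- V_ref$vectors
  if (ncol(V_fed) != ncol(V_ref))
    .stopf("subspaces have different k (%d vs %d)", ncol(V_fed), ncol(V_ref))
  fed <- reconstruction_error(A, V_fed)
  ref <- reconstruction_error(A, V_ref)
  if (ref == 0) return(if (fed == 0) 1 else Inf)
  fed / ref
}

#' Compare a federated subspace to the centralized reference
#'
#' Pairs eigenvectors by rank order (column j against column j — no
#' re-matching, matching how leading respective eigenvectors are compared in
#' practice) and reports per-eigenvector angles, both reconstruction errors
#' and their ratio.
#'
#' @param s_fed,s_ref [subspace()] objects of equal k.
#' @param A The pooled data matrix both were computed on.
#' @return An object of class `accuracy_report`: `angles_deg` (length k),
#'   `max_angle`, `mean_angle`, `reconstruction_error_fed`,
#'   `reconstruction_error_ref`, `ratio`, plus provenance (`k`, `algorithm`).
#' @export
compare_subspaces <- function(s_fed, s_ref, A) {
  stopifnot(inherits(s_fed, "subspace"), inherits(s_ref, "subspace"))
  if (s_fed$k != s_ref$k)
    .stopf("subspaces have different k (%d vs %d)", s_fed$k, s_ref$k)
  angles <- vapply(seq_len(s_fed$k), function(j)
    angle_degrees(s_fed$vectors[, j], s_ref$vectors[, j]), numeric(1))
  fed <- reconstruction_error(A, s_fed$vectors)
  ref <- reconstruction_error(A, s_ref$vectors)
  structure(list(angles_deg = angles,
                 max_angle = max(angles),
                 mean_angle = mean(angles),
                 reconstruction_error_fed = fed,
                 reconstruction_error_ref = ref,
                 ratio = if (ref == 0) (if (fed == 0) 1 else Inf) else fed / ref,
                 k = s_fed$k,
                 algorithm = s_fed$method,
                 reference = s_ref$method),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %s vs %s (k = %d)\n",
              x$algorithm, x$reference, x$k))
  cat(sprintf("  max angle %.4g deg, mean %.4g deg, reconstruction ratio %.8g\n",
              x$max_angle, x$mean_angle, x$ratio))
  invisible(x)
}

#' Canonical sign convention for eigenvector matrices
#'
#' Eigenvector sign is mathematically arbitrary; for reproducible output each
#' column is flipped so that its largest-magnitude entry is positive (ties
#' broken by the lowest index). Idempotent, and angle metrics are unaffected.
#'
#' @param V Numeric matrix (columns are eigenvectors).
#' @return `V` with canonical column signs.
#' @export
canonical_sign <- function(V) {
  if (!is.matrix(V)) V <- as.matrix(V)
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Closed-form communication cost of a federated PCA run
#'
#' Predicts, per client and in total, the number of transmitted scalars and
#' communication rounds for each algorithm: `d x d` Gram uploads for P-COV,
#' `min(n_s, d) x d` triangular factors for QR-PCA, `(d + 1) k'_s` truncated
#' SVD payloads for the AP methods (eigenvectors plus singular values, with
#' k' capped per site at `min(n_s, d)`), and `d x k` in both directions per
#' iteration for SUB-IT. Every run's [comm_log()] matches these predictions
#' exactly.
#'
#' The downlink is the `d x k` eigenvector broadcast per client. Scalars are
#' counted as 1 each; multiply totals by 8 for bytes at double precision.
#'
#' @param algorithm One of `"p-cov"`, `"ap-cov"`, `"ap-stack"`, `"qr-pca"`,
#'   `"sub-it"`.
#' @param d,k Feature dimension and number of components.
#' @param n_sites Number of clients S.
#' @param k_prime Intermediate dimensionality (AP methods only).
#' @param iterations Iteration count i (SUB-IT only).
#' @param site_sizes Optional per-site sample counts; needed for exact
#'   QR-PCA/AP predictions when some `n_s < d` (resp. `n_s < k'`). When
#'   omitted, all sites are assumed large enough.
#' @return An object of class `cost_prediction`: `per_client_upload` (length
#'   S), `per_client_download` (scalar), `rounds` (N), `total` (T).
#' @export
predicted_comm_cost <- function(algorithm, d, k, n_sites,
                                k_prime = NULL, iterations = NULL,
                                site_sizes = NULL) {
  algorithm <- match.arg(algorithm,
                         c("p-cov", "ap-cov", "ap-stack", "qr-pca", "sub-it"))
  stopifnot(.is_count(d), .is_count(k), .is_count(n_sites))
  S <- n_sites
  if (is.null(site_sizes)) site_sizes <- rep(d, S)
  if (length(site_sizes) != S)
    .stopf("`site_sizes` has length %d, expected %d", length(site_sizes), S)
  down <- d * k
  if (algorithm == "p-cov") {
    up <- rep(d * d, S); rounds <- 2L
  } else if (algorithm == "qr-pca") {
    up <- pmin(site_sizes, d) * d; rounds <- 2L
  } else if (algorithm %in% c("ap-cov", "ap-stack")) {
    if (is.null(k_prime))
      .stopf("%s requires `k_prime`", algorithm)
    kp <- pmin(k_prime, site_sizes, d)
    up <- (d + 1) * kp; rounds <- 2L
  } else { # sub-it
    if (is.null(iterations))
      .stopf("sub-it requires `iterations`")
    stopifnot(.is_count(iterations))
    up <- rep(d * k * iterations, S)
    down <- d * k * iterations
    rounds <- 2L * iterations
  }
  structure(list(algorithm = algorithm,
                 per_client_upload = as.numeric(up),
                 per_client_download = as.numeric(down),
                 rounds = as.integer(rounds),
                 total = as.numeric(sum(up) + S * down)),
            class = "cost_prediction")
}

#' @export
print.cost_prediction <- function(x, ...) {
  cat(sprintf("<cost_prediction> %s: N = %d rounds, T = %s scalars (%s bytes at fp64)\n",
              x$algorithm, x$rounds, format(x$total), format(8 * x$total)))
  invisible(x)
}
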