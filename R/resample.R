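#' Project a site block onto a federated subspace
#'
#' Computes the exact local projections `A_s V` — the per-sample principal
#' component coordinates. Exact projections stay with their site; only
#' resampled surrogates (see [resample_local()]) are shared.
#'
#' @param A_s Site block, `n_s x d`.
#' @param subspace A [subspace()] (or `d x k` orthonormal matrix).
#' @param site Site label stored on the cloud.
#' @return An object of class `projection_cloud` with fields `site`, `points`
#'   (`n_s x k`) and `kind = "exact"`.
#' @export
project_onto <- function(A_s, subspace, site = NA) {
  V <- if (inherits(subspace, "subspace")) subspace$vectors else as.matrix(subspace)
  if (!is.matrix(A_s)) A_s <- as.matrix(A_s)
  if (ncol(A_s) != nrow(V))
    .stopf("site block has %d features but the subspace has %d rows",
           ncol(A_s), nrow(V))
  points <- A_s %*% V
  colnames(points) <- paste0("PC", seq_len(ncol(V)))
  structure(list(site = site, points = points, kind = "exact"),
            class = "projection_cloud")
}

#' Resample a projection cloud from its local Gaussian fit
#'
#' The privacy-aware surrogate for sharing projections: the site fits a
#' multivariate Gaussian to its exact projections (sample mean and sample
#' covariance, with a `1e-9` diagonal jitter for degenerate clouds) and
#' shares `m` draws from it instead of the points themselves. The surrogate
#' preserves the first two moments but contains no original point.
#'
#' @param cloud An exact `projection_cloud` from [project_onto()].
#' @param m Number of artificial points; defaults to the cloud size.
#' @param seed Integer seed; draws are deterministic per seed.
#' @return A `projection_cloud` with `kind = "resampled"`.
#' @export
resample_local <- function(cloud, m = NULL, seed = 0L) {
  stopifnot(inherits(cloud, "projection_cloud"))
  if (cloud$kind != "exact")
    .stopf("can only resample an exact projection cloud")
  P <- cloud$points
  if (is.null(m)) m <- nrow(P)
  if (!.is_count(m)) .stopf("`m` must be a positive integer")
  mu <- colMeans(P)
  Sigma <- if (nrow(P) > 1L) stats::cov(P) else matrix(0, ncol(P), ncol(P))
  set.seed(seed)
  points <- .rmvnorm(m, mu, Sigma)
  colnames(points) <- colnames(P)
  structure(list(site = cloud$site, points = points, kind = "resampled"),
            class = "projection_cloud")
}

#' @export
print.projection_cloud <- function(x, ...) {
  cat(sprintf("<projection_cloud> site %s: %d %s points in %d PCs\n",
              as.character(x$site), nrow(x$points), x$kind, ncol(x$points)))
  invisible(x)
}

#' Assemble one client's view of the global sample distribution
#'
#' A client sees its own exact projections plus only resampled clouds from
#' every other site; passing an exact foreign cloud is rejected — that is the
#' privacy contract of the scheme.
#'
#' @param exact_local The client's own exact `projection_cloud`.
#' @param resampled_others List of resampled clouds from the other sites.
#' @return A data frame with columns `site_id`, `kind`, `PC1..PCk`.
#' @export
assemble_global_view <- function(exact_local, resampled_others = list()) {
  stopifnot(inherits(exact_local, "projection_cloud"),
            exact_local$kind == "exact")
  clouds <- c(list(exact_local), resampled_others)
  k <- ncol(exact_local$points)
  for (cl in resampled_others) {
    stopifnot(inherits(cl, "projection_cloud"))
    if (cl$kind != "resampled")
      .stopf("refusing to include exact projections of site %s in a foreign view",
             as.character(cl$site))
    if (ncol(cl$points) != k)
      .stopf("cloud of site %s has k = %d, expected %d",
             as.character(cl$site), ncol(cl$points), k)
  }
  do.call(rbind, lapply(clouds, function(cl) {
    df <- as.data.frame(cl$points)
    cbind(data.frame(site_id = as.character(cl$site), kind = cl$kind,
                     stringsAsFactors = FALSE),
          df)
  }))
}
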