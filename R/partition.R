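#' Site partitions: horizontally split data
#'
#' A site partition holds the per-site row blocks `A_s` of a global matrix
#' `A`: every site owns a different subset of samples but observes the full,
#' identically ordered feature set. The partition remembers which global rows
#' each site received so that [unsplit_partition()] is an exact inverse.
#'
#' @param sites List of numeric matrices sharing identical colnames.
#' @param row_index Optional list of integer vectors: the global row numbers
#'   of each site block (used to invert a shuffle). Defaults to consecutive.
#' @return An object of class `site_partition` with elements `sites`,
#'   `feature_ids`, `row_index`.
#' @export
site_partition <- function(sites, row_index = NULL) {
  if (!is.list(sites) || length(sites) < 1L)
    .stopf("`sites` must be a non-empty list of matrices")
  sites <- lapply(sites, function(s) {
    if (!is.matrix(s)) s <- matrix(s, nrow = NROW(s))
    s
  })
  if (any(vapply(sites, nrow, integer(1)) < 1L))
    .stopf("every site must hold at least one sample")
  fids <- colnames(sites[[1L]]) %||% paste0("feature_", seq_len(ncol(sites[[1L]])))
  for (s in seq_along(sites)) {
    if (ncol(sites[[s]]) != length(fids))
      .stopf("site %d has %d features, site 1 has %d", s, ncol(sites[[s]]), length(fids))
    sf <- colnames(sites[[s]])
    if (!is.null(sf) && !identical(sf, fids))
      .stopf("site %d feature ids differ from site 1 (same features in the same order required)", s)
    colnames(sites[[s]]) <- fids
  }
  if (is.null(row_index)) {
    ends <- cumsum(vapply(sites, nrow, integer(1)))
    row_index <- Map(seq.int, c(1L, ends[-length(ends)] + 1L), ends)
  }
  stopifnot(length(row_index) == length(sites))
  structure(list(sites = sites, feature_ids = fids, row_index = row_index),
            class = "site_partition")
}

#' @export
print.site_partition <- function(x, ...) {
  sz <- site_sizes(x)
  cat(sprintf("<site_partition> %d sites, %d samples, %d features\n",
              length(sz), sum(sz), length(x$feature_ids)))
  cat("  sizes:", paste(sz, collapse = " "), "\n")
  invisible(x)
}

#' @rdname site_partition
#' @param partition A `site_partition`.
#' @export
n_sites <- function(partition) length(partition$sites)

#' @rdname site_partition
#' @export
site_sizes <- function(partition) vapply(partition$sites, nrow, integer(1))

#' Split a data matrix into sites by block sizes
#'
#' Realizes horizontal partitioning: consecutive row blocks of the given
#' sizes become the per-site matrices. With `shuffle = TRUE` rows are
#' permuted (reproducibly, by `seed`) before slicing, emulating sites whose
#' membership is unrelated to row order; the permutation is stored so that
#' [unsplit_partition()] restores the original matrix exactly.
#'
#' @param A Samples-by-features numeric matrix (see [data_matrix()]).
#' @param sizes Positive integers summing to `nrow(A)`.
#' @param seed Integer seed used only when `shuffle = TRUE`.
#' @param shuffle Permute rows before slicing? Default `FALSE`, so site
#'   blocks map deterministically to row ranges.
#' @return A [site_partition()].
#' @examples
#' A <- data_matrix(matrix(rnorm(20), 10, 2))
#' part <- split_by_sizes(A, c(3, 3, 4))
#' site_sizes(part)
#' @export
split_by_sizes <- function(A, sizes, seed = NULL, shuffle = FALSE) {
  A <- data_matrix(A)
  n <- nrow(A)
  if (any(sizes < 1L) || any(sizes != floor(sizes)))
    .stopf("`sizes` must be positive integers")
  if (sum(sizes) != n)
    .stopf("site sizes sum to %d but the matrix has %d rows", sum(sizes), n)
  perm <- seq_len(n)
  if (isTRUE(shuffle)) {
    if (!is.null(seed)) set.seed(seed)
    perm <- sample.int(n)
  }
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-length(ends)] + 1L)
  row_index <- Map(function(a, b) perm[a:b], starts, ends)
  sites <- lapply(row_index, function(ix) A[ix, , drop = FALSE])
  site_partition(sites, row_index = row_index)
}

#' Reassemble the global matrix from a partition
#'
#' Inverts [split_by_sizes()] (including any shuffle): row `i` of the result
#' is the row that was global row `i` before splitting.
#'
#' @param partition A [site_partition()].
#' @return The pooled samples-by-features matrix.
#' @export
unsplit_partition <- function(partition) {
  stopifnot(inherits(partition, "site_partition"))
  n <- sum(site_sizes(partition))
  d <- length(partition$feature_ids)
  A <- matrix(NA_real_, n, d)
  rn <- character(n)
  for (s in seq_along(partition$sites)) {
    ix <- partition$row_index[[s]]
    A[ix, ] <- partition$sites[[s]]
    rn[ix] <- rownames(partition$sites[[s]]) %||% as.character(ix)
  }
  dimnames(A) <- list(rn, partition$feature_ids)
  A
}

#' Partition a matrix according to a site-assignment table
#'
#' @param A Samples-by-features matrix with rownames.
#' @param assignments Data frame with columns `sample_id` and `site_id`
#'   (see [read_site_assignments()]). Every sample of `A` must appear exactly
#'   once. Sites are ordered by sorted unique `site_id`.
#' @return A [site_partition()].
#' @export
partition_by_assignment <- function(A, assignments) {
  A <- data_matrix(A)
  stopifnot(is.data.frame(assignments),
            all(c("sample_id", "site_id") %in% names(assignments)))
  ids <- rownames(A)
  if (anyDuplicated(assignments$sample_id))
    .stopf("duplicated sample ids in the site assignment")
  missing <- setdiff(ids, assignments$sample_id)
  extra <- setdiff(assignments$sample_id, ids)
  if (length(missing) || length(extra))
    .stopf("site assignment does not cover the matrix exactly (%d samples missing, %d unknown)",
           length(missing), length(extra))
  site_of <- assignments$site_id[match(ids, assignments$sample_id)]
  levels <- sort(unique(as.character(site_of)))
  row_index <- lapply(levels, function(l) which(site_of == l))
  sites <- lapply(row_index, function(ix) A[ix, , drop = FALSE])
  part <- site_partition(sites, row_index = row_index)
  names(part$sites) <- levels
  part
}
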