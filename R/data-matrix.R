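#' Validate a samples-by-features data matrix
#'
#' The global data matrix `A` is an `n x d` numeric matrix: rows are samples
#' (patients, cells), columns are features (genes). `data_matrix()` checks the
#' container invariants used throughout the package (finite entries, matching
#' label counts) and attaches row/column labels.
#'
#' @param values Numeric matrix, `n x d`.
#' @param sample_ids Character vector of `n` row labels. Defaults to existing
#'   rownames, or `sample_1..n`.
#' @param feature_ids Character vector of `d` column labels. Defaults to
#'   existing colnames, or `feature_1..d`.
#' @return The validated matrix with dimnames set.
#' @examples
#' A <- data_matrix(matrix(rnorm(12), 4, 3))
#' dim(A)
#' @export
data_matrix <- function(values, sample_ids = NULL, feature_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("`values` must be a numeric matrix")
  n <- nrow(values); d <- ncol(values)
  if (n < 1L || d < 1L)
    .stopf("data matrix must have at least one row and one column (got %d x %d)", n, d)
  if (!all(is.finite(values)))
    .stopf("data matrix contains %d non-finite entries", sum(!is.finite(values)))
  if (is.null(sample_ids))
    sample_ids <- rownames(values) %||% paste0("sample_", seq_len(n))
  if (is.null(feature_ids))
    feature_ids <- colnames(values) %||% paste0("feature_", seq_len(d))
  if (length(sample_ids) != n)
    .stopf("%d sample ids for %d rows", length(sample_ids), n)
  if (length(feature_ids) != d)
    .stopf("%d feature ids for %d columns", length(feature_ids), d)
  if (anyDuplicated(sample_ids))
    .stopf("duplicated sample ids: %s",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    .stopf("duplicated feature ids: %s",
           paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  dimnames(values) <- list(as.character(sample_ids), as.character(feature_ids))
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a
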