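#' Read a numeric matrix from TSV/CSV
#'
#' Expects a rectangular numeric table with a header row and a leading
#' row-label column. Expression tables are conventionally features-by-samples
#' ("features-rows"); the loader transposes those so the in-memory
#' orientation is always samples-by-features.
#'
#' @param path File path.
#' @param orientation `"samples-rows"` (default) or `"features-rows"`.
#' @param sep Field separator; tab by default, `","` for CSV.
#' @return A validated [data_matrix()].
#' @export
read_matrix <- function(path, orientation = c("samples-rows", "features-rows"),
                        sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) .stopf("no such file: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           row.names = NULL, comment.char = "")
  if (ncol(tab) < 2L) .stopf("%s: need a label column plus at least one data column", path)
  labels <- as.character(tab[[1L]])
  if (anyDuplicated(labels))
    .stopf("%s: duplicated row labels (e.g. '%s')", path,
           labels[duplicated(labels)][1L])
  num <- tab[-1L]
  bad <- names(num)[!vapply(num, is.numeric, logical(1))]
  if (length(bad))
    .stopf("%s: non-numeric values in column(s) %s", path,
           paste(utils::head(bad, 3L), collapse = ", "))
  A <- as.matrix(num)
  rownames(A) <- labels
  if (orientation == "features-rows") A <- t(A)
  data_matrix(A)
}

#' Write a matrix as a labeled TSV
#'
#' Inverse of [read_matrix()] (samples-rows orientation): header row with an
#' `id` corner cell plus feature ids, one labeled row per sample.
#'
#' @param A Matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(A, path, sep = "\t") {
  A <- data_matrix(A)
  df <- data.frame(id = rownames(A), A, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-site assignment table
#'
#' Two-column TSV `sample_id<TAB>site_id` with a header row.
#'
#' @param path File path.
#' @return Data frame with character columns `sample_id`, `site_id`.
#' @export
read_site_assignments <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (!all(c("sample_id", "site_id") %in% names(tab)))
    .stopf("%s: header must name columns 'sample_id' and 'site_id'", path)
  data.frame(sample_id = as.character(tab$sample_id),
             site_id = as.character(tab$site_id),
             stringsAsFactors = FALSE)
}

#' Export a subspace as eigenvector and eigenvalue TSVs
#'
#' Eigenvectors: rows = features (labeled), columns `PC1..PCk`. Eigenvalues:
#' a one-column TSV. Column order is deterministic.
#'
#' @param s A [subspace()].
#' @param vectors_path,values_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_subspace <- function(s, vectors_path, values_path) {
  stopifnot(inherits(s, "subspace"))
  V <- s$vectors
  colnames(V) <- paste0("PC", seq_len(s$k))
  rn <- rownames(V) %||% paste0("feature_", seq_len(nrow(V)))
  df <- data.frame(feature_id = rn, V, check.names = FALSE)
  utils::write.table(df, vectors_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(eigenvalue = s$values), values_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vectors_path, values_path))
}

#' Read a subspace written by [write_subspace()]
#'
#' @param vectors_path,values_path Paths written by [write_subspace()].
#' @param method Provenance label for the loaded object.
#' @return A [subspace()].
#' @export
read_subspace <- function(vectors_path, values_path, method = "loaded") {
  vt <- utils::read.table(vectors_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  V <- as.matrix(vt[-1L])
  dimnames(V) <- list(vt[[1L]], NULL)
  vals <- utils::read.table(values_path, header = TRUE, sep = "\t")[[1L]]
  subspace(V, vals, method = method)
}
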