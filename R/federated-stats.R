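#' Federated column means and variances
#'
#' Computes pooled per-feature means and variances without moving raw rows:
#' each client uploads its per-column observation counts, sums and sums of
#' squares (plus its sample count), and the aggregator combines them and
#' broadcasts the pooled statistics back. The result is identical to
#' computing the statistics on the pooled matrix, whatever the site layout.
#'
#' Variances use the sample divisor `n - 1` by default (the convention of
#' expression analysis); set `divisor = "n"` for the population form.
#' Variances that are zero up to accumulation noise are snapped to exactly 0
#' and flagged in `zero_variance_mask`.
#'
#' @param partition A [site_partition()].
#' @param log Optional [comm_log()]; two rounds are recorded (one
#'   `1 x (3d+1)` upload per client, one `2 x d` broadcast per client).
#' @param divisor `"n-1"` (default) or `"n"`.
#' @return An object of class `column_stats`: `n_total`, `means`,
#'   `variances`, `zero_variance_mask`, `divisor`.
#' @examples
#' part <- split_by_sizes(matrix(c(1, 3), 2, 1), c(1, 1))
#' st <- federated_column_stats(part)
#' st$means      # 2
#' st$variances  # 2
#' @export
federated_column_stats <- function(partition, log = NULL, divisor = c("n-1", "n")) {
  stopifnot(inherits(partition, "site_partition"))
  divisor <- match.arg(divisor)
  d <- length(partition$feature_ids)

  # Client phase: each site ships (counts, sums, sums of squares, n_s).
  uploads <- lapply(partition$sites, function(As) {
    list(n = nrow(As), counts = rep(nrow(As), d),
         sums = colSums(As), sumsq = colSums(As^2))
  })
  if (!is.null(log))
    for (s in seq_along(uploads))
      record_message(log, round = 1L, sender = s, receiver = .AGG,
                     rows = 1L, cols = 3L * d + 1L)

  # Aggregator phase: combine and broadcast.
  n_total <- sum(vapply(uploads, `[[`, numeric(1), "n"))
  sums <- Reduce(`+`, lapply(uploads, `[[`, "sums"))
  sumsq <- Reduce(`+`, lapply(uploads, `[[`, "sumsq"))
  means <- sums / n_total
  ss <- sumsq - n_total * means^2      # centered sum of squares
  # snap accumulation noise on constant columns to an exact zero
  ss[ss < 1e-12 * pmax(sumsq, 1)] <- 0
  denom <- if (divisor == "n-1") max(n_total - 1, 1) else n_total
  variances <- ss / denom
  if (!is.null(log))
    for (s in seq_along(uploads))
      record_message(log, round = 2L, sender = .AGG, receiver = s,
                     rows = 2L, cols = d)

  structure(list(n_total = n_total,
                 means = stats::setNames(means, partition$feature_ids),
                 variances = stats::setNames(variances, partition$feature_ids),
                 zero_variance_mask = variances == 0,
                 divisor = divisor),
            class = "column_stats")
}

#' Federated centering and scaling
#'
#' Subtracts the pooled column means from every site block and, if
#' `scale = TRUE`, divides by the pooled column standard deviations so that
#' the pooled data have unit variance per feature. Zero-variance features
#' cannot be scaled; when scaling they are dropped from all sites (and from
#' the feature ids) with a warning.
#'
#' @param partition A [site_partition()].
#' @param stats Pooled [federated_column_stats()] for this partition;
#'   computed on the fly when `NULL`.
#' @param scale Scale to unit variance? Default `TRUE`.
#' @param log Optional [comm_log()] passed to the statistics protocol when
#'   `stats` is `NULL`.
#' @return A new [site_partition()] with transformed blocks.
#' @export
center_scale <- function(partition, stats = NULL, scale = TRUE, log = NULL) {
  stopifnot(inherits(partition, "site_partition"))
  if (is.null(stats)) stats <- federated_column_stats(partition, log = log)
  stopifnot(inherits(stats, "column_stats"))
  if (length(stats$means) != length(partition$feature_ids))
    .stopf("statistics cover %d features but the partition has %d",
           length(stats$means), length(partition$feature_ids))
  keep <- rep(TRUE, length(partition$feature_ids))
  if (isTRUE(scale)) {
    keep <- !stats$zero_variance_mask
    if (!any(keep))
      .stopf("all %d features have zero variance; nothing to scale", length(keep))
    if (any(!keep))
      .warnf("dropping %d zero-variance feature(s): %s", sum(!keep),
             paste(utils::head(partition$feature_ids[!keep], 5L), collapse = ", "))
  }
  mu <- stats$means[keep]
  sdv <- sqrt(stats$variances[keep])
  sites <- lapply(partition$sites, function(As) {
    B <- sweep(As[, keep, drop = FALSE], 2L, mu, "-")
    if (isTRUE(scale)) B <- sweep(B, 2L, sdv, "/")
    B
  })
  site_partition(sites, row_index = partition$row_index)
}
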