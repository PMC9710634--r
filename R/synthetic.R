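#' Synthetic expression-like matrix with a controlled spectrum
#'
#' Generates `A = Z diag(s) W' + E`: a planted rank-r signal with prescribed
#' singular-value scales `s` (orthonormal random feature basis `W`, standard
#' normal scores `Z`) plus i.i.d. Gaussian noise. The matrix is returned
#' column-centered, so it is ready for PCA. The planted basis is attached as
#' attribute `"basis"` for recovery checks.
#'
#' The leading-value scales control the eigengaps, hence both eigenvector
#' identifiability and subspace-iteration convergence speed.
#'
#' @param n,d Dimensions (samples x features).
#' @param leading_values Positive, nonincreasing singular-value scales; their
#'   length is the planted rank `r <= min(n, d)`.
#' @param noise_sd Standard deviation of the additive noise; default 0.5.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A centered [data_matrix()] with attribute `"basis"` (`d x r`).
#' @examples
#' A <- generate_lowrank(100, 30, leading_values = c(10, 5), seed = 1)
#' centralized_pca(A, 2)$values
#' @export
generate_lowrank <- function(n, d, leading_values, noise_sd = 0.5, seed = 0L) {
  stopifnot(.is_count(n), .is_count(d))
  r <- length(leading_values)
  if (r < 1L || any(leading_values <= 0))
    .stopf("`leading_values` must be positive")
  if (is.unsorted(rev(leading_values)))
    .stopf("`leading_values` must be nonincreasing")
  if (r > min(n, d))
    .stopf("planted rank %d exceeds min(n, d) = %d", r, min(n, d))
  if (noise_sd < 0) .stopf("`noise_sd` must be nonnegative")
  set.seed(seed)
  W <- .orthonormalize(matrix(stats::rnorm(d * r), d, r))$Q
  Z <- matrix(stats::rnorm(n * r), n, r)
  A <- Z %*% (leading_values * t(W))
  if (noise_sd > 0) A <- A + matrix(stats::rnorm(n * d, sd = noise_sd), n, d)
  A <- sweep(A, 2L, colMeans(A), "-")
  A <- data_matrix(A, paste0("sample_", seq_len(n)), paste0("gene_", seq_len(d)))
  attr(A, "basis") <- W
  A
}

#' Skewed per-site sample counts
#'
#' Emulates the skewed sample distributions of multi-center studies (a few
#' large collection sites, many small ones): each site receives `min_size`
#' samples, and the remainder is drawn from a multinomial over symmetric
#' Dirichlet(`alpha`) weights. Small `alpha` (e.g. 0.2-0.3) gives strong
#' skew; large `alpha` approaches equal sizes.
#'
#' @param n_total Total number of samples.
#' @param n_sites Number of sites S.
#' @param alpha Dirichlet concentration, `> 0`. Default 0.3.
#' @param min_size Minimum per-site size; default 1.
#' @param seed Integer seed.
#' @return Integer vector of S sizes summing to `n_total`, each
#'   `>= min_size`.
#' @export
skewed_site_sizes <- function(n_total, n_sites, alpha = 0.3, min_size = 1L,
                              seed = 0L) {
  stopifnot(.is_count(n_total), .is_count(n_sites), .is_count(min_size))
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0))
    .stopf("`alpha` must be a positive number")
  if (n_total < n_sites * min_size)
    .stopf("cannot place %d samples on %d sites with min_size %d",
           n_total, n_sites, min_size)
  set.seed(seed)
  w <- stats::rgamma(n_sites, shape = alpha)
  if (sum(w) == 0) w <- rep(1, n_sites)   # extreme-alpha underflow guard
  extra <- n_total - n_sites * min_size
  sizes <- rep(as.integer(min_size), n_sites)
  if (extra > 0)
    sizes <- sizes + as.integer(stats::rmultinom(1L, extra, w / sum(w)))
  sizes
}

#' Inject site-specific batch effects
#'
#' Adds a constant per-site offset vector `b_s` (entries i.i.d.
#' `N(0, shift_scale^2)`) to every row of site s — the mean-shift model of a
#' batch effect. `shift_scale = 0` returns the partition unchanged.
#'
#' @param partition A [site_partition()].
#' @param shift_scale Standard deviation of the per-feature shifts, `>= 0`.
#' @param seed Integer seed.
#' @return A new [site_partition()] with shifted blocks; the per-site shift
#'   vectors are attached as attribute `"shifts"`.
#' @export
inject_batch_effects <- function(partition, shift_scale, seed = 0L) {
  stopifnot(inherits(partition, "site_partition"))
  if (!(is.numeric(shift_scale) && length(shift_scale) == 1L && shift_scale >= 0))
    .stopf("`shift_scale` must be a nonnegative number")
  set.seed(seed)
  d <- length(partition$feature_ids)
  shifts <- lapply(seq_along(partition$sites), function(s)
    stats::rnorm(d, sd = shift_scale))
  sites <- Map(function(As, b) sweep(As, 2L, b, "+"), partition$sites, shifts)
  out <- site_partition(sites, row_index = partition$row_index)
  attr(out, "shifts") <- shifts
  out
}

#' Greedy grouping of sites into balanced meta-sites
#'
#' Groups S sites into g "meta-sample-sites" of approximately equal total
#' size with the longest-processing-time heuristic: sites are sorted by
#' decreasing size and each is assigned to the currently smallest group
#' (ties broken by the lowest group index). Deterministic.
#'
#' @param sizes Positive integer site sizes.
#' @param g Number of groups, `1 <= g <= length(sizes)`.
#' @return Integer vector: the group (1..g) of each site, with attribute
#'   `"group_totals"`.
#' @examples
#' greedy_meta_sites(c(5, 4, 3, 2, 1), 2)  # totals 8 and 7
#' @export
greedy_meta_sites <- function(sizes, g) {
  if (any(sizes < 1L) || any(sizes != floor(sizes)))
    .stopf("`sizes` must be positive integers")
  S <- length(sizes)
  if (!.is_count(g) || g > S)
    .stopf("need 1 <= g <= %d groups (got %s)", S, deparse(g))
  ord <- order(sizes, decreasing = TRUE)   # stable: ties keep input order
  assignment <- integer(S)
  totals <- numeric(g)
  for (i in ord) {
    grp <- which.min(totals)               # ties -> lowest index
    assignment[i] <- grp
    totals[grp] <- totals[grp] + sizes[i]
  }
  structure(assignment, group_totals = totals)
}

#' Multi-center study size presets
#'
#' Sample and site counts of real multi-center cancer transcriptome cohorts
#' (samples federated by tissue source site), usable as realistic `n_total`
#' and `n_sites` presets for [skewed_site_sizes()].
#'
#' @param name Preset name, e.g. `"tcga-kidney"`; `NULL` lists all presets.
#' @return A list with `n_total` and `n_sites`, or the full preset data
#'   frame when `name` is `NULL`.
#' @examples
#' tcga_site_preset("tcga-kidney")
#' @export
tcga_site_preset <- function(name = NULL) {
  presets <- data.frame(
    name = paste0("tcga-", c("kidney", "thyroid", "liver", "bladder", "ovary",
                             "brain", "prostate", "corpus-uteri", "breast",
                             "cervix-uteri", "colon", "lung", "stomach",
                             "skin")),
    n_total = c(887L, 504L, 404L, 408L, 377L, 679L, 495L, 547L, 1093L, 304L,
                458L, 1017L, 386L, 468L),
    n_sites = c(24L, 11L, 8L, 14L, 9L, 20L, 14L, 12L, 19L, 8L, 12L, 34L, 9L,
                11L),
    stringsAsFactors = FALSE)
  if (is.null(name)) return(presets)
  hit <- match(name, presets$name)
  if (is.na(hit))
    .stopf("unknown preset '%s'; see tcga_site_preset() for the list", name)
  list(n_total = presets$n_total[hit], n_sites = presets$n_sites[hit])
}
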