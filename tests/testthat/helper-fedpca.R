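# Shared fixture builders. Everything is generated in code at test time.

# centered random matrix with a decaying spectrum and simple eigengaps
make_centered <- function(n, d, seed, r = min(8L, n - 1L, d),
                          ratio = 0.75, top = 10, noise_sd = 0.2) {
  generate_lowrank(n, d, leading_values = top * ratio^(seq_len(r) - 1L),
                   noise_sd = noise_sd, seed = seed)
}

# random skewed partition of the rows of A
random_partition <- function(A, S, seed, alpha = 0.3) {
  sizes <- skewed_site_sizes(nrow(A), S, alpha = alpha, seed = seed)
  split_by_sizes(A, sizes, seed = seed, shuffle = TRUE)
}

# largest per-column angle (degrees) between two eigenvector matrices
max_pairwise_angle <- function(V1, V2) {
  if (inherits(V1, "subspace")) V1 <- V1$vectors
  if (inherits(V2, "subspace")) V2 <- V2$vectors
  max(vapply(seq_len(ncol(V1)),
             function(j) angle_degrees(V1[, j], V2[, j]), numeric(1)))
}

# indices whose adjacent eigengaps are simple enough for per-vector checks
simple_gap_index <- function(values, k, rel = 1e-6) {
  gaps_ok <- vapply(seq_len(k), function(j) {
    lo <- if (j < length(values)) abs(values[j] - values[j + 1L]) else Inf
    hi <- if (j > 1L) abs(values[j - 1L] - values[j]) else Inf
    min(lo, hi) > rel * max(values[1L], 1e-300)
  }, logical(1))
  which(gaps_ok)
}
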