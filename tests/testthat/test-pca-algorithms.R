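test_that("centralized_pca matches the direct eigendecomposition", {
  A <- matrix(c(2, 0, -2, 0,
                0, 1, 0, -1), 4, 2)      # centered; (1/4) A'A = diag(2, 0.5)
  s <- centralized_pca(A, 1)
  expect_equal(abs(s$vectors[, 1]), c(1, 0), tolerance = 1e-12)
  expect_equal(s$values, 2, tolerance = 1e-12)

  s2 <- centralized_pca(A, 2)
  expect_equal(s2$values, c(2, 0.5), tolerance = 1e-12)
})

test_that("a centered n x d matrix has at most n - 1 nonzero eigenvalues", {
  A <- scale(matrix(rnorm(30), 3, 10), scale = FALSE)
  s <- centralized_pca(A, 3)
  expect_lt(s$values[3], 1e-20)
  expect_gt(s$values[2], 1e-10)
  expect_error(centralized_pca(A, 4), "min\\(n, d\\)")
})

test_that("full-rank projection reconstructs the data exactly", {
  A <- make_centered(20, 6, seed = 9, r = 4, noise_sd = 0)
  s <- centralized_pca(A, 4)
  expect_lt(reconstruction_error(A, s$vectors), 1e-8)
})

test_that("local_subspace truncates and reconstructs the local Gram matrix", {
  su <- local_subspace(matrix(c(3, 0, 0), 1, 3), 1)
  expect_equal(abs(su$v[, 1]), c(1, 0, 0))
  expect_equal(su$d, 3)

  # a 5 x 100 site can yield at most 5 components
  wide <- matrix(rnorm(500), 5, 100)
  expect_warning(su5 <- local_subspace(wide, 20, site = 1), "truncated to 5")
  expect_identical(length(su5$d), 5L)

  # full local rank: V diag(d^2) V' = A'A within 1e-8
  As <- matrix(rnorm(40), 8, 5)
  suf <- local_subspace(As, 5)
  expect_equal(suf$v %*% (suf$d^2 * t(suf$v)), crossprod(As),
               tolerance = 1e-8)
  expect_error(local_subspace(matrix(numeric(0), 0, 3), 1), "empty")
})

test_that("merge_proxy_covariance sums squared-scale reconstructions", {
  s1 <- structure(list(site = 1, v = matrix(c(1, 0), 2, 1), d = 3),
                  class = "local_summary")
  s2 <- structure(list(site = 2, v = matrix(c(0, 1), 2, 1), d = 4),
                  class = "local_summary")
  expect_equal(merge_proxy_covariance(list(s1, s2)), diag(c(9, 16)))
  # linearity: duplicating a summary doubles its contribution
  expect_equal(merge_proxy_covariance(list(s1, s1)),
               2 * merge_proxy_covariance(list(s1)))
  s_bad <- structure(list(site = 3, v = matrix(1, 3, 1), d = 1),
                     class = "local_summary")
  expect_error(merge_proxy_covariance(list(s1, s_bad)), "features")
})

test_that("p_cov recovers the toy summed Gram matrix and the S=1 identity", {
  part <- site_partition(list(matrix(c(3, 0), 1, 2), matrix(c(0, 4), 1, 2)))
  s <- p_cov(part, 1)
  expect_equal(unname(abs(s$vectors[, 1])), c(0, 1), tolerance = 1e-12)
  expect_equal(s$values, 8, tolerance = 1e-12)   # 16 / n, n = 2

  A <- make_centered(30, 8, seed = 2)
  expect_equal(p_cov(split_by_sizes(A, 30), 4)$vectors,
               centralized_pca(A, 4)$vectors, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("exact methods agree with the centralized oracle on skewed partitions", {
  for (seed in 1:6) {
    A <- make_centered(50 + 10 * seed, 5 * seed + 10, seed = seed)
    ref <- centralized_pca(A, 4)
    part <- random_partition(A, min(1 + 2 * seed, 12), seed = seed)
    idx <- simple_gap_index(ref$values, 4)
    for (alg in c("p-cov", "qr-pca")) {
      fed <- federated_pca(part, alg, 4)
      ang <- vapply(idx, function(j)
        angle_degrees(fed$vectors[, j], ref$vectors[, j]), numeric(1))
      expect_lt(max(ang), 1e-6)
      # eigenvalue scale: matches (1/n) A'A within 1e-8 relative
      expect_equal(fed$values, ref$values, tolerance = 1e-8)
    }
  }
})

test_that("qr_pca handles the hand-worked stack and the S=1 identity", {
  part <- site_partition(list(matrix(c(3, 0), 1, 2), matrix(c(0, 4), 1, 2)))
  s <- qr_pca(part, 1)
  expect_equal(unname(abs(s$vectors[, 1])), c(0, 1), tolerance = 1e-12)
  expect_equal(s$values, 8, tolerance = 1e-12)

  A <- make_centered(25, 40, seed = 4)   # short-wide sites exercised too
  expect_lt(max_pairwise_angle(qr_pca(split_by_sizes(A, 25), 5),
                               centralized_pca(A, 5)), 1e-8)
})

test_that("ap_cov / ap_stack are equivalent and recover p_cov in the limit", {
  part <- site_partition(list(matrix(c(3, 0), 1, 2), matrix(c(0, 4), 1, 2)))
  s <- ap_cov(part, 1, k_prime = 1)
  expect_equal(unname(abs(s$vectors[, 1])), c(0, 1), tolerance = 1e-12)

  stck <- ap_stack(part, 1, k_prime = 1)
  expect_equal(unname(abs(stck$vectors[, 1])), c(0, 1), tolerance = 1e-12)

  for (seed in 1:5) {
    A <- make_centered(60, 15, seed = seed)
    prt <- random_partition(A, 4, seed = seed)
    for (kp in c(3L, 6L, 10L)) {
      sc <- suppressWarnings(ap_cov(prt, 3, k_prime = kp))
      ss <- suppressWarnings(ap_stack(prt, 3, k_prime = kp))
      expect_lt(max_pairwise_angle(sc, ss), 1e-6)
      expect_equal(sc$values, ss$values, tolerance = 1e-8)
    }
    # k' = full local rank: proxy equals the exact covariance
    full <- suppressWarnings(ap_cov(prt, 3, k_prime = 15L))
    expect_lt(max_pairwise_angle(full, centralized_pca(A, 3)), 1e-6)
  }
})

test_that("ap methods validate k against k_prime", {
  part <- random_partition(make_centered(30, 10, seed = 1), 3, seed = 1)
  expect_error(ap_cov(part, 5, k_prime = 3), "k'")
  expect_error(ap_stack(part, 5, k_prime = 3), "k'")
  # every site effectively rank 1 but k = 2 requested
  tiny <- site_partition(list(matrix(c(1, 0, 0), 1, 3),
                              matrix(c(0, 1, 0), 1, 3)))
  expect_error(suppressWarnings(ap_cov(tiny, 2, k_prime = 2)),
               "effective k'")
})

test_that("AP uploads are (d+1)k' scalars, below d^2 for small k'", {
  part <- random_partition(make_centered(60, 20, seed = 8), 3, seed = 8,
                           alpha = 5)
  log <- comm_log()
  ap_stack(part, 2, k_prime = 4, log = log)
  df <- as.data.frame(log)
  up <- df[df$receiver == "aggregator", ]
  expect_true(all(up$scalar_count == (20 + 1) * 4))
  expect_true(all(up$scalar_count < 20^2))
})

test_that("site order never changes any algorithm's output", {
  A <- make_centered(40, 12, seed = 11)
  sizes <- c(5L, 10L, 25L)
  fwd <- split_by_sizes(A, sizes)
  rev_part <- site_partition(rev(fwd$sites), row_index = rev(fwd$row_index))
  for (alg in c("p-cov", "qr-pca", "ap-cov", "ap-stack")) {
    a <- suppressWarnings(federated_pca(fwd, alg, 3, k_prime = 5L))
    b <- suppressWarnings(federated_pca(rev_part, alg, 3, k_prime = 5L))
    expect_equal(a$vectors, b$vectors, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(a$values, b$values, tolerance = 1e-10)
  }
})

test_that("subspace validates orthonormality and ordering", {
  expect_error(subspace(matrix(c(1, 1), 2, 1), 1), "orthonormal")
  expect_error(subspace(diag(2), c(1, 2)), "nonincreasing")
  expect_silent(subspace(diag(2), c(2, 1)))
})
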