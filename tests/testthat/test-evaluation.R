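test_that("angle_degrees folds sign and handles the closed forms", {
  expect_equal(angle_degrees(c(1, 0), c(0, 1)), 90)
  expect_equal(angle_degrees(c(1, 1), c(1, 0)), 45)
  expect_equal(angle_degrees(c(1, 0), c(-1, 0)), 0)
  expect_error(angle_degrees(c(0, 0), c(1, 0)), "zero vector")

  # symmetry and scale invariance
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(angle_degrees(x, y), angle_degrees(y, x))
    expect_equal(angle_degrees(3.7 * x, y), angle_degrees(x, -2 * y))
    expect_equal(angle_degrees(x, x), 0, tolerance = 1e-5)
  }
})

test_that("reconstruction_error matches hand values and Eckart-Young", {
  A <- diag(2)
  expect_equal(reconstruction_error(A, matrix(c(1, 0), 2, 1)), 1)

  B <- make_centered(20, 6, seed = 2, r = 3, noise_sd = 0)
  s <- centralized_pca(B, 3)
  expect_lt(reconstruction_error(B, s$vectors), 1e-8)   # V spans the row space

  # any V is no better than the centralized optimum
  sv <- svd(B)$d
  lower <- sqrt(sum(sv[-(1:2)]^2))
  set.seed(3)
  for (i in 1:10) {
    V <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
    expect_gte(reconstruction_error(B, V), lower - 1e-10)
  }
  expect_warning(reconstruction_error(B, matrix(1, 6, 2)), "not orthonormal")
})

test_that("reconstruction_ratio behaves at the boundaries", {
  A <- make_centered(15, 5, seed = 4)
  s <- centralized_pca(A, 2)
  expect_equal(reconstruction_ratio(A, s$vectors, s$vectors), 1)

  part <- random_partition(A, 3, seed = 1)
  expect_equal(reconstruction_ratio(A, p_cov(part, 2)$vectors, s$vectors), 1,
               tolerance = 1e-10)

  # zero reference with nonzero federated error -> Inf sentinel
  C <- rbind(c(1, 0), c(-1, 0))              # rank 1, centered
  v_ref <- matrix(c(1, 0))                   # spans the row space: error 0
  v_fed <- matrix(c(0, 1))
  expect_identical(reconstruction_ratio(C, v_fed, v_ref), Inf)
  expect_error(reconstruction_ratio(A, s$vectors, s$vectors[, 1, drop = FALSE]),
               "different k")
})

test_that("compare_subspaces pairs by rank order and fills the report", {
  A <- make_centered(30, 8, seed = 5)
  s <- centralized_pca(A, 3)
  rep1 <- compare_subspaces(s, s, A)
  expect_equal(rep1$angles_deg, rep(0, 3))
  expect_equal(rep1$ratio, 1)

  swapped <- subspace(s$vectors[, c(2, 1, 3)], sort(s$values, TRUE),
                      method = "swapped")
  rep2 <- compare_subspaces(swapped, s, A)
  expect_gt(max(rep2$angles_deg[1:2]), 45)  # no re-matching by design

  short <- centralized_pca(A, 2)
  expect_error(compare_subspaces(short, s, A), "different k")
})

test_that("canonical_sign flips to a positive leading entry, idempotently", {
  expect_equal(canonical_sign(matrix(c(-2, 1), 2, 1)), matrix(c(2, -1), 2, 1))
  V <- matrix(rnorm(12), 4, 3)
  expect_identical(canonical_sign(canonical_sign(V)), canonical_sign(V))
  expect_equal(angle_degrees(canonical_sign(V)[, 1], V[, 1]), 0,
               tolerance = 1e-6)
})

test_that("predicted_comm_cost reproduces the closed forms", {
  p <- predicted_comm_cost("p-cov", d = 100, k = 10, n_sites = 3)
  expect_true(all(p$per_client_upload == 10000))
  expect_identical(p$total, 3 * (10000 + 1000))

  s <- predicted_comm_cost("sub-it", d = 10, k = 2, n_sites = 1,
                           iterations = 5)
  expect_identical(s$per_client_upload + s$per_client_download, 200)

  a <- predicted_comm_cost("ap-stack", d = 100, k = 10, n_sites = 4,
                           k_prime = 10)
  expect_true(all(a$per_client_upload == 1010))

  q <- predicted_comm_cost("qr-pca", d = 50, k = 5, n_sites = 2,
                           site_sizes = c(10, 80))
  expect_identical(q$per_client_upload, c(10 * 50, 50 * 50))

  expect_error(predicted_comm_cost("ap-cov", d = 10, k = 2, n_sites = 2),
               "k_prime")
  expect_error(predicted_comm_cost("sub-it", d = 10, k = 2, n_sites = 2),
               "iterations")
})

test_that("recorded logs equal predictions for every algorithm", {
  A <- make_centered(45, 14, seed = 10)
  sizes <- c(4L, 11L, 30L)
  part <- split_by_sizes(A, sizes)
  run <- list(
    list(alg = "p-cov", fn = function(l) p_cov(part, 3, log = l)),
    list(alg = "qr-pca", fn = function(l) qr_pca(part, 3, log = l)),
    list(alg = "ap-cov", fn = function(l) ap_cov(part, 3, k_prime = 6, log = l)),
    list(alg = "ap-stack", fn = function(l) ap_stack(part, 3, k_prime = 6, log = l)),
    list(alg = "sub-it", fn = function(l) sub_it(part, 3, seed = 2, log = l)))
  for (r in run) {
    log <- comm_log()
    res <- suppressWarnings(r$fn(log))
    iters <- if (is.null(res$iterations)) 1L else res$iterations
    pred <- predicted_comm_cost(r$alg, d = 14, k = 3, n_sites = 3,
                                k_prime = 6, iterations = iters,
                                site_sizes = sizes)
    expect_identical(comm_total(log), pred$total)
    expect_identical(comm_rounds(log), as.integer(pred$rounds))
  }
})
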