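test_that("split_by_sizes slices deterministically and round-trips exactly", {
  A <- data_matrix(matrix(as.numeric(1:12), 4, 3))

  one <- split_by_sizes(A, 4)
  expect_identical(n_sites(one), 1L)
  expect_equal(one$sites[[1]], A, ignore_attr = FALSE)

  two <- split_by_sizes(A, c(1, 3))
  expect_equal(unname(two$sites[[1]]), unname(A[1, , drop = FALSE]))
  expect_equal(unname(two$sites[[2]]), unname(A[2:4, ]))

  expect_identical(unsplit_partition(two), A)
})

test_that("shuffled splits preserve the row multiset and invert exactly", {
  A <- data_matrix(matrix(rnorm(20), 10, 2))
  part <- split_by_sizes(A, c(3, 3, 4), seed = 7, shuffle = TRUE)
  pooled_rows <- do.call(rbind, lapply(part$sites, unname))
  # row-multiset oracle: sort rows lexicographically on both sides
  canon <- function(M) M[do.call(order, as.data.frame(M)), ]
  expect_equal(canon(pooled_rows), canon(unname(A)))
  expect_identical(unsplit_partition(part), A)
})

test_that("size mismatches are rejected with both totals named", {
  A <- matrix(rnorm(12), 4, 3)
  expect_error(split_by_sizes(A, c(2, 3)), "sum to 5.*4 rows")
  expect_error(split_by_sizes(A, c(0, 4)), "positive")
})

test_that("federated column stats equal pooled statistics", {
  # single site: identical to that site's own stats
  A <- matrix(rnorm(50), 10, 5)
  st <- federated_column_stats(split_by_sizes(A, 10))
  expect_equal(unname(st$means), unname(colMeans(A)))
  expect_equal(unname(st$variances), unname(apply(A, 2, var)))

  # two singleton sites [[1]], [[3]]: pooled two-pass oracle on c(1, 3)
  st2 <- federated_column_stats(split_by_sizes(matrix(c(1, 3), 2, 1), c(1, 1)))
  expect_equal(unname(st2$means), mean(c(1, 3)))       # 2
  expect_equal(unname(st2$variances), var(c(1, 3)))    # 2
  expect_identical(st2$n_total, 2)

  # any layout of the same rows gives identical stats (1e-10 relative)
  B <- make_centered(60, 8, seed = 3)
  pooled_mean <- colMeans(B)
  pooled_var <- apply(B, 2, var)
  for (seed in 1:5) {
    part <- random_partition(B, 5, seed = seed)
    st <- federated_column_stats(part)
    expect_equal(unname(st$means), unname(pooled_mean), tolerance = 1e-10)
    expect_equal(unname(st$variances), unname(pooled_var), tolerance = 1e-10)
  }
})

test_that("the statistics protocol logs the documented two rounds", {
  part <- random_partition(make_centered(30, 6, seed = 1), 3, seed = 1)
  log <- comm_log()
  federated_column_stats(part, log = log)
  df <- as.data.frame(log)
  expect_identical(comm_rounds(log), 2L)
  expect_identical(sum(df$round == 1), 3L)            # one upload per client
  expect_true(all(df$scalar_count[df$round == 1] == 3 * 6 + 1))
  expect_true(all(df$scalar_count[df$round == 2] == 2 * 6))
})

test_that("center_scale standardizes the pooled data and is idempotent", {
  part <- split_by_sizes(matrix(c(1, 3), 2, 1), c(1, 1))
  scaled <- center_scale(part, scale = TRUE)
  expect_equal(as.numeric(scaled$sites[[1]]), -0.7071, tolerance = 1e-4)
  expect_equal(as.numeric(scaled$sites[[2]]), 0.7071, tolerance = 1e-4)

  B <- make_centered(40, 6, seed = 5) + 3   # uncentered copy
  partB <- random_partition(B, 4, seed = 2)
  centered <- center_scale(partB, scale = FALSE)
  st <- federated_column_stats(centered)
  expect_equal(unname(st$means), rep(0, 6), tolerance = 1e-10)

  rescaled <- center_scale(partB, scale = TRUE)
  st2 <- federated_column_stats(rescaled)
  expect_equal(unname(st2$means), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(st2$variances), rep(1, 6), tolerance = 1e-10)
  # idempotence: a second pass changes nothing material
  st3 <- federated_column_stats(center_scale(rescaled, scale = TRUE))
  expect_equal(unname(st3$means), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(st3$variances), rep(1, 6), tolerance = 1e-10)
})

test_that("zero-variance columns are dropped when scaling, kept when centering", {
  A <- cbind(rnorm(10), const = rep(5, 10), rnorm(10))
  colnames(A) <- c("g1", "g2", "g3")
  part <- split_by_sizes(A, c(4, 6))
  expect_warning(scaled <- center_scale(part, scale = TRUE),
                 "zero-variance")
  expect_identical(scaled$feature_ids, c("g1", "g3"))
  expect_identical(ncol(scaled$sites[[1]]), 2L)

  centered <- center_scale(part, scale = FALSE)
  expect_identical(centered$feature_ids, c("g1", "g2", "g3"))

  allconst <- split_by_sizes(matrix(1, 6, 2), c(3, 3))
  expect_error(center_scale(allconst, scale = TRUE), "zero variance")
})

test_that("comm log accounting follows the message records", {
  log <- comm_log()
  record_message(log, 1, 1, "aggregator", rows = 7, cols = 3)
  expect_identical(comm_total(log), 21)                 # T = d * k

  log2 <- comm_log()
  for (s in 1:3)
    record_message(log2, 1, s, "aggregator", rows = 5, cols = 5)
  expect_identical(comm_total(log2), 75)                # 3 * d^2
  expect_identical(comm_rounds(log2), 1L)               # N counts rounds

  expect_error(record_message(log, 1, 1, "aggregator", rows = 0, cols = 2),
               "positive")
  expect_error(record_message(log, 1, 2, 2, rows = 1, cols = 1), "differ")

  # totals invariant to record order
  log3 <- comm_log()
  record_message(log3, 1, 2, "aggregator", rows = 5, cols = 5)
  record_message(log3, 1, 3, "aggregator", rows = 5, cols = 5)
  record_message(log3, 1, 1, "aggregator", rows = 5, cols = 5)
  expect_identical(comm_total(log3), comm_total(log2))
  expect_identical(comm_rounds(log3), comm_rounds(log2))
})

test_that("data_matrix and site_partition enforce their invariants", {
  expect_error(data_matrix(matrix(c(1, NA), 1, 2)), "non-finite")
  expect_error(data_matrix(matrix(1, 2, 2), sample_ids = "a"), "2 rows")
  expect_error(site_partition(list(matrix(1, 1, 2), matrix(1, 1, 3))),
               "features")
  mis <- list(matrix(1, 1, 2, dimnames = list(NULL, c("a", "b"))),
              matrix(1, 1, 2, dimnames = list(NULL, c("b", "a"))))
  expect_error(site_partition(mis), "feature ids differ")
})
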