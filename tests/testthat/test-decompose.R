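test_that("reconstruct matches the brute-force quadruple-loop oracle", {
  d <- random_decomposition(dims = c(2, 2, 2, 2), rank = 2, seed = 11)
  expect_equal(unname(reconstruct(d)), brute_reconstruct(d$factors),
               tolerance = 1e-12)
  # with weights (normalized form) the reconstruction is unchanged
  dn <- normalize_loadings(d)
  expect_equal(reconstruct(dn), reconstruct(d), tolerance = 1e-12)
  # single unit spike
  spike <- random_decomposition(dims = c(2, 1, 1, 1), rank = 1, seed = 1)
  spike$factors <- list(contexts = matrix(c(1, 0), 2, 1),
                        pairs = matrix(1), senders = matrix(1),
                        receivers = matrix(1))
  expect_equal(unname(reconstruct(spike)),
               array(c(1, 0), c(2, 1, 1, 1)))
})

test_that("normalized error equals the hand-computed Frobenius ratio", {
  # 2x1x1x1 tensor (3,4) against reconstruction (3,0): 16/25
  tens <- rank1_tensor(c(3, 4), 1, 1, 1)
  d <- random_decomposition(dims = c(2, 1, 1, 1), rank = 1)
  d$factors <- list(contexts = matrix(c(3, 0), 2, 1), pairs = matrix(1),
                    senders = matrix(1), receivers = matrix(1))
  expect_equal(normalized_error(tens, d), 16 / 25)
  # exact reconstruction gives 0; all-zero loadings give 1
  d$factors$contexts <- matrix(c(3, 4), 2, 1)
  expect_equal(normalized_error(tens, d), 0)
  d$factors$contexts <- matrix(0, 2, 1)
  expect_equal(normalized_error(tens, d), 1)
  # scale consistency: scaling tensor and loadings by a > 0 changes nothing
  d$factors$contexts <- matrix(c(3, 0), 2, 1)
  t2 <- comm_tensor(tens$data * 7, score_method = "external")
  d2 <- d; d2$factors$contexts <- d$factors$contexts * 7
  expect_equal(normalized_error(t2, d2), normalized_error(tens, d))
})

test_that("an exactly rank-1 tensor is fitted to numerical exactness", {
  set.seed(5)
  tens <- rank1_tensor(abs(rnorm(4)) + 0.1, abs(rnorm(5)) + 0.1,
                       abs(rnorm(3)) + 0.1, abs(rnorm(2)) + 0.1)
  fit <- cp_decompose(tens, rank = 1, seed = 3)
  expect_lt(fit$norm_error, 1e-6)
  rel <- sqrt(sum((reconstruct(fit) - tens$data)^2) / sum(tens$data^2))
  expect_lt(rel, 1e-5)
  expect_true(all(vapply(fit$factors, min, 0) >= 0))
})

test_that("fits are bitwise reproducible for a fixed seed", {
  sim <- simulate_comm_tensor(n_pairs = 30, seed = 2)
  f1 <- cp_decompose(sim$tensor, rank = 3, seed = 9)
  f2 <- cp_decompose(sim$tensor, rank = 3, seed = 9)
  expect_identical(f1$factors, f2$factors)
  expect_identical(f1$norm_error, f2$norm_error)
  f3 <- cp_decompose(sim$tensor, rank = 3, seed = 10)
  expect_false(identical(f1$factors, f3$factors))
})

test_that("fitting rejects degenerate tensors", {
  z <- array(0, c(2, 2, 2, 2))
  dimnames(z) <- lapply(dim(z), seq_len)
  expect_error(cp_decompose(z, 1), "all zero")
  z[1] <- NA
  expect_error(cp_decompose(z, 1), "finite")
})

test_that("loading normalization yields unit columns and is idempotent", {
  d <- random_decomposition(seed = 21)
  d$factors$contexts[, 1] <- c(3, 4, 0, 0)
  n1 <- normalize_loadings(d)
  expect_equal(unname(n1$factors$contexts[, 1]), c(0.6, 0.8, 0, 0))
  for (A in n1$factors)
    expect_equal(unname(colSums(A^2)), rep(1, d$rank))
  n2 <- normalize_loadings(n1)
  expect_equal(n2$factors, n1$factors)
  expect_equal(n2$weights, n1$weights)
  # uniform column: each entry 1/sqrt(n)
  d$factors$contexts[, 2] <- 1
  expect_equal(unname(normalize_loadings(d)$factors$contexts[, 2]),
               rep(0.5, 4))
  d$factors$pairs[, 1] <- 0
  expect_error(normalize_loadings(d), "all-zero")
})

test_that("error curves are monotone in rank and bounded in [0, 1]", {
  sim <- simulate_comm_tensor(n_pairs = 30, seed = 4)
  scan <- select_rank(sim$tensor, ranks = 1:6, seed = 1)
  expect_true(all(scan$errors >= 0 & scan$errors <= 1))
  expect_true(all(diff(scan$errors) <= 1e-3))  # up to restart noise
  scan2 <- select_rank(sim$tensor, ranks = 1:6, seed = 1)
  expect_identical(scan$errors, scan2$errors)
  expect_error(select_rank(sim$tensor, ranks = 1:2, seed = 1),
               "three")
})

test_that("the elbow rule finds the bend of an error curve", {
  # piecewise-linear curve bending at rank 3
  expect_equal(tensorccc:::elbow_rank(1:8, c(0.9, 0.6, 0.3, 0.28, 0.26,
                                             0.24, 0.22, 0.2)), 3L)
  # an exactly rank-2 tensor: error vanishes from rank 2 onward
  set.seed(8)
  f <- lapply(c(5, 6, 3, 3), function(d) matrix(abs(rnorm(d * 2)), d, 2))
  arr <- brute_reconstruct(f)
  dimnames(arr) <- lapply(dim(arr), seq_len)
  scan <- select_rank(arr, ranks = 1:6, seed = 2, tol = 1e-10,
                      max_iter = 2000)
  expect_true(all(scan$errors[2:6] < 1e-6))
})

test_that("model accessors expose loadings, fit and residuals", {
  sim <- simulate_comm_tensor(n_pairs = 30, seed = 6)
  fit <- cp_decompose(sim$tensor, rank = 2, seed = 1)
  expect_named(coef(fit), c("contexts", "pairs", "senders", "receivers"))
  expect_equal(dim(coef(fit, "pairs")), c(30L, 2L))
  expect_equal(fitted(fit), reconstruct(fit))
  res <- residuals(fit)
  expect_equal(res, sim$tensor$data - fitted(fit),
               ignore_attr = "dimnames")
  expect_equal(sum(res^2) / sum(sim$tensor$data^2), fit$norm_error,
               tolerance = 1e-6)
  expect_output(print(fit), "rank 2")
  expect_output(print(summary(fit)), "Factor 1")
})
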