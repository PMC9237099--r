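test_that("corrindex is zero for equivalent decompositions", {
  d <- random_decomposition(seed = 31)
  expect_equal(corrindex(d, d), 0, tolerance = 1e-12)
  perm <- c(3, 1, 2)
  scales <- c(0.2, 5, 1.7)
  expect_equal(corrindex(d, permute_and_scale(d, perm, scales)), 0,
               tolerance = 1e-12)
  pd <- corrindex(d, permute_and_scale(d, perm, scales),
                  mode = "per_dimension")
  expect_named(pd, c("contexts", "pairs", "senders", "receivers",
                     "stacked"))
  expect_equal(unname(pd), rep(0, 5), tolerance = 1e-12)
})

test_that("corrindex is symmetric and bounded on random decomposition pairs", {
  for (s in 1:25) {
    a <- random_decomposition(seed = s)
    b <- random_decomposition(seed = s + 1000)
    ab <- corrindex(a, b)
    expect_equal(ab, corrindex(b, a), tolerance = 1e-12)
    expect_gte(ab, 0); expect_lte(ab, 1)
    pd <- corrindex(a, b, mode = "per_dimension")
    expect_true(all(pd >= 0 & pd <= 1))
  }
  wrong_rank <- random_decomposition(rank = 2)
  expect_error(corrindex(random_decomposition(), wrong_rank), "rank")
  relabeled <- random_decomposition(seed = 2)
  rownames(relabeled$factors$contexts) <- paste0("x", 1:4)
  expect_error(corrindex(random_decomposition(seed = 2), relabeled),
               "labels")
})

test_that("factor networks are the rank-one outer product of cell loadings", {
  d <- random_decomposition(seed = 41)
  d$factors$senders[, 1] <- c(1, 0, 0)
  d$factors$receivers[, 1] <- c(0, 1, 0)
  nw <- factor_network(d, 1)
  expect_equal(unname(nw$adjacency),
               matrix(c(0, 0, 0, 1, 0, 0, 0, 0, 0), 3, 3))
  expect_equal(qr(nw$adjacency)$rank, 1L)
  # uniform loadings give equal edges and Gini 0
  d$factors$senders[, 2] <- 1; d$factors$receivers[, 2] <- 1
  expect_equal(factor_network(d, 2)$gini, 0)
  expect_error(factor_network(d, 99), "1..3")
})

test_that("gini coefficient matches the mean-absolute-difference formula", {
  expect_equal(gini_coefficient(c(5, 5, 5, 5)), 0)
  expect_equal(gini_coefficient(c(1, 0)), 0.5)
  expect_equal(gini_coefficient(c(1, 0, 0, 0)), 0.75)
  # single nonzero among n: (n - 1) / n, approaching 1
  for (n in c(10, 100, 1000))
    expect_equal(gini_coefficient(c(1, rep(0, n - 1))), (n - 1) / n)
  # scale invariance and agreement with the O(n^2) double-loop oracle
  set.seed(52)
  w <- rexp(40)
  direct <- sum(outer(w, w, function(a, b) abs(a - b))) /
    (2 * length(w)^2 * mean(w))
  expect_equal(gini_coefficient(w), direct, tolerance = 1e-12)
  expect_equal(gini_coefficient(w * 37), gini_coefficient(w))
  expect_error(gini_coefficient(rep(0, 3)), "zero")
  expect_error(gini_coefficient(c(1, -1)), "non-negative")
})

test_that("ordinal correlation handles ties and degenerate loadings", {
  expect_equal(ordinal_correlation(c(1, 2, 3), c(0, 1, 2))$rho, 1)
  expect_equal(ordinal_correlation(c(3, 2, 1), c(0, 1, 2))$rho, -1)
  expect_equal(ordinal_correlation(c(1, 1, 2, 2), c(0, 0, 1, 1))$rho, 1)
  # character levels are ordered by sorted unique values
  r <- ordinal_correlation(c(0.1, 0.5, 0.9),
                           c("a_healthy", "b_moderate", "c_severe"))
  expect_equal(r$rho, 1)
  flat <- ordinal_correlation(c(2, 2, 2), c(0, 1, 2))
  expect_false(flat$defined)
  expect_true(is.na(flat$rho))
})

test_that("group comparisons use pairwise t-tests with Bonferroni", {
  set.seed(61)
  load <- cbind(f1 = c(rnorm(3, 0, 1e-3), rnorm(3, 1, 1e-3)),
                f2 = rnorm(6))
  groups <- rep(c("ctl", "dis"), each = 3)
  res <- compare_groups(load, groups)
  expect_equal(nrow(res), 2)  # 1 group pair x 2 factors
  expect_equal(res$p_adj, pmin(res$p * 2, 1))
  expect_lt(res$p_adj[res$factor == 1], 0.05)
  # identical distributions: t = 0
  same <- cbind(f1 = c(1, 1, 2, 2, 3, 3))
  res0 <- compare_groups(same, rep(c("a", "b"), 3))
  expect_equal(res0$t, 0)
  expect_equal(res0$p_adj, res0$p)  # single comparison
  # oracle: stats::t.test equal-variance p matches
  tt <- t.test(load[1:3, 1], load[4:6, 1], var.equal = TRUE)
  expect_equal(res$p[res$factor == 1], tt$p.value)
  expect_error(compare_groups(load, c("a", rep("b", 5))), "fewer than 2")
})

test_that("sample clustering z-scores loadings and splits separated groups", {
  set.seed(71)
  load <- rbind(matrix(rnorm(8, 0, 0.1), 4, 2),
                matrix(rnorm(8, 5, 0.1), 4, 2))
  rownames(load) <- paste0("s", 1:8)
  cl <- cluster_samples(load, k = 2)
  expect_equal(unname(cl$clusters), rep(c(1L, 2L), each = 4))
  expect_equal(unname(colMeans(cl$zscores)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(cl$zscores, 2, sd)), c(1, 1))
  expect_equal(cl$hclust$method, "ward.D2")
  # duplicated rows always co-cluster
  dup <- load; dup[2, ] <- dup[1, ]
  cld <- cluster_samples(dup, k = 3)
  expect_equal(cld$clusters[1], cld$clusters[2], ignore_attr = TRUE)
  # zero-variance columns are dropped with a warning
  load0 <- cbind(load, f3 = 1)
  expect_warning(cluster_samples(load0, k = 2), "zero-variance")
})
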