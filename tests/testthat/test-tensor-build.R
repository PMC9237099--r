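test_that("aggregation summaries match hand-computed values", {
  counts <- matrix(c(0, 0, 3, 5,   # g1
                     2, 0, 0, 0),  # g2
                   nrow = 4,
                   dimnames = list(paste0("c", 1:4), c("g1", "g2")))
  labels <- c("A", "A", "A", "A")

  p <- aggregate_expression(counts, labels, "nonzero_fraction")
  expect_equal(unname(p$values["A", ]), c(0.5, 0.25))

  p0 <- aggregate_expression(matrix(0, 3, 1,
                                    dimnames = list(NULL, "g")),
                             rep("A", 3), "nonzero_fraction")
  expect_equal(unname(p0$values["A", "g"]), 0)

  # one cell with count 10 out of a 1e6 library: CPM = 10, log2(11)
  counts1 <- matrix(c(10, 1e6 - 10), 1, 2,
                    dimnames = list("c1", c("g", "filler")))
  pl <- aggregate_expression(counts1, "A", "mean_logcpm")
  expect_equal(unname(pl$values["A", "g"]), log2(11), tolerance = 1e-10)

  pr <- aggregate_expression(counts, labels, "mean_raw")
  expect_equal(unname(pr$values["A", ]), c(2, 0.5))
})

test_that("aggregation is invariant to cell order and rejects bad input", {
  set.seed(42)
  counts <- matrix(rpois(60, 2), 10, 6,
                   dimnames = list(paste0("c", 1:10), paste0("g", 1:6)))
  labels <- rep(c("A", "B"), 5)
  perm <- sample(10)
  for (m in c("nonzero_fraction", "mean_logcpm", "mean_raw")) {
    a <- aggregate_expression(counts + 1, labels, m)
    b <- aggregate_expression((counts + 1)[perm, ], labels[perm], m)
    expect_equal(a$values, b$values, info = m)
  }
  expect_error(aggregate_expression(counts, c(labels[-1], NA)),
               "unlabeled")
  expect_error(aggregate_expression(-counts, labels), "non-negative")
})

test_that("complex expression is the minimum over subunits", {
  prof <- tiny_profiles(values = list(
    s1 = matrix(c(0.2, 0.0, 0.8, 0.9, 0.7, 0.5), 2, 3,
                dimnames = list(c("A", "B"), c("g1", "g2", "g3")))))[[1]]
  expect_equal(unname(complex_expression(prof, c("g1", "g2"))),
               c(0.2, 0.0))
  expect_equal(unname(complex_expression(prof, "g3")), c(0.7, 0.5))
  expect_error(complex_expression(prof, c("g1", "gX")), "gX")
})

test_that("pair scoring implements mean, product and geometric mean", {
  L <- c(A = 0.4); R <- c(A = 0.6)
  expect_equal(score_pair(L, R, "mean")[1, 1], 0.5)
  expect_equal(score_pair(L, R, "product")[1, 1], 0.24)
  expect_equal(score_pair(L, R, "gmean")[1, 1], sqrt(0.24))
  expect_error(score_pair(c(A = -1), R, "mean"), "non-negative")
})

test_that("catalog filtering keeps only pairs measurable in every context", {
  cat3 <- lr_catalog(list("g1", c("g1", "g3"), "g2"),
                     list("g2", "g2", "g4"),
                     pair_ids = c("p1", "p2", "p3"))
  profs <- tiny_profiles()  # genes g1, g2 only
  kept <- filter_catalog(cat3, profs)
  expect_equal(kept$pair_ids, "p1")
  expect_equal(length(filter_catalog(cat3[0], profs)), 0)
})

test_that("built tensor matches hand-computed scores on a 2x1x2x2 case", {
  profs <- tiny_profiles()
  tens <- build_comm_tensor(profs, tiny_catalog(), method = "mean")
  expect_equal(dim(tens), c(2L, 1L, 2L, 2L))
  # context ctx1: g1 = (A 0.2, B 0.4), g2 = (A 0.8, B 0.6)
  expect_equal(tens$data[1, 1, "A", "A"], (0.2 + 0.8) / 2)
  expect_equal(tens$data[1, 1, "A", "B"], (0.2 + 0.6) / 2)
  expect_equal(tens$data[1, 1, "B", "A"], (0.4 + 0.8) / 2)
  # context ctx2: g1 = (A 0.5, B 0.1), g2 = (A 0.3, B 0.9)
  expect_equal(tens$data[2, 1, "B", "B"], (0.1 + 0.9) / 2)
  # mean scores of nonzero-fraction profiles stay in [0, 1]
  expect_true(all(tens$data >= 0 & tens$data <= 1))
})

test_that("sender/receiver axes are the sorted cross-context intersection", {
  v1 <- matrix(0.5, 3, 2, dimnames = list(c("C", "A", "B"), c("g1", "g2")))
  v2 <- matrix(0.5, 2, 2, dimnames = list(c("B", "A"), c("g1", "g2")))
  profs <- list(cell_type_profile(v1, "s1"), cell_type_profile(v2, "s2"))
  tens <- build_comm_tensor(profs, tiny_catalog())
  expect_equal(dimnames(tens)$sender, c("A", "B"))
  expect_equal(dimnames(tens)$receiver, c("A", "B"))
  # all-zero expression gives an all-zero tensor
  z <- lapply(1:2, function(i) cell_type_profile(
    matrix(0, 2, 2, dimnames = list(c("A", "B"), c("g1", "g2"))),
    paste0("s", i)))
  expect_true(all(build_comm_tensor(z, tiny_catalog())$data == 0))
})

test_that("edge-list import intersects axes and fills absent triples with 0", {
  el <- function(pairs, scores, senders = "A", receivers = "B") {
    data.frame(sender = senders, receiver = receivers,
               ligand_complex = sub("\\^.*", "", pairs),
               receptor_complex = sub(".*\\^", "", pairs),
               score = scores, stringsAsFactors = FALSE)
  }
  e1 <- rbind(el(c("L1^R1", "L2^R2"), c(1, 2)),
              el("L1^R1", 5, senders = "B", receivers = "A"))
  e2 <- el(c("L1^R1", "L3^R3"), c(3, 4))
  tens <- tensor_from_edge_lists(list(s1 = e1, s2 = e2))
  expect_equal(dimnames(tens)$pair, "L1^R1")
  expect_equal(sort(dimnames(tens)$sender), c("A", "B"))
  expect_equal(tens$data[1, 1, "A", "B"], 1)
  expect_equal(tens$data[1, 1, "B", "A"], 5)
  expect_equal(tens$data[2, 1, "B", "A"], 0)  # absent triple
  # identical edge lists give identical context slices
  t2 <- tensor_from_edge_lists(list(a = e1, b = e1))
  expect_equal(t2$data[1, , , ], t2$data[2, , , ])
})

test_that("edge-list import round-trips scores and validates input", {
  set.seed(7)
  grid <- expand.grid(sender = c("A", "B"), receiver = c("A", "B"),
                      pair = c("L1^R1", "L2^R2"), stringsAsFactors = FALSE)
  make_el <- function() cbind(grid, score = round(runif(nrow(grid)), 3))
  els <- list(s1 = make_el(), s2 = make_el())
  tens <- tensor_from_edge_lists(els)
  long <- as.data.frame(tens)
  for (ctx in names(els)) {
    for (r in seq_len(nrow(els[[ctx]]))) {
      row <- els[[ctx]][r, ]
      got <- long$score[long$context == ctx & long$pair == row$pair &
                          long$sender == row$sender &
                          long$receiver == row$receiver]
      expect_equal(got, row$score)
    }
  }
  # conflicting duplicates rejected; negatives rejected without the flag
  dup <- rbind(els$s1, transform(els$s1[1, ], score = 99))
  expect_error(tensor_from_edge_lists(list(s1 = dup, s2 = els$s2)),
               "conflicting")
  neg <- transform(els$s1, score = score - 10)
  expect_error(tensor_from_edge_lists(list(s1 = neg, s2 = els$s2)),
               "negative")
  expect_warning(
    tshift <- tensor_from_edge_lists(list(s1 = neg, s2 = els$s2),
                                     shift_negative = TRUE),
    "shifting")
  expect_gte(min(tshift$data), 0)
})

test_that("long-CSV serialization round-trips data and labels exactly", {
  sim <- simulate_comm_tensor(n_pairs = 12, n_pathways = 3, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_comm_tensor(sim$tensor, path)
  back <- read_comm_tensor(path)
  expect_equal(back$data, sim$tensor$data)
  expect_identical(dimnames(back), dimnames(sim$tensor))
})
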