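# Shared fixture builders; everything is generated in code at test time.

# Two-context, two-cell-type, two-gene profile pair with hand-pickable
# values: values[[ctx]] is a cell_type x gene matrix.
tiny_profiles <- function(values = NULL, genes = c("g1", "g2"),
                          cell_types = c("A", "B")) {
  if (is.null(values)) {
    values <- list(
      ctx1 = matrix(c(0.2, 0.4, 0.8, 0.6), 2, 2,
                    dimnames = list(cell_types, genes)),
      ctx2 = matrix(c(0.5, 0.1, 0.3, 0.9), 2, 2,
                    dimnames = list(cell_types, genes)))
  }
  lapply(names(values), function(ctx)
    cell_type_profile(values[[ctx]], context_id = ctx))
}

tiny_catalog <- function() {
  lr_catalog(ligands = list("g1"), receptors = list("g2"),
             pair_ids = "g1^g2")
}

# A random valid cp_decomposition object (not a fitted one) for testing
# decomposition-space operations like the CorrIndex.
random_decomposition <- function(dims = c(4, 6, 3, 3), rank = 3,
                                 seed = 1) {
  set.seed(seed)
  axis_names <- c("contexts", "pairs", "senders", "receivers")
  factors <- lapply(seq_along(dims), function(n) {
    A <- matrix(abs(rnorm(dims[n] * rank)), dims[n], rank)
    dimnames(A) <- list(paste0(substr(axis_names[n], 1, 1), seq_len(dims[n])),
                        paste0("factor_", seq_len(rank)))
    A
  })
  names(factors) <- axis_names
  structure(list(factors = factors, rank = rank, norm_error = NA_real_,
                 weights = NULL, seed = seed, tol = 1e-7, max_iter = 500L,
                 n_restarts = 1L, n_iter_run = 0L, converged = TRUE,
                 tensor = NULL),
            class = "cp_decomposition")
}

# Apply a factor permutation and positive column rescaling to a
# decomposition: an equivalent CP model.
permute_and_scale <- function(d, perm = seq_len(d$rank), scales = NULL) {
  if (is.null(scales)) scales <- rep(1, d$rank)
  d$factors <- lapply(d$factors, function(A) {
    B <- sweep(A[, perm, drop = FALSE], 2, scales, "*")
    colnames(B) <- paste0("factor_", seq_len(ncol(B)))
    B
  })
  d
}

# Brute-force CP reconstruction by explicit quadruple loop (oracle).
brute_reconstruct <- function(factors, weights = NULL) {
  dims <- unname(vapply(factors, nrow, 1L))
  R <- ncol(factors[[1]])
  if (is.null(weights)) weights <- rep(1, R)
  out <- array(0, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) for (l in seq_len(dims[4]))
      out[i, j, k, l] <- sum(weights * factors[[1]][i, ] *
                               factors[[2]][j, ] * factors[[3]][k, ] *
                               factors[[4]][l, ])
  out
}

# An exactly rank-1 non-negative labeled tensor from four vectors.
rank1_tensor <- function(v1, v2, v3, v4) {
  arr <- brute_reconstruct(list(matrix(v1), matrix(v2), matrix(v3),
                                matrix(v4)))
  dimnames(arr) <- list(paste0("c", seq_along(v1)),
                        paste0("p", seq_along(v2)),
                        paste0("s", seq_along(v3)),
                        paste0("r", seq_along(v4)))
  comm_tensor(arr, score_method = "external")
}

# Classic unweighted KS enrichment statistic, written independently of the
# package's running-sum code (direct formula on hit positions).
classic_ks_es <- function(ranked_ids, set) {
  N <- length(ranked_ids)
  hits <- ranked_ids %in% set
  m <- sum(hits)
  rs <- cumsum(ifelse(hits, 1 / m, -1 / (N - m)))
  rs[which.max(abs(rs))]
}
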