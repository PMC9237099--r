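#' CorrIndex distance between two CP decompositions
#'
#' Permutation- and scaling-invariant distance between two equal-rank
#' decompositions of tensors with identical axis labels, so separate runs
#' can be compared without aligning factors first. The factor matrices are
#' (by default) stacked vertically, columns are normalized to unit norm,
#' and for the absolute cross inner-product matrix `C` the distance is
#'
#' \deqn{\frac{1}{2R}\Big[\sum_i (1 - \max_j C_{ij}) +
#'       \sum_j (1 - \max_i C_{ij})\Big]}
#'
#' which is 0 for equivalent decompositions and at most 1. Similarity is
#' conventionally reported as `1 - corrindex()`. The per-dimension mode
#' applies the same formula to each dimension's factor matrix separately
#' (more stringent when taking the minimum, but blind to combinatorial
#' effects across dimensions), and also reports the stacked value.
#'
#' @param a,b `"cp_decomposition"` objects of equal rank whose factor
#'   matrices carry identical row labels.
#' @param mode `"stacked"` (default, one headline number) or
#'   `"per_dimension"`.
#' @return For `"stacked"`, a scalar in \[0, 1\]. For `"per_dimension"`, a
#'   named vector with one value per dimension plus `stacked`.
#' @export
corrindex <- function(a, b, mode = c("stacked", "per_dimension")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "cp_decomposition"), inherits(b, "cp_decomposition"))
  if (a$rank != b$rank)
    stop("decompositions have different ranks (", a$rank, " vs ", b$rank, ")")
  for (n in seq_along(a$factors)) {
    if (!identical(rownames(a$factors[[n]]), rownames(b$factors[[n]])))
      stop("axis labels differ in the ", names(a$factors)[n], " dimension; ",
           "CorrIndex requires tensors with identical elements")
  }
  ci <- function(A, B) {
    A <- unit_cols(A); B <- unit_cols(B)
    C <- abs(crossprod(A, B))
    R <- ncol(C)
    (sum(1 - apply(C, 1, max)) + sum(1 - apply(C, 2, max))) / (2 * R)
  }
  stacked <- ci(do.call(rbind, a$factors), do.call(rbind, b$factors))
  if (mode == "stacked") return(stacked)
  per_dim <- mapply(function(A, B) ci(A, B), a$factors, b$factors)
  c(per_dim, stacked = stacked)
}

unit_cols <- function(A) {
  nrm <- sqrt(colSums(A^2))
  nrm[nrm == 0] <- 1
  sweep(A, 2, nrm, "/")
}

#' Factor-specific cell-cell communication network
#'
#' The outer product of a factor's sender and receiver loading vectors is a
#' rank-one sender x receiver adjacency matrix: each entry is an edge weight
#' summarising the overall communication between that cell pair within the
#' factor. The Gini coefficient of the edge weights measures how unevenly
#' the factor's communication is distributed across cell pairs.
#'
#' @param d a `"cp_decomposition"`.
#' @param r factor index in `1..rank`.
#' @return Object of class `"factor_network"`: list with `factor_id`,
#'   `adjacency` (senders x receivers), `gini`.
#' @export
factor_network <- function(d, r) {
  stopifnot(inherits(d, "cp_decomposition"))
  r <- as.integer(r)
  if (r < 1 || r > d$rank) stop("`r` must be in 1..", d$rank)
  s <- d$factors$senders[, r]
  t <- d$factors$receivers[, r]
  adj <- outer(s, t)
  structure(list(factor_id = r, adjacency = adj,
                 gini = gini_coefficient(as.vector(adj))),
            class = "factor_network")
}

#' @export
print.factor_network <- function(x, ...) {
  cat("Factor", x$factor_id, "communication network:",
      nrow(x$adjacency), "senders x", ncol(x$adjacency), "receivers;",
      "edge-weight Gini =", format(x$gini, digits = 3), "\n")
  invisible(x)
}

#' Gini coefficient of edge weights
#'
#' Mean-absolute-difference form without small-sample correction:
#' `G = sum_ij |w_i - w_j| / (2 n^2 mean(w))`. `G = 0` means all weights
#' equal (communication spread evenly over cell pairs); the upper limit
#' `(n-1)/n -> 1` is reached when a single weight carries everything.
#' Scale-invariant: `gini(c * w) = gini(w)` for `c > 0`.
#'
#' @param weights non-negative numeric vector with positive sum.
#' @return scalar in \[0, 1\].
#' @export
gini_coefficient <- function(weights) {
  if (!length(weights)) stop("`weights` must be non-empty")
  if (min(weights) < 0) stop("`weights` must be non-negative")
  total <- sum(weights)
  if (total == 0) stop("all weights are zero; Gini is undefined")
  n <- length(weights)
  w <- sort(weights)
  # identity: sum_ij |w_i - w_j| / (2 n^2 mean) via the sorted form
  2 * sum(seq_len(n) * w) / (n * total) - (n + 1) / n
}

#' Spearman correlation between context loadings and an ordinal covariate
#'
#' Rank correlation (average ranks for ties) between a factor's context
#' loadings and ordered context levels such as disease severity
#' (healthy < moderate < severe) or time. Constant loadings make the
#' correlation undefined; the result is then flagged rather than reported
#' as a number.
#'
#' @param context_loadings numeric vector, one loading per context.
#' @param levels ordinal context levels: numeric, or an ordered factor /
#'   character vector whose order follows `sort(unique(.))`.
#' @return list with `rho` (`NA` when undefined) and `defined` (logical).
#' @export
ordinal_correlation <- function(context_loadings, levels) {
  if (length(context_loadings) < 3)
    stop("need at least three contexts")
  if (length(levels) != length(context_loadings))
    stop("`levels` must have one entry per context")
  lv <- if (is.numeric(levels)) levels
        else as.integer(factor(levels, levels = sort(unique(levels)),
                               ordered = TRUE))
  if (length(unique(lv)) < 2) stop("need at least two distinct levels")
  if (stats::sd(context_loadings) == 0)
    return(list(rho = NA_real_, defined = FALSE))
  list(rho = stats::cor(context_loadings, lv, method = "spearman"),
       defined = TRUE)
}

#' Pairwise group comparison of context loadings
#'
#' For every factor and every pair of context groups, a two-sided
#' independent two-sample t-test on the context loadings, with Bonferroni
#' correction over all comparisons performed (factors x group pairs),
#' capped at 1.
#'
#' @param context_loadings contexts x factors matrix (e.g.
#'   `coef(d, "contexts")`).
#' @param groups group label per context; every group needs >= 2 contexts.
#' @param var_equal assume equal group variances (classical independent
#'   t-test, the default).
#' @return data.frame with columns `factor`, `group_a`, `group_b`, `t`,
#'   `p`, `p_adj`.
#' @export
compare_groups <- function(context_loadings, groups, var_equal = TRUE) {
  context_loadings <- as.matrix(context_loadings)
  groups <- as.character(groups)
  if (length(groups) != nrow(context_loadings))
    stop("`groups` must label every context (row)")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 contexts: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  gl <- sort(unique(groups))
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  res <- list()
  for (f in seq_len(ncol(context_loadings))) {
    for (gp in pairs) {
      xa <- context_loadings[groups == gp[1], f]
      xb <- context_loadings[groups == gp[2], f]
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        # degenerate constant groups: identical means carry no evidence
        tstat <- if (mean(xa) == mean(xb)) 0 else Inf * sign(mean(xa) -
                                                               mean(xb))
        pval <- if (mean(xa) == mean(xb)) 1 else 0
      } else {
        tt <- stats::t.test(xa, xb, var.equal = var_equal)
        tstat <- unname(tt$statistic)
        pval <- tt$p.value
      }
      res[[length(res) + 1]] <- data.frame(
        factor = f, group_a = gp[1], group_b = gp[2],
        t = tstat, p = pval, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- pmin(out$p * nrow(out), 1)
  out
}

#' Hierarchically cluster contexts by their loading profiles
#'
#' Standardizes each factor's context loadings to z-scores across contexts,
#' then applies agglomerative clustering with Ward's method on Euclidean
#' distances. Cluster labels are renumbered by first-occurring context so
#' the labelling is deterministic. Zero-variance factor columns cannot be
#' z-scored and are dropped with a warning.
#'
#' @param sample_loadings contexts x factors matrix.
#' @param k number of clusters to cut the tree into (or use `h`).
#' @param h cut height, alternative to `k`.
#' @return list with `clusters` (named integer vector), `hclust` (the
#'   linkage object), `zscores` (the standardized matrix used).
#' @export
cluster_samples <- function(sample_loadings, k = NULL, h = NULL) {
  m <- as.matrix(sample_loadings)
  if (nrow(m) < 3) stop("need at least three contexts to cluster")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance factor column(s): ",
            paste(which(sds == 0), collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
    if (!ncol(m)) stop("no factor column with positive variance")
  }
  z <- scale(m)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  if (is.null(k) && is.null(h)) k <- 2L
  raw <- stats::cutree(hc, k = k, h = h)
  # renumber clusters in order of first appearance
  first <- match(unique(raw), raw)
  relabel <- stats::setNames(seq_along(first), raw[first])
  clusters <- stats::setNames(unname(relabel[as.character(raw)]), names(raw))
  list(clusters = clusters, hclust = hc, zscores = z)
}
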