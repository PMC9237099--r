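#' Non-negative CP decomposition of a communication tensor
#'
#' Fits a rank-`R` non-negative CANDECOMP/PARAFAC model to the 4D
#' communication tensor: the tensor is approximated by a sum of `R` rank-one
#' tensors, each the outer product of four non-negative loading vectors
#' (contexts, LR pairs, senders, receivers). The fit minimises the squared
#' Frobenius norm of the residual by alternating least squares with
#' column-wise non-negative (HALS) updates, from seeded non-negative random
#' starts; the best of `n_restarts` runs is returned. Each factor is a
#' communication module: its context loadings trace the module's activity
#' across contexts, and its pair/sender/receiver loadings identify the
#' mediators.
#'
#' @param x a [comm_tensor] (or a plain 4-way non-negative array with
#'   dimnames), not all zero.
#' @param rank number of factors `R` (positive integer).
#' @param seed integer seed controlling all random initialisations; the fit
#'   is bitwise reproducible given `(seed, tol, max_iter, n_restarts)`.
#' @param tol convergence tolerance on the change in relative squared error
#'   between sweeps.
#' @param max_iter maximum ALS sweeps per restart.
#' @param n_restarts number of random restarts; the lowest-error run wins.
#' @param keep_tensor store the input tensor in the result (needed by
#'   [residuals.cp_decomposition()]).
#' @return An object of class `"cp_decomposition"`: list with `factors`
#'   (named list of four loading matrices, columns `factor_1..R`), `rank`,
#'   `norm_error` (normalized reconstruction error in \[0, 1\]), `weights`
#'   (`NULL` until [normalize_loadings()]), `seed`, `n_iter_run`,
#'   `converged`.
#' @seealso [select_rank()], [normalize_loadings()], [reconstruct()]
#' @examples
#' tens <- simulate_comm_tensor(seed = 1)$tensor
#' fit <- cp_decompose(tens, rank = 4, seed = 1)
#' fit
#' @export
cp_decompose <- function(x, rank, seed = 1L, tol = 1e-7, max_iter = 500L,
                         n_restarts = 3L, keep_tensor = TRUE) {
  arr <- tensor_array(x)
  if (any(!is.finite(arr))) stop("tensor entries must be finite")
  if (min(arr) < 0) stop("tensor entries must be non-negative")
  norm_x2 <- sum(arr^2)
  if (norm_x2 == 0) stop("tensor is all zero; nothing to decompose")
  rank <- as.integer(rank)
  if (rank < 1) stop("`rank` must be a positive integer")

  dims <- dim(arr)
  unfoldings <- lapply(1:4, function(n) unfold4(arr, n))

  set.seed(as.integer(seed))
  restart_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)
  best <- NULL
  for (k in seq_len(n_restarts)) {
    set.seed(restart_seeds[k])
    init <- lapply(dims, function(d) abs(matrix(stats::rnorm(d * rank), d, rank)))
    run <- nncp_als_core(unfoldings, dims, init, norm_x2, tol, max_iter)
    if (is.null(best) || run$rel_err < best$rel_err) best <- run
  }

  factors <- rebalance_and_sort(best$factors)
  dn <- dimnames(arr)
  axis_names <- c("contexts", "pairs", "senders", "receivers")
  for (n in 1:4)
    dimnames(factors[[n]]) <- list(dn[[n]], paste0("factor_", seq_len(rank)))
  names(factors) <- axis_names

  structure(list(factors = factors,
                 rank = rank,
                 norm_error = best$rel_err,
                 weights = NULL,
                 seed = as.integer(seed),
                 tol = tol, max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts),
                 n_iter_run = best$n_iter,
                 converged = best$converged,
                 tensor = if (keep_tensor) arr else NULL,
                 call = match.call()),
            class = "cp_decomposition")
}

# Accept comm_tensor or bare labeled array.
tensor_array <- function(x) {
  if (inherits(x, "comm_tensor")) return(x$data)
  if (is.array(x) && length(dim(x)) == 4L) {
    if (is.null(dimnames(x)) || any(vapply(dimnames(x), is.null, TRUE)))
      dimnames(x) <- lapply(dim(x), function(d) as.character(seq_len(d)))
    return(x)
  }
  stop("`x` must be a comm_tensor or a 4-way array")
}

# Mode-n unfolding (Kolda-Bader ordering): rows index mode n, columns index
# the remaining modes with the lowest-numbered mode varying fastest.
unfold4 <- function(arr, n) {
  perm <- c(n, setdiff(1:4, n))
  matrix(aperm(arr, perm), nrow = dim(arr)[n])
}

# Khatri-Rao (column-wise Kronecker) of factor matrices given in increasing
# mode order; the first matrix's rows vary fastest, matching unfold4.
# Built by row replication rather than kronecker() calls: one vectorized
# product per matrix instead of a dispatch per column.
khatri_rao <- function(mats) {
  out <- mats[[1]]
  for (m in mats[-1]) {
    na <- nrow(out); nb <- nrow(m)
    out <- out[rep(seq_len(na), times = nb), , drop = FALSE] *
      m[rep(seq_len(nb), each = na), , drop = FALSE]
  }
  out
}

# ALS with column-wise non-negative (HALS) updates. `unfoldings` holds the
# four mode-n unfoldings of the data; error tracked via the identity
# ||X - Xhat||^2 = ||X||^2 - 2<A_n, P> + <G_other * A_n'A_n> after a sweep.
# The initial factors are scaled so the starting reconstruction has the
# data's Frobenius norm (a badly mismatched scale makes the first sweep zero
# out whole components). Updates are floored at a tiny positive value
# rather than 0 so a component squeezed out early can regrow through later
# sweeps; at the floor its contribution to the fit is negligible (~1e-64
# relative).
nncp_als_core <- function(unfoldings, dims, factors, norm_x2, tol, max_iter) {
  R <- ncol(factors[[1]])
  grams <- lapply(factors, crossprod)
  norm_hat2 <- sum(Reduce(`*`, grams))
  if (norm_hat2 > 0) {
    s <- (norm_x2 / norm_hat2)^(1 / 8)
    factors <- lapply(factors, function(A) A * s)
    grams <- lapply(grams, function(G) G * s^2)
  }
  floor_val <- 1e-8 * (norm_x2 / prod(dims))^(1 / 8)
  rel_err <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    for (n in 1:4) {
      others <- setdiff(1:4, n)
      W <- khatri_rao(factors[others])
      P <- unfoldings[[n]] %*% W
      V <- Reduce(`*`, grams[others])
      A <- factors[[n]]
      for (r in seq_len(R)) {
        a <- A[, r] + (P[, r] - A %*% V[, r]) / V[r, r]
        A[, r] <- pmax(a, floor_val)
      }
      factors[[n]] <- A
      grams[[n]] <- crossprod(A)
    }
    # error after the sweep from the mode-4 update quantities (P and V are
    # those of the just-updated last mode, so the identity is exact)
    err2 <- norm_x2 - 2 * sum(factors[[4]] * P) + sum(V * grams[[4]])
    new_rel <- max(err2, 0) / norm_x2
    if (is.finite(rel_err) && abs(rel_err - new_rel) < tol) {
      rel_err <- new_rel
      converged <- TRUE
      break
    }
    rel_err <- new_rel
  }
  list(factors = factors, rel_err = rel_err, n_iter = iter,
       converged = converged)
}

# Put each component's scale into a weight, redistribute it evenly across the
# four modes (so no single mode carries the magnitude), and sort components
# by total weight, descending, for stable reporting (CP factors are
# permutable).
rebalance_and_sort <- function(factors) {
  R <- ncol(factors[[1]])
  lambda <- rep(1, R)
  for (n in 1:4) {
    nrm <- sqrt(colSums(factors[[n]]^2))
    nrm[nrm == 0] <- 1
    factors[[n]] <- sweep(factors[[n]], 2, nrm, "/")
    lambda <- lambda * nrm
  }
  ord <- order(lambda, decreasing = TRUE)
  scale_back <- lambda[ord]^(1 / 4)
  lapply(factors, function(A)
    sweep(A[, ord, drop = FALSE], 2, scale_back, "*"))
}

#' Reconstruct the tensor approximated by a decomposition
#'
#' Entrywise sum over factors of the products of the four loading vectors:
#' the low-rank approximation of the communication tensor.
#'
#' @param d a `"cp_decomposition"`.
#' @return 4-way non-negative array with the decomposition's axis labels.
#' @export
reconstruct <- function(d) {
  stopifnot(inherits(d, "cp_decomposition"))
  f <- d$factors
  w <- if (is.null(d$weights)) rep(1, d$rank) else d$weights
  A1 <- sweep(f[[1]], 2, w, "*")
  dims <- unname(vapply(f, nrow, 1L))
  M <- A1 %*% t(khatri_rao(f[2:4]))
  arr <- array(as.vector(M), dim = dims)
  dimnames(arr) <- lapply(f, rownames)
  arr
}

#' Normalized reconstruction error
#'
#' Residual squared Frobenius norm divided by the tensor's squared Frobenius
#' norm; lies in \[0, 1\] for a non-negative fit and is analogous to the
#' fraction of unexplained variance in PCA.
#'
#' @param x a [comm_tensor] or 4-way array (not all zero).
#' @param d a `"cp_decomposition"` with matching shape.
#' @return numeric scalar in \[0, 1\].
#' @export
normalized_error <- function(x, d) {
  arr <- tensor_array(x)
  rec <- reconstruct(d)
  if (!identical(dim(arr), dim(rec)))
    stop("tensor and decomposition shapes do not match")
  denom <- sum(arr^2)
  if (denom == 0) stop("tensor is all zero; normalized error is undefined")
  sum((arr - rec)^2) / denom
}

#' Scale every factor column to unit Euclidean length
#'
#' Rescales each loading vector of each dimension to unit L2 norm, the
#' convention used for reporting and plotting loadings. The component scales
#' are preserved in `weights` so [reconstruct()] is unchanged.
#'
#' @param d a `"cp_decomposition"`.
#' @return The decomposition with unit-norm factor columns and a `weights`
#'   vector.
#' @export
normalize_loadings <- function(d) {
  stopifnot(inherits(d, "cp_decomposition"))
  w <- if (is.null(d$weights)) rep(1, d$rank) else d$weights
  for (n in seq_along(d$factors)) {
    nrm <- sqrt(colSums(d$factors[[n]]^2))
    if (any(nrm == 0))
      stop("factor ", which(nrm == 0)[1], " has an all-zero ",
           names(d$factors)[n], " loading column; degenerate factor")
    d$factors[[n]] <- sweep(d$factors[[n]], 2, nrm, "/")
    w <- w * nrm
  }
  d$weights <- w
  d
}

#' Scan ranks and select one at the reconstruction-error elbow
#'
#' Fits the non-negative CP model at every rank in `ranks`, records the
#' normalized reconstruction error (best of `n_restarts` per rank), and
#' selects the elbow of the (rank, error) curve: the rank with maximum
#' perpendicular distance from the chord joining the curve's endpoints.
#' The full curve is returned so the automatic choice can be overridden.
#'
#' @inheritParams cp_decompose
#' @param ranks increasing vector of at least three candidate ranks.
#' @param ... passed to [cp_decompose()] (`tol`, `max_iter`).
#' @return An object of class `"rank_scan"`: list with `ranks`, `errors`,
#'   `selected`.
#' @export
select_rank <- function(x, ranks = 1:10, seed = 1L, n_restarts = 3L, ...) {
  ranks <- as.integer(ranks)
  if (length(ranks) < 3)
    stop("need at least three candidate ranks to locate an elbow")
  if (is.unsorted(ranks, strictly = TRUE))
    stop("`ranks` must be strictly increasing")
  errors <- vapply(ranks, function(r) {
    cp_decompose(x, rank = r, seed = seed, n_restarts = n_restarts,
                 keep_tensor = FALSE, ...)$norm_error
  }, numeric(1))
  structure(list(ranks = ranks, errors = errors,
                 selected = elbow_rank(ranks, errors),
                 seed = as.integer(seed)),
            class = "rank_scan")
}

# Max perpendicular distance from the chord between the first and last
# (rank, error) points.
elbow_rank <- function(ranks, errors) {
  x1 <- ranks[1]; y1 <- errors[1]
  x2 <- ranks[length(ranks)]; y2 <- errors[length(errors)]
  num <- abs((y2 - y1) * ranks - (x2 - x1) * errors + x2 * y1 - y2 * x1)
  den <- sqrt((y2 - y1)^2 + (x2 - x1)^2)
  ranks[which.max(num / den)]
}

#' @export
print.rank_scan <- function(x, ...) {
  cat("Rank scan over ranks", x$ranks[1], "..", x$ranks[length(x$ranks)],
      "\n  normalized errors:",
      paste(format(round(x$errors, 4), nsmall = 4), collapse = " "),
      "\n  selected rank (error-curve elbow):", x$selected, "\n")
  invisible(x)
}

#' @export
plot.rank_scan <- function(x, ...) {
  graphics::plot(x$ranks, x$errors, type = "b", pch = 16,
                 xlab = "rank", ylab = "normalized reconstruction error",
                 ...)
  graphics::abline(v = x$selected, lty = 2, col = "grey40")
}

#' @export
print.cp_decomposition <- function(x, ...) {
  d <- vapply(x$factors, nrow, 1L)
  cat("Non-negative CP decomposition, rank ", x$rank, "\n", sep = "")
  cat("  tensor: ", paste(d, collapse = " x "),
      " (contexts x pairs x senders x receivers)\n", sep = "")
  cat("  normalized reconstruction error: ",
      format(x$norm_error, digits = 5), "\n", sep = "")
  cat("  ", x$n_iter_run, " ALS sweeps (best of ", x$n_restarts,
      " restarts, seed ", x$seed, ")",
      if (!x$converged) " [not converged]", "\n", sep = "")
  if (!is.null(x$weights))
    cat("  loadings normalized to unit Euclidean length\n")
  invisible(x)
}

#' @export
summary.cp_decomposition <- function(object, n_top = 5L, ...) {
  nd <- normalize_loadings(if (is.null(object$weights)) object else object)
  top <- lapply(nd$factors, function(A) {
    apply(A, 2, function(col) {
      ord <- order(col, decreasing = TRUE)[seq_len(min(n_top, length(col)))]
      paste0(rownames(A)[ord], " (", format(round(col[ord], 3), nsmall = 3),
             ")", collapse = ", ")
    })
  })
  structure(list(rank = object$rank, norm_error = object$norm_error,
                 weights = nd$weights, top = top, n_top = n_top),
            class = "summary.cp_decomposition")
}

#' @export
print.summary.cp_decomposition <- function(x, ...) {
  cat("Non-negative CP decomposition, rank ", x$rank,
      " (normalized error ", format(x$norm_error, digits = 4), ")\n",
      sep = "")
  for (r in seq_len(x$rank)) {
    cat("\nFactor ", r, " (weight ", format(x$weights[r], digits = 4),
        ")\n", sep = "")
    for (dim_name in names(x$top))
      cat("  top ", dim_name, ": ", x$top[[dim_name]][r], "\n", sep = "")
  }
  invisible(x)
}

#' Extract factor loading matrices
#'
#' @param object a `"cp_decomposition"`.
#' @param dimension one of `"contexts"`, `"pairs"`, `"senders"`,
#'   `"receivers"`, or `NULL` for the full list.
#' @param ... unused.
#' @return A loading matrix (elements x factors), or the named list of all
#'   four.
#' @export
coef.cp_decomposition <- function(object, dimension = NULL, ...) {
  if (is.null(dimension)) return(object$factors)
  dimension <- match.arg(dimension, names(object$factors))
  object$factors[[dimension]]
}

#' @export
fitted.cp_decomposition <- function(object, ...) reconstruct(object)

#' @export
residuals.cp_decomposition <- function(object, ...) {
  if (is.null(object$tensor))
    stop("decomposition was fitted with keep_tensor = FALSE; ",
         "residuals are unavailable")
  object$tensor - reconstruct(object)
}

#' Plot factor loadings
#'
#' One row of bar panels per factor, one column per tensor dimension, after
#' unit-norm scaling — the standard loadings overview for a communication
#' decomposition.
#'
#' @param x a `"cp_decomposition"`.
#' @param dimensions which dimensions to show.
#' @param max_bars pair axes are often large; dimensions with more elements
#'   than this are drawn without per-element axis labels.
#' @param ... unused.
#' @export
plot.cp_decomposition <- function(x, dimensions = names(x$factors),
                                  max_bars = 30L, ...) {
  nd <- normalize_loadings(if (is.null(x$weights)) x else x)
  dimensions <- match.arg(dimensions, names(nd$factors), several.ok = TRUE)
  old <- graphics::par(mfrow = c(x$rank, length(dimensions)),
                       mar = c(2.5, 2.5, 1.5, 0.5), mgp = c(1.5, 0.4, 0))
  on.exit(graphics::par(old))
  for (r in seq_len(x$rank)) {
    for (dim_name in dimensions) {
      A <- nd$factors[[dim_name]]
      show_names <- nrow(A) <= max_bars
      graphics::barplot(A[, r], names.arg = if (show_names) rownames(A),
                        las = 2, cex.names = 0.6, col = "grey30",
                        border = NA,
                        main = if (r == 1) dim_name else "",
                        ylab = if (dim_name == dimensions[1])
                          paste0("factor ", r) else "")
    }
  }
  invisible(x)
}
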