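#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: one set per line, fields are set name,
#' description (ignored), then member genes.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) character(0) else unique(f[-(1:2)])
  })
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  out
}

#' Build LR pathway sets from gene sets
#'
#' Annotates each LR pair with the pathways whose gene set contains *all*
#' genes participating in the interaction (every ligand and receptor
#' subunit), then discards pathway sets with fewer than `min_size` pairs —
#' small sets make the enrichment statistic unstable.
#'
#' @param gene_sets named list of gene-symbol vectors (e.g. [read_gmt()]
#'   output).
#' @param catalog an [lr_catalog].
#' @param min_size minimum number of LR pairs a retained set must have
#'   (default 15).
#' @return Object of class `"lr_set_collection"`: list with `sets` (named
#'   list, pathway -> pair_ids) and `min_size`.
#' @export
build_lr_sets <- function(gene_sets, catalog, min_size = 15L) {
  stopifnot(inherits(catalog, "lr_catalog"))
  if (!length(gene_sets)) stop("`gene_sets` is empty")
  if (!length(catalog)) stop("`catalog` is empty")
  pair_genes <- mapply(function(l, r) unique(c(l, r)),
                       catalog$ligands, catalog$receptors,
                       SIMPLIFY = FALSE)
  sets <- lapply(gene_sets, function(gs) {
    keep <- vapply(pair_genes, function(g) all(g %in% gs), TRUE)
    catalog$pair_ids[keep]
  })
  sets <- sets[lengths(sets) >= min_size]
  structure(list(sets = sets, min_size = as.integer(min_size)),
            class = "lr_set_collection")
}

#' @export
print.lr_set_collection <- function(x, ...) {
  cat("LR pathway set collection:", length(x$sets),
      "sets (min size", x$min_size, ")\n")
  if (length(x$sets))
    print(utils::head(sort(lengths(x$sets), decreasing = TRUE), 10))
  invisible(x)
}

#' Pre-ranked gene-set enrichment on LR-pair loadings
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment of LR pathway sets in
#' the factor-wise ranking of LR pairs by loading. Pairs are ranked by
#' loading, descending, with ties broken by pair id (ascending) so the
#' ranking is strictly ordered and deterministic. Hits advance the running
#' sum proportionally to `|loading|^weight` (weight 1 by default; weight 0
#' recovers the classic unweighted KS statistic); misses decrement it
#' uniformly. The enrichment score (ES) is the signed maximum deviation.
#' The null is generated by `n_perm` seeded permutations of the pair
#' labels; the empirical p-value and the normalized score
#' `NES = ES / mean(|null ES| of matching sign)` are computed from the
#' same-sign part of the null, and p-values are Benjamini-Hochberg adjusted
#' jointly across all (factor, set) results.
#'
#' @param ranked_pairs named numeric vector (one factor's pair loadings) or
#'   a pairs x factors matrix such as `coef(d, "pairs")`.
#' @param sets an [build_lr_sets()] collection (or a named list of pair-id
#'   vectors); every set must be a subset of the ranked pairs.
#' @param n_perm number of permutations (default 999).
#' @param weight running-sum weight exponent on loading magnitudes
#'   (default 1).
#' @param seed integer seed for the permutation null.
#' @return data.frame with columns `factor`, `set`, `size`, `ES`, `NES`,
#'   `p`, `p_adj`.
#' @export
prerank_gsea <- function(ranked_pairs, sets, n_perm = 999L, weight = 1,
                         seed = 1L) {
  if (inherits(sets, "lr_set_collection")) sets <- sets$sets
  if (!length(sets)) stop("no sets to test")
  if (is.null(names(sets))) stop("`sets` must be named")
  mat <- if (is.matrix(ranked_pairs)) ranked_pairs
         else matrix(ranked_pairs, ncol = 1,
                     dimnames = list(names(ranked_pairs), "factor_1"))
  if (is.null(rownames(mat))) stop("pair loadings must be named by pair id")
  if (!nrow(mat)) stop("empty ranking")
  universe <- rownames(mat)
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], universe)
    if (length(extra))
      stop("set '", nm, "' contains pairs absent from the ranking: ",
           paste(utils::head(extra, 3), collapse = ", "))
  }

  set.seed(as.integer(seed))
  res <- list()
  for (f in seq_len(ncol(mat))) {
    x <- mat[, f]
    ord <- order(-x, universe, method = "radix")
    ranked_ids <- universe[ord]
    w <- abs(x[ord])^weight
    N <- length(w)
    # shared permutation null per set size within this factor
    null_cache <- new.env(parent = emptyenv())
    for (nm in names(sets)) {
      hits <- ranked_ids %in% sets[[nm]]
      m <- sum(hits)
      es <- ks_es(w, hits, m, N)
      key <- as.character(m)
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- vapply(seq_len(n_perm), function(b) {
          idx <- sample.int(N, m)
          h <- logical(N); h[idx] <- TRUE
          ks_es(w, h, m, N)
        }, numeric(1))
      }
      null <- null_cache[[key]]
      same <- if (es >= 0) null[null >= 0] else null[null < 0]
      p <- if (length(same))
        (1 + sum(abs(same) >= abs(es))) / (1 + length(same)) else 1
      nes <- if (length(same) && mean(abs(same)) > 0)
        es / mean(abs(same)) else NA_real_
      res[[length(res) + 1]] <- data.frame(
        factor = colnames(mat)[f], set = nm, size = m, ES = es, NES = nes,
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

# Signed maximum deviation of the weighted KS running sum.
ks_es <- function(w, hits, m, N) {
  if (m == 0 || m == N)
    stop("a set must be a strict, non-empty subset of the ranking")
  nr <- sum(w[hits])
  step <- numeric(N)
  step[hits] <- if (nr > 0) w[hits] / nr else 1 / m
  step[!hits] <- -1 / (N - m)
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}
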