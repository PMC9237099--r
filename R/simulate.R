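#' Canonical temporal communication patterns
#'
#' Four qualitatively distinct, non-negative score trajectories over a
#' context (time) axis: an oscillation, a pulse (elevated plateau over the
#' middle third of contexts), an exponential decay, and a linear decrease.
#' All curves run between `baseline` and `peak`, and at the default 12
#' contexts no two are close to proportional, so each can seed a separable
#' communication module.
#'
#' @param n_contexts number of contexts (>= 4).
#' @param baseline lowest curve value (also the background score level in
#'   the simulator).
#' @param peak highest curve value.
#' @return matrix `n_contexts` x 4 with columns `oscillation`, `pulse`,
#'   `exponential`, `linear`.
#' @export
pattern_curves <- function(n_contexts, baseline = 0.05, peak = 1) {
  n_contexts <- as.integer(n_contexts)
  if (n_contexts < 4)
    stop("need at least 4 contexts to express the four patterns")
  if (baseline < 0 || peak <= baseline)
    stop("need 0 <= baseline < peak")
  t <- seq_len(n_contexts) - 1L
  span <- n_contexts - 1L
  unit <- cbind(
    oscillation = (1 + sin(2 * pi * 2 * t / span)) / 2,
    pulse = as.numeric(t >= span / 3 & t <= 2 * span / 3),
    exponential = exp(-5 * t / span),
    linear = 1 - t / span
  )
  curves <- baseline + (peak - baseline) * unit
  rownames(curves) <- paste0("context_", seq_len(n_contexts))
  curves
}

#' Simulate a communication tensor with embedded context patterns
#'
#' Generates the synthetic study system: `n_celltypes` cell types
#' interacting through `n_pairs` LR pairs across `n_contexts` contexts
#' (time points). Pairs are partitioned into `n_pathways` equal signaling
#' pathways; four LR-CC combinations — a pathway plus one (sender,
#' receiver) cell pair — are drawn (seeded) so that combinations sharing a
#' pathway overlap in their LR pairs but not in their interacting cell
#' types (disjoint sender/receiver cell-type sets, so no single rank-one
#' term can absorb two modules), and each is assigned one of the four
#' [pattern_curves()]. A tensor entry belonging to a combination
#' follows its pattern's curve over contexts; every other entry sits at the
#' background score. Optional additive Gaussian noise (sd expressed as a
#' fraction of the peak amplitude) is clipped at zero to keep the tensor
#' non-negative.
#'
#' @param n_contexts,n_celltypes,n_pairs system size (defaults 12, 3, 300).
#' @param n_pathways number of equal pathway blocks (default 3; must divide
#'   `n_pairs`).
#' @param base_score background communication level (default 0.05).
#' @param noise_sd noise standard deviation as a fraction of the peak curve
#'   amplitude; 0 disables noise.
#' @param seed integer seed; regeneration with the same seed is bitwise
#'   identical.
#' @return list with `tensor` (a [comm_tensor]) and `truth`, an object of
#'   class `"sim_truth"` recording the pathway partition, the pattern ->
#'   (pathway, sender, receiver) combinations and the per-context curves.
#' @examples
#' sim <- simulate_comm_tensor(seed = 7)
#' dim(sim$tensor)  # 12 300 3 3
#' @export
simulate_comm_tensor <- function(n_contexts = 12L, n_celltypes = 3L,
                                 n_pairs = 300L, n_pathways = 3L,
                                 base_score = 0.05, noise_sd = 0,
                                 seed = 1L) {
  n_contexts <- as.integer(n_contexts); n_celltypes <- as.integer(n_celltypes)
  n_pairs <- as.integer(n_pairs); n_pathways <- as.integer(n_pathways)
  if (n_pairs %% n_pathways != 0)
    stop("`n_pathways` must divide `n_pairs` into equal blocks")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  curves <- pattern_curves(n_contexts, baseline = base_score)
  patterns <- colnames(curves)

  contexts <- paste0("context_", seq_len(n_contexts))
  cell_types <- paste0("cell_", LETTERS[seq_len(n_celltypes)])
  pairs <- sprintf("L%03d^R%03d", seq_len(n_pairs), seq_len(n_pairs))
  block <- n_pairs %/% n_pathways
  pathways <- stats::setNames(rep(paste0("pathway_", seq_len(n_pathways)),
                                  each = block), pairs)

  # Draw one (pathway, sender, receiver) combination per pattern. Every
  # combination gets its own (sender, receiver) cell pair, and combinations
  # assigned the same pathway must not overlap in their interacting cell
  # types at all ({sender, receiver} sets disjoint), so no module is a
  # rank-one merge of two others.
  set.seed(as.integer(seed))
  cc_pairs <- expand.grid(sender = cell_types, receiver = cell_types,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  combos <- NULL
  for (attempt in 1:100) {  # greedy placement can dead-end; redraw
    draw <- data.frame(pattern = patterns,
                       pathway = sample(rep_len(unique(pathways), 4)),
                       sender = NA_character_, receiver = NA_character_,
                       stringsAsFactors = FALSE)
    for (i in seq_len(nrow(draw))) {
      used <- draw[seq_len(i - 1), , drop = FALSE]
      shared <- used[used$pathway == draw$pathway[i], , drop = FALSE]
      taken_cells <- unique(c(shared$sender, shared$receiver))
      ok <- !(cc_pairs$sender %in% taken_cells |
                cc_pairs$receiver %in% taken_cells) &
        !(paste(cc_pairs$sender, cc_pairs$receiver) %in%
            paste(used$sender, used$receiver))
      if (!any(ok)) break
      cand <- which(ok)
      pick <- cc_pairs[cand[sample.int(length(cand), 1L)], ]
      draw$sender[i] <- pick$sender
      draw$receiver[i] <- pick$receiver
    }
    if (!anyNA(draw$sender)) {
      combos <- draw
      break
    }
  }
  if (is.null(combos))
    stop("cannot place combinations on distinct, pathway-disjoint cell ",
         "pairs; increase `n_celltypes`")

  arr <- array(base_score, dim = c(n_contexts, n_pairs, n_celltypes,
                                   n_celltypes))
  for (i in seq_len(nrow(combos))) {
    j <- which(pathways == combos$pathway[i])
    k <- match(combos$sender[i], cell_types)
    l <- match(combos$receiver[i], cell_types)
    arr[, j, k, l] <- curves[, combos$pattern[i]]
  }
  if (noise_sd > 0) {
    amp <- max(curves)
    arr <- arr + stats::rnorm(length(arr), sd = noise_sd * amp)
    arr <- pmax(arr, 0)
  }

  tensor <- comm_tensor(arr, contexts = contexts, pairs = pairs,
                        senders = cell_types, receivers = cell_types,
                        score_method = "external")
  truth <- structure(list(n_contexts = n_contexts,
                          n_celltypes = n_celltypes, n_pairs = n_pairs,
                          pathways = pathways, combos = combos,
                          curves = curves, base_score = base_score,
                          noise_sd = noise_sd, seed = as.integer(seed)),
                     class = "sim_truth")
  list(tensor = tensor, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated communication ground truth:", x$n_contexts, "contexts,",
      x$n_pairs, "LR pairs,", x$n_celltypes, "cell types\n")
  print(x$combos, row.names = FALSE)
  invisible(x)
}

#' Evaluate pattern recovery of a decomposition against simulation truth
#'
#' Greedily matches factors to ground-truth patterns by maximum Pearson
#' correlation between context loadings and the pattern curves (one-to-one,
#' best correlation first). For each matched pattern it reports that
#' correlation plus the Jaccard index between the combination's LR-pair set
#' and the matched factor's `n` top-loaded pairs (`n` = combination set
#' size).
#'
#' @param d a `"cp_decomposition"` with rank >= number of patterns.
#' @param truth a `"sim_truth"` from [simulate_comm_tensor()].
#' @return data.frame with one row per pattern: `pattern`, `factor`,
#'   `pearson_context`, `jaccard_pairs`.
#' @export
evaluate_recovery <- function(d, truth) {
  stopifnot(inherits(d, "cp_decomposition"), inherits(truth, "sim_truth"))
  patterns <- colnames(truth$curves)
  if (d$rank < length(patterns))
    stop("decomposition rank (", d$rank, ") is below the number of ",
         "ground-truth patterns (", length(patterns), ")")
  ctx <- coef(d, "contexts")
  cors <- stats::cor(truth$curves, ctx)  # patterns x factors

  matched <- rep(NA_integer_, length(patterns))
  free <- seq_len(d$rank)
  remaining <- seq_along(patterns)
  while (length(remaining)) {
    sub <- cors[remaining, free, drop = FALSE]
    best <- arrayInd(which.max(sub), dim(sub))
    p <- remaining[best[1]]; f <- free[best[2]]
    matched[p] <- f
    remaining <- setdiff(remaining, p)
    free <- setdiff(free, f)
  }

  pair_load <- coef(d, "pairs")
  out <- lapply(seq_along(patterns), function(p) {
    combo <- truth$combos[truth$combos$pattern == patterns[p], ]
    true_set <- names(truth$pathways)[truth$pathways == combo$pathway]
    f <- matched[p]
    top <- rownames(pair_load)[order(pair_load[, f],
                                     decreasing = TRUE)[seq_along(true_set)]]
    data.frame(pattern = patterns[p], factor = f,
               pearson_context = cors[p, f],
               jaccard_pairs = length(intersect(true_set, top)) /
                 length(union(true_set, top)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
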