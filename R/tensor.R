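#' 4D communication tensor
#'
#' Container for a labeled non-negative four-way array of cell-cell
#' communication scores with dimensions contexts x ligand-receptor pairs x
#' sender cell types x receiver cell types.
#'
#' @param data 4-way numeric array, non-negative and finite, with complete
#'   `dimnames` (contexts, pairs, senders, receivers) unless supplied via
#'   the label arguments.
#' @param contexts,pairs,senders,receivers optional axis labels; taken from
#'   `dimnames(data)` when `NULL`.
#' @param score_method how the scores were computed: `"mean"`, `"product"`,
#'   `"gmean"` or `"external"`.
#' @return An object of class `"comm_tensor"`.
#' @export
comm_tensor <- function(data, contexts = NULL, pairs = NULL, senders = NULL,
                        receivers = NULL,
                        score_method = c("mean", "product", "gmean",
                                         "external")) {
  score_method <- match.arg(score_method)
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4-way array (contexts x pairs x senders x receivers)")
  labs <- list(contexts, pairs, senders, receivers)
  dn <- dimnames(data)
  for (ax in 1:4) {
    if (is.null(labs[[ax]])) labs[[ax]] <- dn[[ax]]
    if (is.null(labs[[ax]]))
      stop("axis ", ax, " has no labels; supply dimnames or label arguments")
    labs[[ax]] <- as.character(labs[[ax]])
    if (length(labs[[ax]]) != dim(data)[ax])
      stop("axis ", ax, " label count does not match array shape")
    if (anyDuplicated(labs[[ax]]))
      stop("axis ", ax, " labels must be unique")
  }
  if (any(!is.finite(data))) stop("tensor entries must be finite")
  if (min(data) < 0) stop("tensor entries must be non-negative")
  data <- array(as.numeric(data), dim = dim(data))
  dimnames(data) <- stats::setNames(labs,
    c("context", "pair", "sender", "receiver"))
  structure(list(data = data, score_method = score_method),
            class = "comm_tensor")
}

#' @export
dim.comm_tensor <- function(x) dim(x$data)

#' @export
dimnames.comm_tensor <- function(x) dimnames(x$data)

#' @export
print.comm_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat("4D communication tensor (", x$score_method, " scores): ",
      d[1], " contexts x ", d[2], " LR pairs x ", d[3], " senders x ",
      d[4], " receivers\n", sep = "")
  cat("  values in [", format(min(x$data), digits = 4), ", ",
      format(max(x$data), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Score one ligand-receptor pair across all sender-receiver combinations
#'
#' Combines ligand expression in each sender cell type with receptor
#' expression in each receiver cell type into a sender x receiver matrix of
#' communication scores: the arithmetic mean `(L + R) / 2`, the product
#' `L * R`, or the geometric mean `sqrt(L * R)`.
#'
#' @param ligand_vals non-negative named vector: ligand (complex) expression
#'   per sender cell type.
#' @param receptor_vals non-negative named vector: receptor (complex)
#'   expression per receiver cell type.
#' @param method `"mean"`, `"product"` or `"gmean"`.
#' @return sender x receiver matrix of non-negative scores.
#' @export
score_pair <- function(ligand_vals, receptor_vals,
                       method = c("mean", "product", "gmean")) {
  method <- match.arg(method)
  if (min(ligand_vals) < 0 || min(receptor_vals) < 0)
    stop("expression values must be non-negative")
  out <- switch(method,
    mean = outer(ligand_vals, receptor_vals, function(l, r) (l + r) / 2),
    product = outer(ligand_vals, receptor_vals),
    gmean = sqrt(outer(ligand_vals, receptor_vals)))
  dimnames(out) <- list(names(ligand_vals), names(receptor_vals))
  out
}

#' Build the communication tensor from per-context profiles
#'
#' For every context and every LR pair in the catalog, computes the
#' sender x receiver communication-score matrix from complex-aware ligand
#' and receptor expression, then stacks the per-context 3D tensors into the
#' 4D tensor. Only cell types present in every context are kept (the
#' decomposition has no missing-value handling), sorted lexicographically
#' for determinism; contexts keep the input order of `profiles` (which is
#' meaningful for time series) and pairs keep catalog order.
#'
#' @param profiles list of [cell_type_profile] objects, one per context,
#'   with unique `context_id`s.
#' @param catalog an [lr_catalog]; it is filtered against the profiles
#'   first, and construction fails if nothing survives.
#' @param method communication score, see [score_pair()].
#' @return A [comm_tensor].
#' @export
build_comm_tensor <- function(profiles, catalog,
                              method = c("mean", "product", "gmean")) {
  method <- match.arg(method)
  if (length(profiles) < 2) stop("need at least two contexts")
  ids <- vapply(profiles, function(p) p$context_id, "")
  if (anyDuplicated(ids)) stop("context_ids must be unique")
  catalog <- filter_catalog(catalog, profiles)
  if (!length(catalog))
    stop("no LR pair has all subunit genes present in every context")
  cell_types <- sort(Reduce(intersect,
                            lapply(profiles, function(p) p$cell_types)))
  if (!length(cell_types))
    stop("no cell type is shared across all contexts")

  C <- length(profiles); P <- length(catalog); S <- length(cell_types)
  arr <- array(0, dim = c(C, P, S, S))
  for (i in seq_len(C)) {
    prof <- profiles[[i]]
    for (j in seq_len(P)) {
      lig <- complex_expression(prof, catalog$ligands[[j]])[cell_types]
      rec <- complex_expression(prof, catalog$receptors[[j]])[cell_types]
      arr[i, j, , ] <- score_pair(lig, rec, method)
    }
  }
  comm_tensor(arr, contexts = ids, pairs = catalog$pair_ids,
              senders = cell_types, receivers = cell_types,
              score_method = method)
}

#' Assemble a communication tensor from external edge lists
#'
#' Restructures per-context long-format communication scores, as produced
#' by external scoring tools (CellPhoneDB, CellChat, NATMI, ... typically
#' via LIANA), into the 4D tensor. The pair axis is the intersection of
#' pairs scored in every context, and the sender/receiver axes the
#' intersection of cell types observed in every context; a (sender,
#' receiver, pair) triple absent from a context within those kept axes is
#' filled with score 0.
#'
#' @param edge_lists named list of data.frames (one per context) with
#'   columns `sender`, `receiver`, `ligand_complex`, `receptor_complex`,
#'   `score` (or a precomputed `pair` column).
#' @param shift_negative if `TRUE`, negative scores are allowed and all
#'   scores are shifted globally by minus the overall minimum so the tensor
#'   is non-negative (a warning reports the shift); if `FALSE` (default)
#'   negative scores are an error.
#' @return A [comm_tensor] with `score_method = "external"`.
#' @export
tensor_from_edge_lists <- function(edge_lists, shift_negative = FALSE) {
  if (length(edge_lists) < 2) stop("need edge lists for at least two contexts")
  if (is.null(names(edge_lists)) || any(names(edge_lists) == ""))
    stop("`edge_lists` must be a named list (names are context ids)")
  edge_lists <- lapply(edge_lists, function(df) {
    df <- as.data.frame(df)
    if (!"pair" %in% names(df)) {
      need <- c("ligand_complex", "receptor_complex")
      if (!all(need %in% names(df)))
        stop("edge lists need a 'pair' column or 'ligand_complex' + ",
             "'receptor_complex' columns")
      df$pair <- paste(df$ligand_complex, df$receptor_complex, sep = "^")
    }
    for (col in c("sender", "receiver", "score"))
      if (!col %in% names(df)) stop("edge lists need a '", col, "' column")
    df[c("sender", "receiver", "pair", "score")]
  })
  all_scores <- unlist(lapply(edge_lists, function(df) df$score))
  if (any(!is.finite(all_scores))) stop("edge-list scores must be finite")
  shift <- 0
  if (min(all_scores) < 0) {
    if (!shift_negative)
      stop("negative communication scores found; the tensor must be ",
           "non-negative. Set shift_negative = TRUE to shift all scores ",
           "globally so the minimum becomes 0.")
    shift <- -min(all_scores)
    warning(sprintf("shifting all scores by +%g so the minimum is 0", shift))
  }

  pairs <- sort(Reduce(intersect,
                       lapply(edge_lists, function(df) unique(df$pair))))
  cell_types <- sort(Reduce(intersect, lapply(edge_lists, function(df)
    unique(c(df$sender, df$receiver)))))
  if (!length(pairs)) stop("no LR pair is scored in every context")
  if (!length(cell_types)) stop("no cell type is shared across all contexts")

  contexts <- names(edge_lists)
  arr <- array(0, dim = c(length(contexts), length(pairs),
                          length(cell_types), length(cell_types)))
  for (i in seq_along(contexts)) {
    df <- edge_lists[[i]]
    df <- df[df$pair %in% pairs & df$sender %in% cell_types &
               df$receiver %in% cell_types, , drop = FALSE]
    key <- paste(df$sender, df$receiver, df$pair, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)]
      conflicting <- any(vapply(unique(dup), function(k) {
        length(unique(df$score[key == k])) > 1
      }, TRUE))
      if (conflicting)
        stop("context '", contexts[i],
             "' has duplicated (sender, receiver, pair) rows with ",
             "conflicting scores")
      df <- df[!duplicated(key), , drop = FALSE]
    }
    idx <- cbind(i,
                 match(df$pair, pairs),
                 match(df$sender, cell_types),
                 match(df$receiver, cell_types))
    arr[idx] <- df$score + shift
  }
  comm_tensor(arr, contexts = contexts, pairs = pairs,
              senders = cell_types, receivers = cell_types,
              score_method = "external")
}

#' Flatten a communication tensor to a long data frame
#'
#' @param x a [comm_tensor].
#' @param ... unused.
#' @return data.frame with columns `context`, `pair`, `sender`, `receiver`,
#'   `score`, one row per tensor entry.
#' @export
as.data.frame.comm_tensor <- function(x, ...) {
  dn <- dimnames(x$data)
  d <- dim(x$data)
  out <- expand.grid(context = dn[[1]], pair = dn[[2]], sender = dn[[3]],
                     receiver = dn[[4]], KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$score <- as.vector(x$data)
  out
}

#' Write / read a communication tensor as long-format CSV
#'
#' Plain-text serialization: one row per entry with the four axis labels and
#' the score. `read_comm_tensor()` reconstructs the tensor with axis label
#' order taken from first appearance in the file, so a write/read round trip
#' is exact.
#'
#' @param x a [comm_tensor].
#' @param path CSV file path.
#' @return `write_comm_tensor()` returns `path` invisibly;
#'   `read_comm_tensor()` returns a [comm_tensor].
#' @export
write_comm_tensor <- function(x, path) {
  stopifnot(inherits(x, "comm_tensor"))
  df <- as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comm_tensor
#' @param score_method recorded scoring method for the reconstructed tensor.
#' @export
read_comm_tensor <- function(path, score_method = "external") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(context = "character",
                                       pair = "character",
                                       sender = "character",
                                       receiver = "character"))
  labs <- lapply(df[c("context", "pair", "sender", "receiver")], unique)
  arr <- array(NA_real_, dim = unname(lengths(labs)))
  idx <- cbind(match(df$context, labs$context), match(df$pair, labs$pair),
               match(df$sender, labs$sender),
               match(df$receiver, labs$receiver))
  arr[idx] <- df$score
  if (anyNA(arr)) stop("long CSV does not cover the full label grid")
  comm_tensor(arr, contexts = labs$context, pairs = labs$pair,
              senders = labs$sender, receivers = labs$receiver,
              score_method = score_method)
}
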