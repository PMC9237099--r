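#' Aggregate single-cell expression into a cell-type profile
#'
#' Summarises a cell x gene count matrix into a cell-type x gene matrix for
#' one context (sample, time point, ...). Three aggregation summaries are
#' supported:
#'
#' * `"nonzero_fraction"` (default): the fraction of cells of a type with a
#'   non-zero count for the gene. Values lie in \[0, 1\] and this summary
#'   represents lowly expressed genes (e.g. cell-surface receptors) better
#'   than a mean.
#' * `"mean_logcpm"`: per-cell counts-per-million, then `log(CPM + 1)`
#'   (base `log_base`, default 2), averaged within the type.
#' * `"mean_raw"`: mean of raw counts within the type.
#'
#' @param counts cell x gene matrix of non-negative counts (dense or
#'   `Matrix` sparse); columns must carry unique gene names, rows cell
#'   barcodes.
#' @param cell_labels character vector of cell-type labels, one per row of
#'   `counts` (or a named vector keyed by barcode).
#' @param method aggregation summary, see above.
#' @param context_id label for the context this profile belongs to.
#' @param log_base logarithm base for `"mean_logcpm"`.
#' @return An object of class `"cell_type_profile"`: list with `context_id`,
#'   `values` (cell-type x gene matrix), `genes`, `cell_types`,
#'   `aggregation`.
#' @examples
#' counts <- matrix(c(0, 0, 3, 5), nrow = 4,
#'                  dimnames = list(paste0("c", 1:4), "GENE1"))
#' p <- aggregate_expression(counts, rep("A", 4), "nonzero_fraction", "s1")
#' p$values  # 0.5: 2 of 4 cells express GENE1
#' @export
aggregate_expression <- function(counts,
                                 cell_labels,
                                 method = c("nonzero_fraction",
                                            "mean_logcpm", "mean_raw"),
                                 context_id = "context",
                                 log_base = 2) {
  method <- match.arg(method)
  if (is.null(colnames(counts)))
    stop("`counts` must have gene names as column names")
  if (anyDuplicated(colnames(counts)))
    stop("gene names must be unique; de-duplicate before aggregating")
  if (!is.null(names(cell_labels)) && !is.null(rownames(counts)))
    cell_labels <- cell_labels[rownames(counts)]
  cell_labels <- as.character(cell_labels)
  if (length(cell_labels) != nrow(counts))
    stop("`cell_labels` must provide one label per cell (row of `counts`)")
  if (anyNA(cell_labels) || any(cell_labels == ""))
    stop("unlabeled cell(s): every cell must have a cell-type label")
  if (min(counts) < 0) stop("`counts` must be non-negative")

  counts <- as.matrix(counts)
  types <- sort(unique(cell_labels))

  mat <- switch(method,
    nonzero_fraction = {
      nz <- counts > 0
      t(vapply(types, function(ty) colMeans(nz[cell_labels == ty, ,
                                               drop = FALSE]),
               numeric(ncol(counts))))
    },
    mean_logcpm = {
      libsize <- rowSums(counts)
      if (any(libsize == 0))
        stop("cell(s) with zero total counts cannot be CPM-normalized")
      logcpm <- log1p(counts / libsize * 1e6) / log(log_base)
      t(vapply(types, function(ty) colMeans(logcpm[cell_labels == ty, ,
                                                   drop = FALSE]),
               numeric(ncol(counts))))
    },
    mean_raw = t(vapply(types, function(ty)
      colMeans(counts[cell_labels == ty, , drop = FALSE]),
      numeric(ncol(counts))))
  )
  dimnames(mat) <- list(types, colnames(counts))
  cell_type_profile(mat, context_id = context_id, aggregation = method)
}

#' Construct a cell-type expression profile
#'
#' Low-level constructor wrapping an already-summarised cell-type x gene
#' matrix. Use [aggregate_expression()] to build one from counts.
#'
#' @param values non-negative cell-type x gene matrix with unique dimnames.
#' @param context_id context label.
#' @param aggregation how `values` was computed.
#' @return A `"cell_type_profile"` object.
#' @export
cell_type_profile <- function(values, context_id = "context",
                              aggregation = c("nonzero_fraction",
                                              "mean_logcpm", "mean_raw")) {
  aggregation <- match.arg(aggregation)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have cell types as rownames and genes as colnames")
  if (anyDuplicated(rownames(values))) stop("cell-type labels must be unique")
  if (anyDuplicated(colnames(values))) stop("gene labels must be unique")
  if (any(!is.finite(values)) || min(values) < 0)
    stop("profile values must be finite and non-negative")
  if (aggregation == "nonzero_fraction" && max(values) > 1 + 1e-12)
    stop("nonzero_fraction values must lie in [0, 1]")
  structure(list(context_id = as.character(context_id),
                 values = values,
                 genes = colnames(values),
                 cell_types = rownames(values),
                 aggregation = aggregation),
            class = "cell_type_profile")
}

#' @export
print.cell_type_profile <- function(x, ...) {
  cat("Cell-type expression profile '", x$context_id, "': ",
      length(x$cell_types), " cell types x ", length(x$genes),
      " genes (", x$aggregation, ")\n", sep = "")
  invisible(x)
}

#' Complex-aware expression of a ligand or receptor
#'
#' Expression of a (possibly heteromeric) protein across cell types: the
#' elementwise minimum over subunit genes, since the limiting subunit bounds
#' how much functional complex a cell type can assemble. A single-subunit
#' protein returns that gene's row unchanged.
#'
#' @param profile a [cell_type_profile].
#' @param subunits character vector of subunit gene symbols (length >= 1).
#' @return Named numeric vector over the profile's cell types.
#' @export
complex_expression <- function(profile, subunits) {
  stopifnot(inherits(profile, "cell_type_profile"))
  subunits <- as.character(subunits)
  if (!length(subunits)) stop("`subunits` must be non-empty")
  missing <- setdiff(subunits, profile$genes)
  if (length(missing))
    stop("subunit gene(s) absent from profile: ",
         paste(missing, collapse = ", "))
  sub <- profile$values[, subunits, drop = FALSE]
  out <- apply(sub, 1, min)
  names(out) <- profile$cell_types
  out
}
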