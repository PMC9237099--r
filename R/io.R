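#' Read a gene x cell expression matrix
#'
#' Supports Matrix Market triplet files with `genes`/`barcodes` sidecars
#' (the 10x-style layout) and dense CSV/TSV with genes as rows and cells as
#' columns. Returns the transposed cell x gene dense matrix used by
#' [aggregate_expression()].
#'
#' @param path path to a `.mtx` file or a dense delimited file.
#' @param genes_path,barcodes_path sidecar files (one label per line) for
#'   MTX input; default to `genes.tsv` / `barcodes.tsv` next to the matrix.
#' @param sep field separator for dense input (`","` for CSV, `"\t"` for
#'   TSV); guessed from the extension when `NULL`.
#' @return cell x gene numeric matrix with barcodes as rownames.
#' @export
read_expression_matrix <- function(path, genes_path = NULL,
                                   barcodes_path = NULL, sep = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- Matrix::readMM(path)
    dir <- dirname(path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.tsv")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.tsv")
    genes <- read_first_column(genes_path)
    barcodes <- read_first_column(barcodes_path)
    if (length(genes) != nrow(m))
      stop("genes sidecar has ", length(genes), " entries but matrix has ",
           nrow(m), " rows")
    if (length(barcodes) != ncol(m))
      stop("barcodes sidecar has ", length(barcodes),
           " entries but matrix has ", ncol(m), " columns")
    out <- t(as.matrix(m))
    dimnames(out) <- list(barcodes, genes)
    return(out)
  }
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  t(as.matrix(df))
}

read_first_column <- function(path) {
  if (!file.exists(path)) stop("sidecar file not found: ", path)
  vapply(strsplit(readLines(path), "\t", fixed = TRUE), `[`, "", 1)
}

#' Read a cell-annotation table
#'
#' TSV with columns `barcode` and `cell_type`.
#'
#' @param path file path.
#' @return named character vector mapping barcode to cell type.
#' @export
read_cell_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("barcode", "cell_type") %in% names(df)))
    stop("annotation file needs columns 'barcode' and 'cell_type'")
  stats::setNames(as.character(df$cell_type), df$barcode)
}

#' Read context metadata
#'
#' TSV with columns `context_id`, `group` and optionally `ordinal_level`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_context_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("context_id", "group") %in% names(df)))
    stop("context metadata needs columns 'context_id' and 'group'")
  df
}

#' Export decomposition loadings to TSV files
#'
#' Writes one TSV per tensor dimension (element label plus one
#' `factor_<r>` column per factor), a rank-scan CSV when supplied, and a
#' JSON snapshot of the fit configuration — everything needed to reproduce
#' and reuse the decomposition.
#'
#' @param d a `"cp_decomposition"`.
#' @param dir output directory, created if missing.
#' @param rank_scan optional `"rank_scan"` to write alongside.
#' @return `dir`, invisibly.
#' @export
export_loadings <- function(d, dir, rank_scan = NULL) {
  stopifnot(inherits(d, "cp_decomposition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(d$factors)) {
    df <- data.frame(element = rownames(d$factors[[nm]]),
                     d$factors[[nm]], check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(nm, "_loadings.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(rank_scan)) {
    utils::write.csv(data.frame(rank = rank_scan$ranks,
                                error = rank_scan$errors),
                     file.path(dir, "rank_scan.csv"), row.names = FALSE)
  }
  cfg <- list(rank = d$rank, seed = d$seed, tol = d$tol,
              max_iter = d$max_iter, n_restarts = d$n_restarts,
              n_iter_run = d$n_iter_run, converged = d$converged,
              norm_error = d$norm_error,
              normalized = !is.null(d$weights),
              weights = d$weights)
  jsonlite::write_json(cfg, file.path(dir, "decomposition_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
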