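#' Ligand-receptor interaction catalog
#'
#' Constructs an ordered catalog of ligand-receptor (LR) pairs. Ligands and
#' receptors may be heteromeric protein complexes; each is represented by a
#' non-empty character vector of subunit gene symbols. Roughly half of the
#' curated human LR interactions involve multi-subunit complexes, so complex
#' support is first-class rather than an afterthought.
#'
#' @param ligands list of character vectors, one per pair: ligand subunit
#'   gene symbols (length >= 1).
#' @param receptors list of character vectors, receptor subunits, same length
#'   as `ligands`.
#' @param pair_ids optional character vector of unique pair identifiers.
#'   Defaults to `"<ligand>^<receptor>"` with subunits joined by `"&"`.
#' @return An object of class `"lr_catalog"`: a list with elements
#'   `pair_ids`, `ligands`, `receptors`.
#' @examples
#' cat <- lr_catalog(list("TGFB1", c("IL12A", "IL12B")),
#'                   list(c("TGFBR1", "TGFBR2"), c("IL12RB1", "IL12RB2")))
#' cat$pair_ids
#' @export
lr_catalog <- function(ligands, receptors, pair_ids = NULL) {
  if (!is.list(ligands)) ligands <- as.list(ligands)
  if (!is.list(receptors)) receptors <- as.list(receptors)
  if (length(ligands) != length(receptors))
    stop("`ligands` and `receptors` must have the same length")
  ligands <- lapply(ligands, as.character)
  receptors <- lapply(receptors, as.character)
  bad <- which(vapply(ligands, length, 1L) < 1L |
               vapply(receptors, length, 1L) < 1L)
  if (length(bad))
    stop("pair ", bad[1], " has an empty ligand or receptor subunit list")
  if (any(vapply(c(ligands, receptors),
                 function(s) any(is.na(s) | s == ""), TRUE)))
    stop("subunit gene symbols must be non-missing and non-empty")
  if (is.null(pair_ids)) {
    pair_ids <- paste(vapply(ligands, paste, "", collapse = "&"),
                      vapply(receptors, paste, "", collapse = "&"),
                      sep = "^")
  }
  pair_ids <- as.character(pair_ids)
  if (length(pair_ids) != length(ligands))
    stop("`pair_ids` length does not match the number of pairs")
  if (anyDuplicated(pair_ids))
    stop("duplicated pair_ids: ",
         paste(unique(pair_ids[duplicated(pair_ids)]), collapse = ", "))
  structure(list(pair_ids = pair_ids, ligands = ligands,
                 receptors = receptors),
            class = "lr_catalog")
}

#' @export
length.lr_catalog <- function(x) length(x$pair_ids)

#' @export
print.lr_catalog <- function(x, ...) {
  n <- length(x)
  n_complex <- sum(vapply(x$ligands, length, 1L) > 1L |
                   vapply(x$receptors, length, 1L) > 1L)
  cat("Ligand-receptor catalog:", n, "pairs (",
      n_complex, "involving complexes )\n")
  if (n) cat("  ", paste(utils::head(x$pair_ids, 5), collapse = ", "),
             if (n > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
`[.lr_catalog` <- function(x, i) {
  lr_catalog(x$ligands[i], x$receptors[i], x$pair_ids[i])
}

#' Read a ligand-receptor catalog from CSV
#'
#' Expects columns `ligand` and `receptor` holding subunit gene symbols
#' joined by a delimiter (`"&"` by convention, e.g. `"IL12A&IL12B"`), and an
#' optional `pair_id` column.
#'
#' @param path path to a CSV file.
#' @param delim subunit delimiter within the ligand/receptor fields.
#' @return An [lr_catalog].
#' @export
read_lr_catalog <- function(path, delim = "&") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor")
  if (!all(need %in% names(df)))
    stop("LR catalog CSV must have columns 'ligand' and 'receptor'")
  split_units <- function(s) strsplit(as.character(s), delim, fixed = TRUE)
  lr_catalog(split_units(df$ligand), split_units(df$receptor),
             pair_ids = if ("pair_id" %in% names(df)) df$pair_id else NULL)
}

#' Restrict a catalog to pairs measurable in every context
#'
#' Keeps only LR pairs whose every ligand and receptor subunit gene is
#' present in the gene list of every context's expression profile, so that
#' every tensor entry can be computed. Input order is preserved; the result
#' may be empty (downstream tensor construction rejects an empty catalog).
#'
#' @param catalog an [lr_catalog].
#' @param profiles a list of [cell_type_profile] objects, one per context.
#' @return The filtered [lr_catalog].
#' @export
filter_catalog <- function(catalog, profiles) {
  stopifnot(inherits(catalog, "lr_catalog"))
  if (length(profiles) < 1) stop("need at least one profile")
  shared_genes <- Reduce(intersect, lapply(profiles, function(p) p$genes))
  keep <- vapply(seq_along(catalog$pair_ids), function(i) {
    all(c(catalog$ligands[[i]], catalog$receptors[[i]]) %in% shared_genes)
  }, TRUE)
  catalog[keep]
}
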