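#' Validate a set of pipeline input files
#'
#' Checks that the expression matrix, cell annotations, context metadata
#' and LR catalog agree with each other before any computation, and
#' returns a machine-readable issue table instead of failing at the first
#' problem.
#'
#' @param paths named list; recognized entries: `expression` (named list or
#'   vector of per-context matrix paths), `annotations` (per-context
#'   annotation TSVs), `metadata` (context metadata TSV), `lr_catalog`
#'   (catalog CSV).
#' @param delim subunit delimiter in the catalog CSV.
#' @return data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `issue`, `detail`; zero rows when everything is consistent.
#' @export
validate_inputs <- function(paths, delim = "&") {
  issues <- list()
  note <- function(severity, issue, detail = "")
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, issue = issue, detail = detail,
      stringsAsFactors = FALSE)

  for (nm in intersect(names(paths), c("metadata", "lr_catalog"))) {
    if (!file.exists(paths[[nm]]))
      note("error", "missing file", paste0(nm, ": ", paths[[nm]]))
  }

  catalog <- NULL
  if (!is.null(paths$lr_catalog) && file.exists(paths$lr_catalog)) {
    df <- tryCatch(utils::read.csv(paths$lr_catalog,
                                   stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(df) || !all(c("ligand", "receptor") %in% names(df))) {
      note("error", "unparseable LR catalog",
           "needs columns 'ligand' and 'receptor'")
    } else {
      bad <- which(is.na(df$ligand) | df$ligand == "" |
                     is.na(df$receptor) | df$receptor == "")
      for (b in bad)
        note("error", "malformed pair",
             paste0("row ", b, " has an empty ligand or receptor field"))
      if (!length(bad))
        catalog <- tryCatch(read_lr_catalog(paths$lr_catalog, delim = delim),
                            error = function(e) {
                              note("error", "unparseable LR catalog",
                                   conditionMessage(e))
                              NULL
                            })
    }
  }

  meta <- NULL
  if (!is.null(paths$metadata) && file.exists(paths$metadata))
    meta <- tryCatch(read_context_metadata(paths$metadata),
                     error = function(e) {
                       note("error", "unparseable metadata",
                            conditionMessage(e))
                       NULL
                     })

  expr_paths <- paths$expression
  ann_paths <- paths$annotations
  if (!is.null(expr_paths)) {
    for (ctx in names(expr_paths)) {
      if (!file.exists(expr_paths[[ctx]])) {
        note("error", "missing file",
             paste0("expression[", ctx, "]: ", expr_paths[[ctx]]))
        next
      }
      counts <- tryCatch(read_expression_matrix(expr_paths[[ctx]]),
                         error = function(e) {
                           note("error", "unparseable expression matrix",
                                paste0(ctx, ": ", conditionMessage(e)))
                           NULL
                         })
      if (is.null(counts)) next
      if (!is.null(ann_paths[[ctx]]) && file.exists(ann_paths[[ctx]])) {
        ann <- read_cell_annotations(ann_paths[[ctx]])
        unlabeled <- setdiff(rownames(counts), names(ann))
        for (b in utils::head(unlabeled, 10))
          note("error", "unlabeled cell",
               paste0(ctx, ": barcode '", b, "' has no annotation"))
      } else if (!is.null(ann_paths)) {
        note("error", "missing file",
             paste0("annotations[", ctx, "]"))
      }
      if (!is.null(meta) && !ctx %in% meta$context_id)
        note("warning", "context missing from metadata", ctx)
    }
  }

  if (length(issues)) do.call(rbind, issues)
  else data.frame(severity = character(), issue = character(),
                  detail = character(), stringsAsFactors = FALSE)
}

#' Run the full communication-decomposition pipeline
#'
#' Orchestrates one end-to-end analysis from a single configuration: build
#' the tensor (from expression data, from external edge lists, or from the
#' simulator), scan ranks, fit the non-negative CP model at the selected
#' rank, normalize loadings, and run the requested downstream analyses.
#' Everything is written into `out_dir` together with a JSON snapshot of
#' the configuration and a log recording the seed and settings, so a rerun
#' of the same config reproduces the outputs byte for byte.
#'
#' @param config named list (or path to a YAML/JSON file readable by
#'   `yaml::read_yaml` / `jsonlite::read_json`). Recognized fields:
#'   * `mode`: `"simulate"`, `"build"` or `"edge_lists"`.
#'   * `seed` (default 1), `rank` (fixed rank; otherwise `ranks`, default
#'     1..10, drives elbow selection), `tol`, `max_iter`, `n_restarts`.
#'   * `score_method`, `aggregation` for `"build"` mode, plus `expression`,
#'     `annotations`, `lr_catalog`, `metadata` paths.
#'   * `edge_lists`: named list of CSV paths for `"edge_lists"` mode.
#'   * `simulate`: list of [simulate_comm_tensor()] arguments.
#'   * `downstream`: list of toggles — `groups` (context group labels or
#'     `TRUE` to use metadata), `ordinal_levels`, `cluster_k`, `gsea` with
#'     `gmt` path.
#' @param out_dir output directory.
#' @return list with the tensor, rank scan, decomposition and downstream
#'   results (invisibly also written under `out_dir`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package; ",
             "pass a JSON file or a list instead")
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(mode = "simulate", seed = 1L, ranks = 1:10, rank = NULL,
         tol = 1e-7, max_iter = 500L, n_restarts = 3L,
         score_method = "mean", aggregation = "nonzero_fraction",
         simulate = list(), downstream = list()),
    config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logln <- function(...) cat(..., "\n", file = log_path, append = TRUE)
  cat("", file = log_path)
  logln("tensorccc", as.character(utils::packageVersion("tensorccc")),
        "| R", paste(R.version$major, R.version$minor, sep = "."))
  logln("seed:", cfg$seed, "| tol:", cfg$tol, "| max_iter:", cfg$max_iter,
        "| n_restarts:", cfg$n_restarts)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logln("FAILED at stage", name, ":", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  tensor <- stage("tensor", switch(cfg$mode,
    simulate = {
      args <- utils::modifyList(list(seed = cfg$seed), cfg$simulate)
      sim <- do.call(simulate_comm_tensor, args)
      truth <- sim$truth
      jsonlite::write_json(
        list(combos = sim$truth$combos,
             curves = as.data.frame(sim$truth$curves),
             base_score = sim$truth$base_score,
             noise_sd = sim$truth$noise_sd, seed = sim$truth$seed),
        file.path(out_dir, "sim_truth.json"), digits = NA,
        auto_unbox = TRUE)
      sim$tensor
    },
    build = {
      issues <- validate_inputs(cfg)
      if (any(issues$severity == "error")) {
        utils::write.csv(issues, file.path(out_dir, "validation_issues.csv"),
                         row.names = FALSE)
        stop("input validation failed; see validation_issues.csv")
      }
      profiles <- lapply(names(cfg$expression), function(ctx) {
        counts <- read_expression_matrix(cfg$expression[[ctx]])
        ann <- read_cell_annotations(cfg$annotations[[ctx]])
        aggregate_expression(counts, ann[rownames(counts)],
                             method = cfg$aggregation, context_id = ctx)
      })
      catalog <- read_lr_catalog(cfg$lr_catalog)
      build_comm_tensor(profiles, catalog, method = cfg$score_method)
    },
    edge_lists = {
      els <- lapply(cfg$edge_lists, utils::read.csv,
                    stringsAsFactors = FALSE)
      tensor_from_edge_lists(els,
                             shift_negative = isTRUE(cfg$shift_negative))
    },
    stop("unknown mode: ", cfg$mode)))
  logln("tensor:", paste(dim(tensor), collapse = " x "))
  write_comm_tensor(tensor, file.path(out_dir, "tensor.csv"))

  scan <- NULL
  rank <- cfg$rank
  if (is.null(rank)) {
    scan <- stage("select_rank",
                  select_rank(tensor, ranks = cfg$ranks, seed = cfg$seed,
                              n_restarts = cfg$n_restarts, tol = cfg$tol,
                              max_iter = cfg$max_iter))
    rank <- scan$selected
    logln("rank scan errors:",
          paste(format(scan$errors, digits = 5), collapse = " "))
  }
  logln("rank:", rank)

  fit <- stage("decompose",
               cp_decompose(tensor, rank = rank, seed = cfg$seed,
                            tol = cfg$tol, max_iter = cfg$max_iter,
                            n_restarts = cfg$n_restarts))
  fit <- normalize_loadings(fit)
  logln("normalized error:", format(fit$norm_error, digits = 6))
  export_loadings(fit, out_dir, rank_scan = scan)

  ds <- cfg$downstream
  downstream <- list()
  ctx_load <- coef(fit, "contexts")

  downstream$networks <- stage("networks", {
    nets <- lapply(seq_len(fit$rank), function(r) factor_network(fit, r))
    edges <- do.call(rbind, lapply(nets, function(nw) {
      df <- as.data.frame(as.table(nw$adjacency), stringsAsFactors = FALSE)
      names(df) <- c("sender", "receiver", "weight")
      cbind(factor = nw$factor_id, df, gini = nw$gini)
    }))
    utils::write.table(edges, file.path(out_dir, "factor_networks.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    nets
  })

  if (!is.null(ds$groups)) {
    groups <- ds$groups
    if (isTRUE(groups)) {
      meta <- read_context_metadata(cfg$metadata)
      groups <- meta$group[match(rownames(ctx_load), meta$context_id)]
    }
    downstream$group_stats <- stage("compare_groups", {
      gs <- compare_groups(ctx_load, groups)
      utils::write.table(gs, file.path(out_dir, "group_stats.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      gs
    })
  }
  if (!is.null(ds$ordinal_levels)) {
    downstream$ordinal <- stage("ordinal_correlation", {
      rho <- vapply(seq_len(fit$rank), function(r)
        ordinal_correlation(ctx_load[, r], ds$ordinal_levels)$rho,
        numeric(1))
      df <- data.frame(factor = seq_len(fit$rank), spearman_rho = rho)
      utils::write.table(df, file.path(out_dir, "ordinal_correlation.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      df
    })
  }
  if (!is.null(ds$cluster_k)) {
    downstream$clusters <- stage("cluster_samples", {
      cl <- cluster_samples(ctx_load, k = ds$cluster_k)
      utils::write.table(
        data.frame(context = names(cl$clusters), cluster = cl$clusters),
        file.path(out_dir, "sample_clusters.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      cl
    })
  }
  if (!is.null(ds$gsea)) {
    downstream$gsea <- stage("gsea", {
      catalog <- read_lr_catalog(cfg$lr_catalog)
      gene_sets <- read_gmt(ds$gsea$gmt)
      sets <- build_lr_sets(gene_sets, catalog,
                            min_size = ds$gsea$min_size %||% 15L)
      res <- prerank_gsea(coef(fit, "pairs"), sets,
                          n_perm = ds$gsea$n_perm %||% 999L,
                          weight = ds$gsea$weight %||% 1,
                          seed = cfg$seed)
      utils::write.table(res, file.path(out_dir, "gsea.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      res
    })
  }

  cfg_out <- cfg
  cfg_out$ranks <- as.integer(cfg$ranks)
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  logln("done")
  invisible(list(tensor = tensor, truth = truth, rank_scan = scan,
                 decomposition = fit, downstream = downstream,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
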