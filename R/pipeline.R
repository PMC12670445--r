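## Orchestration: read -> QC -> normalize -> graph -> coloc +
## composition, one reproducible run per condition.

#' Validate a pipeline run configuration
#'
#' Reads a JSON (or YAML, when the `yaml` package is available) config
#' file, fills documented defaults (`n_perm = 100`, `alpha = 0.05`,
#' `qc.min_umi = 500`, `qc.min_genes = 300`), and validates everything
#' at once: all problems are aggregated into a single error rather than
#' reported one at a time.
#'
#' Expected structure:
#' ```
#' {
#'   "conditions": [
#'     {"name": "day0", "matrix": "...", "features": "...",
#'      "barcodes": "...", "positions": "...", "proportions": "..."}
#'   ],
#'   "row_genes": "myeloid_genes.txt",   # one gene id per line
#'   "col_genes": "fibro_genes.txt",
#'   "qc": {"min_umi": 500, "min_genes": 300},
#'   "n_perm": 100, "alpha": 0.05, "seed": 1,
#'   "expression": "normalized",
#'   "use_pixels": true,
#'   "enrichment": {"type": "Fibroblast", "threshold": 0.25},
#'   "out_dir": "results"
#' }
#' ```
#'
#' @param path config file path
#' @return validated config list of class `run_config`
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  defaults <- list(n_perm = 100L, alpha = 0.05, seed = 1L,
                   expression = "normalized", use_pixels = TRUE,
                   qc = list(min_umi = 500, min_genes = 300),
                   enrichment = list(type = NULL, threshold = 0.25),
                   out_dir = "spotcoloc_out")
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      for (kk in names(defaults[[k]])) {
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- defaults[[k]][[kk]]
      }
    }
  }
  probs <- character(0)
  if (is.null(cfg$conditions) || length(cfg$conditions) == 0) {
    probs <- c(probs, "at least one condition is required")
  }
  need_file <- function(p, what) {
    if (is.null(p)) {
      probs <<- c(probs, paste(what, "path missing"))
    } else if (!file.exists(p)) {
      probs <<- c(probs, paste0(what, " not found: ", p))
    }
  }
  for (cond in cfg$conditions) {
    nm <- if (is.null(cond$name)) "<unnamed>" else cond$name
    for (f in c("matrix", "features", "barcodes", "positions")) {
      need_file(cond[[f]], paste0("condition '", nm, "' ", f))
    }
    if (!is.null(cond$proportions)) {
      need_file(cond$proportions, paste0("condition '", nm, "' proportions"))
    }
  }
  for (f in c("row_genes", "col_genes")) {
    if (!is.null(cfg[[f]])) need_file(cfg[[f]], f)
  }
  if (!is.numeric(cfg$n_perm) || cfg$n_perm < 1) {
    probs <- c(probs, "n_perm must be >= 1")
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha > 1) {
    probs <- c(probs, "alpha must satisfy 0 < alpha <= 1")
  }
  if (!cfg$expression %in% c("normalized", "raw", "external")) {
    probs <- c(probs, "expression must be one of normalized/raw/external")
  }
  th <- cfg$enrichment$threshold
  if (!is.numeric(th) || th < 0 || th > 1) {
    probs <- c(probs, "enrichment threshold must be in [0, 1]")
  }
  if (length(probs)) stop_aggregate(probs, "invalid run config")
  cfg$n_perm <- as.integer(cfg$n_perm)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

read_gene_list <- function(path) {
  if (is.null(path)) return(character(0))
  g <- read_lines_auto(path)
  g[nzchar(g)]
}

#' Run the full pipeline
#'
#' For each condition independently (one slide per condition; spots are
#' never pooled across slides): read counts + positions, keep in-tissue
#' spots, QC-filter, normalize, build the Delaunay graph, compute the
#' colocalization matrix over the configured gene lists, and — when a
#' proportion table is given — dominant-type labels, enriched spots and
#' marker tables. Per-condition subset frequencies are summarized
#' across conditions at the end.
#'
#' All outputs are plain text under `cfg$out_dir`; a re-run with the
#' same config and seed is byte-identical (wall time is logged to the
#' console, never serialized).
#'
#' @param cfg a validated `run_config` (or a path, validated on the fly)
#' @param quiet suppress stage logging
#' @return list of class `run_result`: per-condition results
#'   (`coloc`, `dominant`, `enriched`, `markers`, `graph`, `spots`),
#'   cross-condition `frequencies`, and `report`
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  log <- function(...) if (!quiet) message(sprintf(...))
  row_genes <- read_gene_list(cfg$row_genes)
  col_genes <- read_gene_list(cfg$col_genes)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  per_cond <- list()
  labels_all <- character(0)
  cond_all <- character(0)
  report_stages <- list()
  for (cond in cfg$conditions) {
    nm <- cond$name
    log("[%s] reading counts", nm)
    m <- read_counts(cond$matrix, cond$features, cond$barcodes, condition = nm)
    n_loaded <- ncol(m$counts)
    pos <- read_positions(cond$positions)
    m <- attach_positions(m, pos, use_pixels = isTRUE(cfg$use_pixels))
    n_tissue <- ncol(m$counts)
    m <- qc_filter(m, min_umi = cfg$qc$min_umi, min_genes = cfg$qc$min_genes)
    n_qc <- ncol(m$counts)
    log("[%s] spots: %d loaded, %d in tissue, %d post-QC", nm,
        n_loaded, n_tissue, n_qc)
    if (cfg$expression == "normalized") m <- normalize_spots(m)
    g <- build_delaunay_graph(m)
    log("[%s] graph: %d edges, mean degree %.2f", nm, nrow(g$edges),
        mean(lengths(g$neighbors)))
    write_graph_tsv(g, file.path(out_dir, paste0("graph_", nm, ".tsv")))

    cm <- NULL
    if (length(row_genes) && length(col_genes)) {
      src <- if (cfg$expression == "raw") "raw" else "normalized"
      cm <- coloc_matrix(m, row_genes, col_genes, g, n_perm = cfg$n_perm,
                         alpha = cfg$alpha, seed = cfg$seed, source = src)
      write_coloc(cm, out_dir, prefix = paste0("coloc_", nm))
      log("[%s] coloc: %d/%d significant at alpha=%g", nm,
          sum(cm$significant, na.rm = TRUE), length(cm$significant), cfg$alpha)
    }

    dom <- NULL; enr <- NULL; mk <- NULL; n_dominant <- NULL
    if (!is.null(cond$proportions)) {
      pt <- read_proportions(cond$proportions)
      keep <- match(m$barcodes, pt$barcodes)
      if (anyNA(keep)) {
        stop("condition '", nm, "': spots missing from proportions table",
             call. = FALSE)
      }
      pt <- proportion_table(pt$barcodes[keep], pt$cell_types,
                             pt$proportions[keep, , drop = FALSE])
      dom <- dominant_type(pt)
      n_dominant <- table(dom)
      writeLines(c("barcode\tlabel\tcondition",
                   paste(names(dom), dom, nm, sep = "\t")),
                 file.path(out_dir, paste0("dominant_", nm, ".tsv")))
      if (!is.null(cfg$enrichment$type)) {
        enr <- enriched_spots(pt, cfg$enrichment$type,
                              cfg$enrichment$threshold)
        log("[%s] %d spots enriched for %s (>= %g)", nm, length(enr),
            cfg$enrichment$type, cfg$enrichment$threshold)
        if (!is.null(m$normalized)) {
          grp <- m$barcodes %in% enr
          if (any(grp) && any(!grp)) {
            mk <- marker_test(m, grp)
            write_marker_tsv(mk, file.path(out_dir, paste0("markers_", nm, ".tsv")))
          }
        }
      }
      labels_all <- c(labels_all, unname(dom))
      cond_all <- c(cond_all, rep(nm, length(dom)))
    }
    report_stages[[nm]] <- list(
      loaded = n_loaded, in_tissue = n_tissue, post_qc = n_qc,
      n_edges = nrow(g$edges),
      dominant = if (is.null(n_dominant)) NULL else as.list(n_dominant),
      n_enriched = if (is.null(enr)) NULL else length(enr)
    )
    per_cond[[nm]] <- list(spots = m, graph = g, coloc = cm,
                           dominant = dom, enriched = enr, markers = mk)
  }

  freqs <- NULL
  if (length(labels_all)) {
    freqs <- subset_frequencies(labels_all, cond_all)
    write_frequencies_tsv(freqs, file.path(out_dir, "frequencies.tsv"))
  }

  report <- list(
    package_version = as.character(utils::packageVersion("spotcoloc")),
    seed = cfg$seed, n_perm = cfg$n_perm, alpha = cfg$alpha,
    qc = cfg$qc, expression = cfg$expression,
    stages = report_stages
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log("done in %.1f s", elapsed)
  report$wall_time_s <- elapsed  # in-memory only; keeps files byte-stable
  structure(list(conditions = per_cond, frequencies = freqs, report = report,
                 out_dir = out_dir),
            class = "run_result")
}

#' Write a marker table as TSV
#' @param mk a `marker_table`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_marker_tsv <- function(mk, path) {
  writeLines(c(
    "gene\tn_group1\tn_group2\tlog2fc\tp_value\tp_adj\tpasses_lfc",
    paste(mk$gene, mk$n_group1, mk$n_group2, fmt_num(mk$log2fc),
          fmt_num(mk$p_value), fmt_num(mk$p_adj), mk$passes_lfc, sep = "\t")
  ), path)
  invisible(path)
}

#' Write a composition summary as TSV
#' @param cs a `composition_summary`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_frequencies_tsv <- function(cs, path) {
  conds <- colnames(cs$counts)
  rows <- character(0)
  for (cn in conds) {
    rows <- c(rows, paste(rownames(cs$counts), cn, cs$counts[, cn],
                          fmt_num(cs$frequencies[, cn]), sep = "\t"))
  }
  writeLines(c("label\tcondition\tcount\tfrequency", rows), path)
  invisible(path)
}
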