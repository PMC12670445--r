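## Permutation-based gene-pair colocalization.
##
## The statistic asks: is gene A expressed where the *neighborhood* of a
## spot expresses gene B?  Concretely, the Pearson correlation of A's
## per-spot expression with the Delaunay-neighborhood average of B's
## expression.  Significance comes from shuffling B across spots
## (default 100 shuffles) and an add-one empirical p-value.  Note the
## statistic is not symmetric in (A, B).

#' Colocalization score of a gene pair
#'
#' Correlation of `x_a` with the neighborhood average of `x_b` over the
#' spatial graph. Pearson by default; Spearman available via `method`.
#'
#' @param x_a per-spot expression of gene A (the anchor: used as-is)
#' @param x_b per-spot expression of gene B (neighborhood-averaged)
#' @param g a `spatial_graph`
#' @param method `"pearson"` (default) or `"spearman"`
#' @param include_self include the focal spot in its neighborhood
#' @return scalar score in `[-1, 1]`
#' @export
coloc_score <- function(x_a, x_b, g, method = c("pearson", "spearman"),
                        include_self = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(g, "spatial_graph"))
  if (length(x_a) != g$n_spots || length(x_b) != g$n_spots) {
    stop("expression vectors must have length n_spots", call. = FALSE)
  }
  if (stats::sd(x_a) == 0) {
    stop("constant x_a: correlation undefined", call. = FALSE)
  }
  nb <- neighborhood_average(g, x_b, include_self = include_self)
  if (stats::sd(nb) == 0) {
    stop("constant neighborhood-averaged x_b: correlation undefined",
         call. = FALSE)
  }
  stats::cor(x_a, nb, method = method)
}

#' Permutation test for colocalization of one gene pair
#'
#' Computes the observed [coloc_score()] and a null distribution from
#' `n_perm` uniform random permutations of `x_b` over spots (shuffling
#' destroys spatial structure while preserving the value multiset). The
#' one-sided empirical p-value uses an add-one pseudocount,
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so `p >= 1/(n_perm+1)`
#' and is never zero.
#'
#' The permutation stream is derived deterministically from
#' `(seed, gene_a, gene_b)`, so results are reproducible and independent
#' of the order in which pairs are evaluated.
#'
#' @inheritParams coloc_score
#' @param n_perm number of shuffles (default 100)
#' @param seed master seed (integer)
#' @param gene_a,gene_b identifiers used for labeling and seed derivation
#' @return object of class `coloc_result`: `gene_a`, `gene_b`, `score`,
#'   `null_scores` (length `n_perm`), `p_value`, `n_perm`, `seed`
#' @export
permutation_test <- function(x_a, x_b, g, n_perm = 100, seed = 1L,
                             gene_a = "geneA", gene_b = "geneB",
                             method = c("pearson", "spearman"),
                             include_self = FALSE) {
  method <- match.arg(method)
  stopifnot(n_perm >= 1)
  obs <- coloc_score(x_a, x_b, g, method = method, include_self = include_self)
  W <- adjacency_operator(g, include_self = include_self)
  pair_seed <- derive_seed(seed, gene_a, gene_b)
  n <- g$n_spots
  perms <- with_seed(pair_seed, {
    vapply(seq_len(n_perm), function(k) sample.int(n), integer(n))
  })
  xb_perm <- matrix(x_b[perms], nrow = n, ncol = n_perm)
  nb_perm <- as.matrix(W %*% xb_perm)
  xa <- if (method == "spearman") rank(x_a) else x_a
  if (method == "spearman") nb_perm <- apply(nb_perm, 2, rank)
  null_scores <- suppressWarnings(as.numeric(stats::cor(xa, nb_perm)))
  # a permuted column can in principle average to a constant on tiny
  # graphs; cor() returns NA there — treat as non-exceeding
  p_value <- (1 + sum(null_scores >= obs, na.rm = TRUE)) / (1 + n_perm)
  structure(
    list(gene_a = gene_a, gene_b = gene_b, score = obs,
         null_scores = null_scores, p_value = p_value,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         method = method),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result: %s ~ navg(%s)  score = %.4f  p = %.4g (%d perms)\n",
              x$gene_a, x$gene_b, x$score, x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise colocalization matrix
#'
#' Runs [permutation_test()] for every (row gene, column gene) pair and
#' assembles score and p-value matrices plus a significance mask at
#' `alpha`. Convention: the *column* gene is gene A (the anchor whose
#' raw per-spot expression is used; e.g. fibroblast markers) and the
#' *row* gene is gene B (neighborhood-averaged; e.g. myeloid markers).
#'
#' Per-pair RNG streams derive from `(seed, gene_a, gene_b)`, so
#' subsetting the gene lists leaves surviving pairs' p-values unchanged.
#' Genes with all-zero expression are skipped with a warning and yield
#' `NA` entries.
#'
#' @param m a `spot_matrix` (with normalized values unless
#'   `source = "raw"`)
#' @param row_genes gene ids for the rows (neighborhood-averaged side)
#' @param col_genes gene ids for the columns (anchor side)
#' @param g a `spatial_graph` over the spots of `m`
#' @param n_perm shuffles per pair (default 100)
#' @param alpha significance threshold for the mask (default 0.05)
#' @param seed master seed
#' @param source expression source, `"normalized"` (default) or `"raw"`
#' @param method correlation type
#' @return object of class `coloc_matrix`: `row_genes`, `col_genes`,
#'   `scores`, `p_values`, `significant`, `alpha`, and `table` (long
#'   format with BH-adjusted p-values)
#' @export
coloc_matrix <- function(m, row_genes, col_genes, g, n_perm = 100,
                         alpha = 0.05, seed = 1L,
                         source = c("normalized", "raw"),
                         method = c("pearson", "spearman")) {
  source <- match.arg(source)
  method <- match.arg(method)
  stopifnot(inherits(m, "spot_matrix"), inherits(g, "spatial_graph"))
  unknown <- setdiff(c(row_genes, col_genes), m$gene_ids)
  if (length(unknown)) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  expr <- lapply(stats::setNames(nm = unique(c(row_genes, col_genes))),
                 function(gid) gene_vector(m, gid, source = source))
  zero <- names(expr)[vapply(expr, function(v) all(v == 0), logical(1))]
  if (length(zero)) {
    warning("all-zero expression, skipped: ", paste(zero, collapse = ", "),
            call. = FALSE)
  }
  nr <- length(row_genes); nc <- length(col_genes)
  scores <- matrix(NA_real_, nr, nc, dimnames = list(row_genes, col_genes))
  pvals <- scores
  rows <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      gb <- row_genes[i]  # neighborhood-averaged
      ga <- col_genes[j]  # anchor
      if (ga %in% zero || gb %in% zero) next
      res <- permutation_test(expr[[ga]], expr[[gb]], g, n_perm = n_perm,
                              seed = seed, gene_a = ga, gene_b = gb,
                              method = method)
      scores[i, j] <- res$score
      pvals[i, j] <- res$p_value
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = ga, gene_b = gb, score = res$score,
        p_value = res$p_value, n_perm = n_perm, seed = seed,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene_a = character(0), gene_b = character(0),
               score = numeric(0), p_value = numeric(0),
               n_perm = integer(0), seed = integer(0))
  }
  tab$p_adj <- stats::p.adjust(tab$p_value, method = "BH")
  structure(
    list(row_genes = row_genes, col_genes = col_genes,
         scores = scores, p_values = pvals,
         significant = !is.na(pvals) & pvals <= alpha,
         alpha = alpha, table = tab),
    class = "coloc_matrix"
  )
}

#' @export
print.coloc_matrix <- function(x, ...) {
  cat(sprintf("coloc_matrix: %d x %d gene pairs, alpha = %g, %d significant\n",
              length(x$row_genes), length(x$col_genes), x$alpha,
              sum(x$significant, na.rm = TRUE)))
  invisible(x)
}

#' Write colocalization results to disk
#'
#' Emits a long-format TSV (`coloc_long.tsv`: gene_a, gene_b, score,
#' p_value, p_adj, n_perm, seed) and wide CSV score/p matrices
#' (`coloc_scores.csv`, `coloc_pvalues.csv`).
#'
#' @param cm a `coloc_matrix`
#' @param dir output directory
#' @param prefix filename prefix (default `"coloc"`)
#' @return invisibly, the paths written
#' @export
write_coloc <- function(cm, dir, prefix = "coloc") {
  stopifnot(inherits(cm, "coloc_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- file.path(dir, paste0(prefix, "_long.tsv"))
  tab <- cm$table
  lines <- c(
    paste(c("gene_a", "gene_b", "score", "p_value", "p_adj", "n_perm", "seed"),
          collapse = "\t"),
    if (nrow(tab)) paste(tab$gene_a, tab$gene_b, fmt_num(tab$score),
                         fmt_num(tab$p_value), fmt_num(tab$p_adj),
                         tab$n_perm, tab$seed, sep = "\t")
  )
  writeLines(lines, long)
  wide <- function(mat, path) {
    hdr <- paste(c("", colnames(mat)), collapse = ",")
    body <- vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], fmt_num(mat[i, ])), collapse = ",")
    }, character(1))
    writeLines(c(hdr, body), path)
  }
  sc <- file.path(dir, paste0(prefix, "_scores.csv"))
  pv <- file.path(dir, paste0(prefix, "_pvalues.csv"))
  wide(cm$scores, sc)
  wide(cm$p_values, pv)
  invisible(c(long = long, scores = sc, pvalues = pv))
}
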