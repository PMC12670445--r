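## Deconvolution-proportion composition summaries and Wilcoxon marker
## testing.

#' ProportionTable: per-spot cell-type proportions
#'
#' Validates a spots x types proportion matrix: values in `[0, 1]`
#' (tolerance 1e-9 on the bounds), unique type names, rows summing to 1
#' within 1e-3 (then renormalized to sum exactly 1).
#'
#' @param barcodes spot identifiers (unique)
#' @param cell_types type names (unique)
#' @param proportions numeric matrix, spots x types
#' @return object of class `proportion_table`
#' @export
proportion_table <- function(barcodes, cell_types, proportions) {
  proportions <- as.matrix(proportions)
  storage.mode(proportions) <- "double"
  if (anyDuplicated(barcodes)) stop("duplicate barcodes", call. = FALSE)
  if (anyDuplicated(cell_types)) stop("duplicate cell type names", call. = FALSE)
  if (nrow(proportions) != length(barcodes) ||
      ncol(proportions) != length(cell_types)) {
    stop("proportions must be |barcodes| x |cell_types|", call. = FALSE)
  }
  if (any(proportions < -1e-9) || any(proportions > 1 + 1e-9)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  proportions[proportions < 0] <- 0
  rs <- rowSums(proportions)
  if (nrow(proportions) > 0 && any(abs(rs - 1) > 1e-3)) {
    bad <- which(abs(rs - 1) > 1e-3)
    stop("row sums deviate from 1 by more than 1e-3 (rows ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...", ")", call. = FALSE)
  }
  if (nrow(proportions) > 0) proportions <- proportions / rs
  dimnames(proportions) <- list(as.character(barcodes), as.character(cell_types))
  structure(
    list(barcodes = as.character(barcodes),
         cell_types = as.character(cell_types),
         proportions = proportions),
    class = "proportion_table"
  )
}

#' @export
print.proportion_table <- function(x, ...) {
  cat(sprintf("proportion_table: %d spots x %d cell types (%s)\n",
              length(x$barcodes), length(x$cell_types),
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

#' Dominant cell type per spot
#'
#' The type with the largest deconvolved proportion in each spot. Ties
#' are broken by the lexicographically smallest type name, so the result
#' is deterministic regardless of column order.
#'
#' @param p a `proportion_table`
#' @return character vector of type labels, named by barcode
#' @export
dominant_type <- function(p) {
  stopifnot(inherits(p, "proportion_table"))
  ord <- order(p$cell_types)
  mat <- p$proportions[, ord, drop = FALSE]
  types <- p$cell_types[ord]
  idx <- apply(mat, 1, which.max)  # first max = lexicographically smallest
  stats::setNames(types[idx], p$barcodes)
}

#' Spots enriched for a cell type
#'
#' @param p a `proportion_table`
#' @param type cell type name
#' @param threshold minimum proportion, inclusive (default 0.25; the
#'   enrichment cutoff is a configuration choice, not a universal
#'   constant)
#' @return character vector of barcodes with
#'   `proportion[, type] >= threshold`
#' @export
enriched_spots <- function(p, type, threshold = 0.25) {
  stopifnot(inherits(p, "proportion_table"))
  if (!type %in% p$cell_types) stop("unknown cell type: ", type, call. = FALSE)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]", call. = FALSE)
  p$barcodes[p$proportions[, type] >= threshold]
}

#' Per-condition label frequencies
#'
#' Counts and fractions of each label (cell type or cluster subset)
#' within each condition; the backbone of per-timepoint composition
#' bar plots.
#'
#' @param labels per-spot label vector
#' @param condition per-spot condition vector, same length
#' @return object of class `composition_summary`: `counts` and
#'   `frequencies` (label x condition matrices), `n_spots` per condition
#' @export
subset_frequencies <- function(labels, condition) {
  if (length(labels) != length(condition)) {
    stop("labels and condition must have equal length", call. = FALSE)
  }
  condition <- as.character(condition)
  labels <- as.character(labels)
  conds <- if (is.factor(condition)) levels(condition) else sort(unique(condition))
  n_per <- table(factor(condition, levels = conds))
  if (any(n_per == 0) || length(conds) == 0) {
    stop("every condition must have at least one spot", call. = FALSE)
  }
  labs <- sort(unique(labels))
  counts <- table(factor(labels, levels = labs),
                  factor(condition, levels = conds))
  counts <- matrix(as.integer(counts), nrow = length(labs),
                   dimnames = list(labs, conds))
  freqs <- sweep(counts, 2, colSums(counts), "/")
  structure(
    list(counts = counts, frequencies = freqs,
         n_spots = stats::setNames(as.integer(n_per), conds)),
    class = "composition_summary"
  )
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("composition_summary over conditions:",
      paste(colnames(x$counts), collapse = ", "), "\n")
  print(round(x$frequencies, 3))
  invisible(x)
}

#' Wilcoxon rank-sum marker test with log2 fold-change filter
#'
#' Per-gene two-group comparison on normalized expression: a two-sided
#' Wilcoxon rank-sum test (exact by complete enumeration when both
#' groups have <= `exact_limit` spots, otherwise the normal
#' approximation with tie correction) and a Seurat-style fold change
#' `log2((mean1 + 1) / (mean2 + 1))` computed on de-logged normalized
#' values. `passes_lfc` is `|log2fc| > lfc_threshold` by default;
#' `direction = "up"` keeps only `log2fc > lfc_threshold`.
#'
#' Genes with zero variance across both groups combined get `p = 1`,
#' `log2fc = 0`.
#'
#' @param m a `spot_matrix` with normalized values
#' @param group logical or 0/1 vector over spots; `TRUE`/1 = group 1
#' @param lfc_threshold log2 fold-change cutoff (default 0.25)
#' @param genes optional subset of gene ids (default: all)
#' @param direction `"both"` (default) or `"up"`
#' @param exact_limit max group size for the exact test (default 10)
#' @return data.frame of class `marker_table`: gene, group sizes,
#'   log2fc, p_value, p_adj (BH), passes_lfc; sorted by p_value
#' @export
marker_test <- function(m, group, lfc_threshold = 0.25, genes = NULL,
                        direction = c("both", "up"), exact_limit = 10L) {
  direction <- match.arg(direction)
  stopifnot(inherits(m, "spot_matrix"))
  if (is.null(m$normalized)) {
    stop("normalized values required; run normalize_spots() first", call. = FALSE)
  }
  group <- as.logical(group)
  if (length(group) != ncol(m$counts)) {
    stop("group length must equal number of spots", call. = FALSE)
  }
  n1 <- sum(group); n2 <- sum(!group)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  if (is.null(genes)) genes <- m$gene_ids
  norm <- as.matrix(m$normalized[match(genes, m$gene_ids), , drop = FALSE])
  res <- lapply(seq_along(genes), function(k) {
    v <- norm[k, ]
    v1 <- v[group]; v2 <- v[!group]
    if (stats::sd(v) == 0) {
      return(c(log2fc = 0, p = 1))
    }
    mean1 <- mean(expm1(v1)); mean2 <- mean(expm1(v2))
    lfc <- log2((mean1 + 1) / (mean2 + 1))
    p <- wilcox_rank_sum(v1, v2, exact_limit = exact_limit)
    c(log2fc = lfc, p = p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    gene = genes,
    n_group1 = n1, n_group2 = n2,
    log2fc = res[, "log2fc"],
    p_value = res[, "p"],
    p_adj = stats::p.adjust(res[, "p"], method = "BH"),
    stringsAsFactors = FALSE
  )
  out$passes_lfc <- if (direction == "both") {
    abs(out$log2fc) > lfc_threshold
  } else {
    out$log2fc > lfc_threshold
  }
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact complete enumeration of the rank-sum distribution (ties
#' handled via midranks) when both groups are small; otherwise the
#' normal approximation with the standard tie correction to the
#' variance (no continuity correction, documented).
#'
#' @param v1,v2 numeric samples
#' @param exact_limit both groups <= this size triggers the exact path
#' @return two-sided p-value
#' @export
wilcox_rank_sum <- function(v1, v2, exact_limit = 10L) {
  n1 <- length(v1); n2 <- length(v2); n <- n1 + n2
  r <- rank(c(v1, v2))
  w <- sum(r[seq_len(n1)])
  if (n1 <= exact_limit && n2 <= exact_limit) {
    ## enumerate every assignment of n1 of the n midranks to group 1
    combs <- utils::combn(n, n1)
    sums <- colSums(matrix(r[combs], nrow = n1))
    mu <- mean(sums)
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    return(p)
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}
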