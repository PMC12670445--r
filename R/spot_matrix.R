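#' SpotMatrix: a gene-by-spot count container
#'
#' Light S3 container for Visium-style spot data: a sparse gene x spot
#' count matrix plus gene identifiers, display symbols, spot barcodes,
#' optional 2D coordinates, an optional normalized matrix of the same
#' shape, and a free-text condition label for the dataset (e.g. "day0").
#'
#' Invariants enforced at construction:
#' * `nrow(counts) == length(gene_ids) == length(gene_names)`,
#'   `ncol(counts) == length(barcodes)`
#' * counts are non-negative integers (stored sparse)
#' * barcodes are unique; gene_ids are unique (gene_names may repeat)
#' * coords, when present, has one row per barcode and no duplicated
#'   positions
#'
#' @param counts gene x spot matrix (coerced to [Matrix::dgCMatrix-class])
#' @param gene_ids unique gene identifier per row
#' @param gene_names display symbol per row (may repeat); defaults to
#'   `gene_ids`
#' @param barcodes unique spot identifier per column
#' @param coords optional numeric matrix (n_spots x 2) of x,y positions
#' @param condition free-text dataset label, e.g. `"day0"`
#' @param normalized optional matrix of the same shape as `counts`
#' @return an object of class `spot_matrix`
#' @export
spot_matrix <- function(counts, gene_ids, gene_names = gene_ids, barcodes,
                        coords = NULL, condition = NA_character_,
                        normalized = NULL) {
  if (!methods::is(counts, "Matrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(gene_ids)) {
    stop("nrow(counts) != length(gene_ids)", call. = FALSE)
  }
  if (length(gene_names) != length(gene_ids)) {
    stop("gene_names and gene_ids lengths differ", call. = FALSE)
  }
  if (ncol(counts) != length(barcodes)) {
    stop("ncol(counts) != length(barcodes)", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("barcodes must be unique", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("gene_ids must be unique", call. = FALSE)
  }
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != floor(v)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dimnames(counts) <- list(as.character(gene_ids), as.character(barcodes))
  if (!is.null(coords)) {
    coords <- validate_coords(coords, barcodes)
  }
  if (!is.null(normalized)) {
    if (!all(dim(normalized) == dim(counts))) {
      stop("normalized matrix shape differs from counts", call. = FALSE)
    }
  }
  structure(
    list(
      counts = counts,
      gene_ids = as.character(gene_ids),
      gene_names = as.character(gene_names),
      barcodes = as.character(barcodes),
      coords = coords,
      condition = condition,
      normalized = normalized
    ),
    class = "spot_matrix"
  )
}

validate_coords <- function(coords, barcodes) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(barcodes) || ncol(coords) != 2L) {
    stop("coords must be an n_spots x 2 matrix", call. = FALSE)
  }
  if (anyDuplicated(coords) > 0L) {
    stop("duplicate spot coordinates", call. = FALSE)
  }
  rownames(coords) <- as.character(barcodes)
  colnames(coords) <- c("x", "y")
  coords
}

#' @export
dim.spot_matrix <- function(x) dim(x$counts)

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf("spot_matrix: %d genes x %d spots\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  condition: %s | coords: %s | normalized: %s\n",
              x$condition,
              if (is.null(x$coords)) "absent" else "present",
              if (is.null(x$normalized)) "absent" else "present"))
  invisible(x)
}

#' Subset a spot_matrix by spot (column) index
#'
#' Keeps genes; subsets counts, barcodes, coords and normalized in step.
#'
#' @param m a `spot_matrix`
#' @param idx integer or logical index over spots
#' @return a `spot_matrix`
#' @export
subset_spots <- function(m, idx) {
  stopifnot(inherits(m, "spot_matrix"))
  keep_bc <- m$barcodes[idx]
  spot_matrix(
    counts = m$counts[, idx, drop = FALSE],
    gene_ids = m$gene_ids,
    gene_names = m$gene_names,
    barcodes = keep_bc,
    coords = if (is.null(m$coords)) NULL else m$coords[idx, , drop = FALSE],
    condition = m$condition,
    normalized = if (is.null(m$normalized)) NULL else m$normalized[, idx, drop = FALSE]
  )
}

#' Extract an expression vector for one gene
#'
#' @param m a `spot_matrix`
#' @param gene gene id (row identifier)
#' @param source `"normalized"` (default; requires [normalize_spots()] to
#'   have been run or an external matrix attached) or `"raw"`
#' @return numeric vector over spots
#' @export
gene_vector <- function(m, gene, source = c("normalized", "raw")) {
  source <- match.arg(source)
  i <- match(gene, m$gene_ids)
  if (is.na(i)) stop("unknown gene: ", gene, call. = FALSE)
  mat <- if (source == "normalized") {
    if (is.null(m$normalized)) {
      stop("no normalized values; run normalize_spots() first", call. = FALSE)
    }
    m$normalized
  } else {
    m$counts
  }
  as.numeric(mat[i, ])
}
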