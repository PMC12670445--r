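## Reading SpaceRanger-style spot-level files, QC filtering and
## normalization.

#' Read a filtered feature-barcode matrix
#'
#' Loads a MatrixMarket coordinate matrix together with its features and
#' barcodes TSV sidecars (plain or gzipped, detected by magic bytes) into
#' a [spot_matrix()]. The matrix is kept genes x spots and sparse; zero
#' entries are never materialized.
#'
#' @param matrix_path path to `matrix.mtx(.gz)` (coordinate format)
#' @param features_path path to `features.tsv(.gz)`; column 1 = gene id,
#'   column 2 (optional) = gene symbol
#' @param barcodes_path path to `barcodes.tsv(.gz)`, one barcode per line
#' @param condition free-text label stored on the result
#' @return a `spot_matrix`
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path,
                        condition = NA_character_) {
  con <- open_auto(matrix_path)
  on.exit(close(con))
  mat <- tryCatch(
    Matrix::readMM(con),
    error = function(e) {
      stop("malformed MatrixMarket file '", matrix_path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  feat <- split_tsv(read_lines_auto(features_path))
  bc <- read_lines_auto(barcodes_path)
  bc <- bc[nzchar(bc)]
  if (nrow(feat) != nrow(mat)) {
    stop(sprintf("features file has %d rows but matrix declares %d genes",
                 nrow(feat), nrow(mat)), call. = FALSE)
  }
  if (length(bc) != ncol(mat)) {
    stop(sprintf("barcodes file has %d lines but matrix declares %d spots",
                 length(bc), ncol(mat)), call. = FALSE)
  }
  gene_ids <- feat[, 1]
  gene_names <- if (ncol(feat) >= 2L) feat[, 2] else feat[, 1]
  spot_matrix(mat, gene_ids = gene_ids, gene_names = gene_names,
              barcodes = bc, condition = condition)
}

#' Write a spot_matrix to MatrixMarket + TSV sidecars
#'
#' Inverse of [read_counts()]; only nonzero entries are written.
#'
#' @param m a `spot_matrix`
#' @param dir output directory (created if needed)
#' @return invisibly, the three file paths written
#' @export
write_counts <- function(m, dir) {
  stopifnot(inherits(m, "spot_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  feats <- file.path(dir, "features.tsv")
  bcs <- file.path(dir, "barcodes.tsv")
  Matrix::writeMM(m$counts, mtx)
  writeLines(paste(m$gene_ids, m$gene_names, "Gene Expression", sep = "\t"), feats)
  writeLines(m$barcodes, bcs)
  invisible(c(matrix = mtx, features = feats, barcodes = bcs))
}

#' Read a SpaceRanger tissue-positions table
#'
#' Accepts both dialects: the legacy headerless CSV and the headered
#' `tissue_positions.csv` (first field `barcode`). Columns, in order:
#' barcode, in_tissue, array_row, array_col, pxl_row_in_fullres,
#' pxl_col_in_fullres. Pixel columns are mapped to `pixel_y` (row) and
#' `pixel_x` (col), matching image axis conventions.
#'
#' @param positions_path CSV path (plain or gzipped)
#' @return data.frame with columns barcode, in_tissue, array_row,
#'   array_col, pixel_x, pixel_y, rows in file order
#' @export
read_positions <- function(positions_path) {
  lines <- read_lines_auto(positions_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty positions file", call. = FALSE)
  has_header <- grepl("^\"?barcode", lines[1])
  if (has_header) lines <- lines[-1]
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (any(lengths(parts) < 6L)) {
    stop("positions table needs >= 6 columns (SpaceRanger dialect)", call. = FALSE)
  }
  get <- function(k) vapply(parts, `[[`, character(1), k)
  in_tissue_chr <- get(2)
  if (!all(in_tissue_chr %in% c("0", "1"))) {
    bad <- setdiff(unique(in_tissue_chr), c("0", "1"))
    stop("in_tissue must be 0 or 1; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    barcode = get(1),
    in_tissue = as.integer(in_tissue_chr),
    array_row = as.integer(get(3)),
    array_col = as.integer(get(4)),
    pixel_y = as.numeric(get(5)),
    pixel_x = as.numeric(get(6)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$barcode)) {
    stop("duplicate barcodes in positions table", call. = FALSE)
  }
  out
}

#' Attach spatial coordinates to a spot_matrix
#'
#' Joins a positions table onto the matrix by barcode, drops spots with
#' `in_tissue == 0`, and populates `coords`. With `use_pixels = TRUE`
#' (default) full-resolution pixel coordinates are used directly. The
#' fallback maps array indices onto a Cartesian hex lattice — Visium
#' interleaves columns across rows, so `x = array_col * 0.5`,
#' `y = array_row * sqrt(3) / 2`.
#'
#' @param m a `spot_matrix`
#' @param p positions table from [read_positions()]
#' @param use_pixels use pixel coordinates (default) instead of the
#'   array-index hex transform
#' @return `spot_matrix` with `coords` set, restricted to in-tissue spots
#' @export
attach_positions <- function(m, p, use_pixels = TRUE) {
  stopifnot(inherits(m, "spot_matrix"))
  idx <- match(m$barcodes, p$barcode)
  if (anyNA(idx)) {
    missing <- m$barcodes[is.na(idx)]
    stop("barcodes absent from positions table: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  }
  p <- p[idx, , drop = FALSE]
  coords <- if (use_pixels) {
    cbind(x = p$pixel_x, y = p$pixel_y)
  } else {
    cbind(x = p$array_col * 0.5, y = p$array_row * (sqrt(3) / 2))
  }
  keep <- p$in_tissue == 1L
  m2 <- m
  m2$coords <- coords  # validated (incl. duplicate check) on the kept set
  subset_spots(m2, which(keep))
}

#' Spot quality-control filter
#'
#' Retains exactly the spots with total UMI count strictly greater than
#' `min_umi` and number of detected genes (count > 0) strictly greater
#' than `min_genes`. Strict inequalities are deliberate. The number of
#' spots removed is attached as attribute `"qc_report"` and retrievable
#' with [qc_report()].
#'
#' @param m a `spot_matrix`
#' @param min_umi minimum total UMIs, exclusive (default 500)
#' @param min_genes minimum detected genes, exclusive (default 300)
#' @return filtered `spot_matrix` with a `qc_report` attribute
#' @export
qc_filter <- function(m, min_umi = 500, min_genes = 300) {
  stopifnot(inherits(m, "spot_matrix"))
  umi <- Matrix::colSums(m$counts)
  genes <- Matrix::colSums(m$counts > 0)
  keep <- umi > min_umi & genes > min_genes
  out <- subset_spots(m, which(keep))
  attr(out, "qc_report") <- list(
    n_before = length(keep),
    n_after = sum(keep),
    n_removed = sum(!keep),
    min_umi = min_umi,
    min_genes = min_genes
  )
  out
}

#' Retrieve the QC report attached by qc_filter
#' @param m a `spot_matrix` returned by [qc_filter()]
#' @return list with n_before, n_after, n_removed and the thresholds used
#' @export
qc_report <- function(m) attr(m, "qc_report")

#' Median-library-size normalization
#'
#' Scales each spot so its total equals the median spot total, then
#' applies `log1p`. This is a deliberately simple, documented stand-in
#' for regularized NB normalization (an external method, not
#' reimplemented here); a matrix produced by an external tool can be
#' attached instead via `external`.
#'
#' Zeros map to zeros, so the sparse pattern is preserved.
#'
#' @param m a `spot_matrix` with at least one spot
#' @param external optional pre-normalized matrix (same shape as counts)
#'   attached verbatim, bypassing the internal scheme
#' @return `spot_matrix` with `normalized` populated; counts unchanged
#' @export
normalize_spots <- function(m, external = NULL) {
  stopifnot(inherits(m, "spot_matrix"))
  if (!is.null(external)) {
    if (!all(dim(external) == dim(m$counts))) {
      stop("external matrix shape differs from counts", call. = FALSE)
    }
    m$normalized <- external
    return(m)
  }
  if (ncol(m$counts) < 1L) stop("no spots to normalize", call. = FALSE)
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0)) {
    stop("spot(s) with zero total counts; run qc_filter first", call. = FALSE)
  }
  target <- stats::median(totals)
  scaled <- m$counts %*% Matrix::Diagonal(x = target / totals)
  norm <- scaled
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m$counts)
  m$normalized <- methods::as(norm, "CsparseMatrix")
  m
}

#' Read a per-spot cell-type proportion table
#'
#' CSV with a barcode column followed by one column per cell type.
#' Values must lie in `[0, 1]`; each row must sum to 1 within 1e-3 and
#' is renormalized to sum exactly 1.
#'
#' @param path CSV path (plain or gzipped); first line must be a header
#' @return a [proportion_table()]
#' @export
read_proportions <- function(path) {
  lines <- read_lines_auto(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("proportions file needs header + data", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  cell_types <- header[-1]
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  if (any(lengths(parts) != length(header))) {
    stop("ragged proportions table", call. = FALSE)
  }
  barcodes <- vapply(parts, `[[`, character(1), 1)
  prop <- t(vapply(parts, function(p) as.numeric(p[-1]),
                   numeric(length(cell_types))))
  if (length(cell_types) == 1L) prop <- matrix(prop, ncol = 1L)
  proportion_table(barcodes, cell_types, prop)
}
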