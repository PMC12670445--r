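## Delaunay spot-adjacency graph and neighborhood averaging.

#' Build a Delaunay spot-adjacency graph
#'
#' Triangulates the 2D spot positions and takes the union of triangle
#' edges as an undirected, parameter-free neighbor graph (no radius or k
#' to choose). The graph is symmetric, self-loop free, and connected for
#' any valid input.
#'
#' Cocircular point sets (common on regular lattices) make the
#' triangulation non-unique; the triangulation engine resolves such
#' ties deterministically, so no jitter is applied by default — on
#' lattice input a perturbation would turn exactly-collinear boundary
#' chains into spurious sliver edges. A deterministic jitter (relative
#' to the bounding-box diagonal, fixed internal seed) can be requested
#' via `jitter` for pathological inputs; the magnitude used is recorded
#' in the returned object (`jitter_applied`).
#'
#' @param coords numeric matrix (n x 2) of spot positions, or a
#'   `spot_matrix` with coords attached
#' @param barcodes optional spot names; taken from coords rownames or the
#'   `spot_matrix` when available
#' @param jitter relative jitter magnitude (default 0 = none)
#' @return object of class `spatial_graph`: `n_spots`, `edges` (2-column
#'   integer matrix, i < j), `neighbors` (list of sorted neighbor
#'   indices), `barcodes`, `jitter_applied`
#' @export
build_delaunay_graph <- function(coords, barcodes = NULL, jitter = 0) {
  if (inherits(coords, "spot_matrix")) {
    if (is.null(coords$coords)) stop("spot_matrix has no coords", call. = FALSE)
    barcodes <- coords$barcodes
    coords <- coords$coords
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stop("coords must have 2 columns", call. = FALSE)
  n <- nrow(coords)
  if (is.null(barcodes)) barcodes <- rownames(coords)
  if (is.null(barcodes)) barcodes <- as.character(seq_len(n))
  if (n < 3L) stop("Delaunay triangulation needs >= 3 points", call. = FALSE)
  if (anyDuplicated(coords) > 0L) {
    stop("duplicate points in coords", call. = FALSE)
  }
  # collinearity: rank of centered coordinates < 2
  centered <- sweep(coords, 2, colMeans(coords))
  sv <- svd(centered, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-12 * max(sv[1], 1)) {
    stop("all points are collinear; triangulation undefined", call. = FALSE)
  }
  xy <- coords
  eps <- 0
  if (jitter > 0) {
    bbox_diag <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
    eps <- jitter * bbox_diag
    jit <- with_seed(20557L, matrix(stats::runif(2L * n, -eps, eps), ncol = 2L))
    xy <- coords + jit
  }
  dd <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
  e <- cbind(dd$delsgs$ind1, dd$delsgs$ind2)
  swap <- e[, 1] > e[, 2]
  e[swap, ] <- e[swap, c(2, 1)]
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  nbrs <- vector("list", n)
  for (i in seq_len(n)) nbrs[[i]] <- integer(0)
  for (k in seq_len(nrow(e))) {
    i <- e[k, 1]; j <- e[k, 2]
    nbrs[[i]] <- c(nbrs[[i]], j)
    nbrs[[j]] <- c(nbrs[[j]], i)
  }
  nbrs <- lapply(nbrs, sort)
  structure(
    list(
      n_spots = n,
      edges = e,
      neighbors = nbrs,
      barcodes = as.character(barcodes),
      jitter_applied = eps
    ),
    class = "spatial_graph"
  )
}

#' Construct a spatial_graph from an explicit edge list
#'
#' For hand-built graphs in tests and for TSV import; applies the same
#' invariants (symmetry by construction, no self-loops) but does not
#' require the graph to come from a triangulation.
#'
#' @param n_spots number of vertices
#' @param edges 2-column integer matrix of undirected edges
#' @param barcodes optional vertex names
#' @return a `spatial_graph`
#' @export
spatial_graph_from_edges <- function(n_spots, edges, barcodes = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0) {
    if (any(edges < 1L | edges > n_spots)) stop("edge index out of range", call. = FALSE)
    if (any(edges[, 1] == edges[, 2])) stop("self-loops not allowed", call. = FALSE)
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, c(2, 1)]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  if (is.null(barcodes)) barcodes <- as.character(seq_len(n_spots))
  nbrs <- rep(list(integer(0)), n_spots)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    nbrs[[i]] <- c(nbrs[[i]], j)
    nbrs[[j]] <- c(nbrs[[j]], i)
  }
  structure(
    list(n_spots = as.integer(n_spots), edges = edges,
         neighbors = lapply(nbrs, sort),
         barcodes = as.character(barcodes), jitter_applied = 0),
    class = "spatial_graph"
  )
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph: %d spots, %d edges\n", x$n_spots, nrow(x$edges)))
  invisible(x)
}

#' Neighborhood average of a per-spot vector
#'
#' For each spot, the unweighted mean of `x` over its graph neighbors,
#' excluding the spot itself (Delaunay adjacency carries no self-edges;
#' set `include_self = TRUE` to add the focal spot to its own
#' neighborhood).
#'
#' @param g a `spatial_graph`
#' @param x numeric vector of length `g$n_spots`
#' @param include_self include the focal spot in its own average
#' @return numeric vector of length `g$n_spots`
#' @export
neighborhood_average <- function(g, x, include_self = FALSE) {
  stopifnot(inherits(g, "spatial_graph"))
  if (length(x) != g$n_spots) {
    stop("length(x) != n_spots", call. = FALSE)
  }
  deg <- lengths(g$neighbors)
  if (any(deg == 0L)) {
    stop("isolated vertex: neighborhood average undefined", call. = FALSE)
  }
  vapply(seq_len(g$n_spots), function(s) {
    nb <- g$neighbors[[s]]
    if (include_self) nb <- c(nb, s)
    mean(x[nb])
  }, numeric(1))
}

#' Row-normalized adjacency matrix of a spatial graph
#'
#' Sparse operator `W` with `W[s, t] = 1/deg(s)` for each neighbor `t`
#' of `s`; `W %*% x` equals [neighborhood_average()] and is the fast
#' path used by the colocalization permutation machinery.
#'
#' @param g a `spatial_graph`
#' @param include_self include the focal spot in its own neighborhood
#' @return a [Matrix::dgCMatrix-class]
#' @export
adjacency_operator <- function(g, include_self = FALSE) {
  stopifnot(inherits(g, "spatial_graph"))
  i <- c(g$edges[, 1], g$edges[, 2])
  j <- c(g$edges[, 2], g$edges[, 1])
  if (include_self) {
    i <- c(i, seq_len(g$n_spots))
    j <- c(j, seq_len(g$n_spots))
  }
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(g$n_spots, g$n_spots))
  deg <- Matrix::rowSums(a)
  if (any(deg == 0)) stop("isolated vertex", call. = FALSE)
  Matrix::Diagonal(x = 1 / deg) %*% a
}

#' Per-spot degrees and a degree histogram
#'
#' @param g a `spatial_graph`
#' @return list with `degrees` (integer vector) and `histogram` (table
#'   over observed degrees); degrees satisfy the handshake lemma
#' @export
degree_summary <- function(g) {
  stopifnot(inherits(g, "spatial_graph"))
  deg <- lengths(g$neighbors)
  list(degrees = as.integer(deg), histogram = table(deg))
}

#' Is the graph connected?
#' @param g a `spatial_graph`
#' @return logical
#' @export
is_connected <- function(g) {
  n <- g$n_spots
  if (n == 0L) return(TRUE)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- g$neighbors[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  all(seen)
}

#' Export a graph as a two-column edge-list TSV
#'
#' Each row holds the two spot barcodes of one undirected edge, ordered
#' lexicographically within the row; rows sorted for byte-stable output.
#'
#' @param g a `spatial_graph`
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_graph_tsv <- function(g, path) {
  a <- g$barcodes[g$edges[, 1]]
  b <- g$barcodes[g$edges[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(a, b)
  writeLines(paste(a[ord], b[ord], sep = "\t"), path)
  invisible(path)
}

#' Import a graph from an edge-list TSV
#'
#' @param path TSV written by [write_graph_tsv()]
#' @param barcodes the full vertex set (edge lists cannot represent
#'   isolated vertices on their own)
#' @return a `spatial_graph`
#' @export
read_graph_tsv <- function(path, barcodes) {
  lines <- read_lines_auto(path)
  lines <- lines[nzchar(lines)]
  parts <- split_tsv(lines)
  i <- match(parts[, 1], barcodes)
  j <- match(parts[, 2], barcodes)
  if (anyNA(i) || anyNA(j)) stop("edge barcode not in vertex set", call. = FALSE)
  spatial_graph_from_edges(length(barcodes), cbind(i, j), barcodes)
}
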