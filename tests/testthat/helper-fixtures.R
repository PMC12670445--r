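# Shared fixture builders; everything generated in code, nothing stored.

# Write a minimal MatrixMarket coordinate file by hand (independent of
# Matrix::writeMM, so read/write tests have two routes).
write_mtx_by_hand <- function(path, nrow, ncol, entries) {
  # entries: data.frame(i, j, x)
  lines <- c(
    "%%MatrixMarket matrix coordinate integer general",
    paste(nrow, ncol, nrow(entries)),
    if (nrow(entries)) paste(entries$i, entries$j, entries$x)
  )
  writeLines(lines, path)
  path
}

write_sidecars <- function(dir, gene_ids, barcodes, gene_names = gene_ids) {
  writeLines(paste(gene_ids, gene_names, "Gene Expression", sep = "\t"),
             file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

# Tiny deterministic spot matrix: counts chosen by formula, coords on a
# hex grid.
make_test_spots <- function(n_genes = 8, n_spots = 12, seed = 42) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_genes * n_spots, lambda = 5), n_genes, n_spots)
  })
  coords <- make_hex_grid(3, 4, pitch = 10)
  spot_matrix(counts,
              gene_ids = sprintf("g%02d", seq_len(n_genes)),
              barcodes = rownames(coords),
              coords = coords, condition = "test")
}

# Triangle graph: 3 vertices, all edges.
triangle_graph <- function() {
  spatial_graph_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
}

# Brute-force Delaunay edge set: a triangle (i,j,k) is Delaunay iff its
# open circumdisc contains no other point; union of edges of all such
# triangles. Valid for points in general position. O(n^4) -- tests only.
delaunay_edges_bruteforce <- function(coords) {
  n <- nrow(coords)
  x <- coords[, 1]; y <- coords[, 2]
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 1, n - 1)) {
      for (k in seq(j + 1, n)) {
        ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
        d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
        if (abs(d) < 1e-12) next  # collinear triple
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
        r2 <- (ax - ux)^2 + (ay - uy)^2
        others <- setdiff(seq_len(n), c(i, j, k))
        d2 <- (x[others] - ux)^2 + (y[others] - uy)^2
        if (all(d2 > r2 * (1 - 1e-9))) {
          edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
        }
      }
    }
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# Textbook Pearson correlation, written independently of stats::cor.
pearson_by_hand <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}

# From-scratch colocalization score: explicit loop over spots/neighbors.
coloc_score_by_hand <- function(x_a, x_b, g) {
  nb_avg <- numeric(g$n_spots)
  for (s in seq_len(g$n_spots)) {
    acc <- 0; cnt <- 0
    for (t in g$neighbors[[s]]) { acc <- acc + x_b[t]; cnt <- cnt + 1 }
    nb_avg[s] <- acc / cnt
  }
  pearson_by_hand(x_a, nb_avg)
}

edge_key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
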