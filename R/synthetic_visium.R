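## Synthetic Visium-like data with planted ground truth.
##
## The generator emulates the structure the pipeline is built for: a
## hexagonal spot lattice, 1-4 cells per spot mixed across cell types,
## a spatially patchy immune-infiltrated region, negative-binomial
## counts with log-normal library-size variation, and planted gene
## pairs whose spatial colocalization strength is a tunable effect
## size gamma (a shared log-scale Gaussian-smoothed latent field).

#' Simulation configuration
#'
#' Assembles and validates all generator parameters. Defaults describe
#' a small cardiac-like tissue: four cell types (cardiomyocytes,
#' fibroblasts, macrophages, endothelial cells), 10 marker genes per
#' type plus 20 ubiquitously expressed genes, a central infiltrated
#' disc where macrophage and fibroblast Dirichlet weights are raised,
#' 1-4 cells per spot, and a median spot total of ~5000 UMIs.
#'
#' @param n_rows,n_cols lattice dimensions (default 20 x 20)
#' @param pitch center-to-center spot spacing in microns (default 100,
#'   the Visium spacing)
#' @param cell_types type names; must match the signature columns
#' @param signature genes x types matrix of mean expression per cell of
#'   each type; `NULL` builds the default panel
#' @param gene_ids,gene_names identifiers for the signature rows
#' @param alpha_background,alpha_infiltrated Dirichlet concentration per
#'   type in the background and infiltrated domains
#' @param domain_radius_frac infiltrated-disc radius as a fraction of the
#'   smaller lattice extent (default 0.3)
#' @param domain_center disc center (x, y); `NULL` = lattice centroid
#' @param cells_per_spot integer range, cells mixed per spot (default
#'   `c(1, 4)`)
#' @param library_sdlog sd of the log-normal per-spot library factor
#'   (default 0.35)
#' @param target_umi median spot total the base means are scaled to
#'   (default 5000); `NA` disables rescaling so signature means are used
#'   verbatim
#' @param nb_dispersion NB size parameter per gene (recycled; default 2)
#' @param coloc_pairs data.frame with columns gene_a, gene_b, gamma
#'   (>= 0); planted colocalized pairs
#' @param field_smoothness Gaussian kernel bandwidth of the latent
#'   fields, in the same units as `pitch` (default `1.5 * pitch`)
#' @param condition label stored on simulated datasets
#' @param seed default seed used when none is passed to the simulators
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_rows = 20, n_cols = 20, pitch = 100,
                       cell_types = NULL, signature = NULL,
                       gene_ids = NULL, gene_names = NULL,
                       alpha_background = NULL, alpha_infiltrated = NULL,
                       domain_radius_frac = 0.3, domain_center = NULL,
                       cells_per_spot = c(1L, 4L),
                       library_sdlog = 0.35, target_umi = 5000,
                       nb_dispersion = 2, coloc_pairs = NULL,
                       field_smoothness = 1.5 * pitch,
                       condition = "synthetic", seed = 1L) {
  if (is.null(signature)) {
    def <- default_signature()
    signature <- def$signature
    cell_types <- colnames(signature)
    gene_ids <- def$gene_ids
    gene_names <- def$gene_names
  } else {
    signature <- as.matrix(signature)
    if (is.null(cell_types)) cell_types <- colnames(signature)
    if (is.null(gene_ids)) gene_ids <- rownames(signature)
    if (is.null(gene_names)) gene_names <- gene_ids
  }
  if (is.null(alpha_background)) {
    alpha_background <- c(Cardiomyocyte = 8, Fibroblast = 4,
                          Macrophage = 0.5, Endothelial = 1.5)[cell_types]
    alpha_background[is.na(alpha_background)] <- 1
    names(alpha_background) <- cell_types
  }
  if (is.null(alpha_infiltrated)) {
    alpha_infiltrated <- alpha_background
    if ("Macrophage" %in% cell_types) alpha_infiltrated["Macrophage"] <- 6
    if ("Fibroblast" %in% cell_types) alpha_infiltrated["Fibroblast"] <- 6
  }
  if (is.null(coloc_pairs)) {
    coloc_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                              gamma = numeric(0), stringsAsFactors = FALSE)
  }
  cfg <- structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pitch = pitch, cell_types = cell_types, signature = signature,
         gene_ids = as.character(gene_ids),
         gene_names = as.character(gene_names),
         alpha_background = alpha_background,
         alpha_infiltrated = alpha_infiltrated,
         domain_radius_frac = domain_radius_frac,
         domain_center = domain_center,
         cells_per_spot = as.integer(cells_per_spot),
         library_sdlog = library_sdlog, target_umi = target_umi,
         nb_dispersion = nb_dispersion, coloc_pairs = coloc_pairs,
         field_smoothness = field_smoothness,
         condition = condition, seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- character(0)
  if (cfg$n_rows < 1 || cfg$n_cols < 1) probs <- c(probs, "lattice dims must be >= 1")
  if (cfg$pitch <= 0) probs <- c(probs, "pitch must be > 0")
  if (nrow(cfg$signature) != length(cfg$gene_ids)) {
    probs <- c(probs, "signature rows != gene_ids")
  }
  if (ncol(cfg$signature) != length(cfg$cell_types)) {
    probs <- c(probs, "signature cols != cell_types")
  }
  if (any(cfg$signature < 0)) probs <- c(probs, "signature means must be >= 0")
  if (any(cfg$alpha_background <= 0) || any(cfg$alpha_infiltrated <= 0)) {
    probs <- c(probs, "dirichlet alpha must be > 0")
  }
  if (length(cfg$cells_per_spot) != 2L || cfg$cells_per_spot[1] < 1L ||
      cfg$cells_per_spot[2] < cfg$cells_per_spot[1]) {
    probs <- c(probs, "cells_per_spot must be an increasing range with lower bound >= 1")
  }
  if (any(cfg$nb_dispersion <= 0)) probs <- c(probs, "nb_dispersion must be > 0")
  if (nrow(cfg$coloc_pairs)) {
    if (any(cfg$coloc_pairs$gamma < 0)) probs <- c(probs, "gamma must be >= 0")
    unknown <- setdiff(c(cfg$coloc_pairs$gene_a, cfg$coloc_pairs$gene_b),
                       cfg$gene_ids)
    if (length(unknown)) {
      probs <- c(probs, paste("coloc pair gene(s) not in panel:",
                              paste(unknown, collapse = ", ")))
    }
  }
  if (cfg$field_smoothness <= 0) probs <- c(probs, "field_smoothness must be > 0")
  if (length(probs)) stop_aggregate(probs, "invalid sim_config")
  invisible(cfg)
}

#' Default gene panel: type markers, background genes, ubiquitous genes
#'
#' 10 marker genes per type (mean 20 per cell of the own type, 0.5
#' elsewhere), 360 background genes (mean 1 in every type, giving the
#' panel enough breadth that the `>300 detected genes` QC threshold is
#' meaningful on simulated spots), and 20 ubiquitous genes (UBQ*, mean
#' 5 in every type) — the natural hosts for planted colocalization
#' pairs, since their expression carries no cell-type structure.
#'
#' @return list with `signature`, `gene_ids`, `gene_names`
#' @export
default_signature <- function() {
  types <- c("Cardiomyocyte", "Fibroblast", "Macrophage", "Endothelial")
  short <- c("CM", "FB", "MAC", "EC")
  n_mark <- 10L
  n_bg <- 360L
  n_ubq <- 20L
  n_genes <- n_mark * length(types) + n_bg + n_ubq
  sig <- matrix(0.5, nrow = n_genes, ncol = length(types),
                dimnames = list(NULL, types))
  gene_names <- character(n_genes)
  row <- 1L
  for (t in seq_along(types)) {
    for (k in seq_len(n_mark)) {
      sig[row, t] <- 20
      gene_names[row] <- sprintf("%s-mk%02d", short[t], k)
      row <- row + 1L
    }
  }
  for (k in seq_len(n_bg)) {
    sig[row, ] <- 1
    gene_names[row] <- sprintf("BG%03d", k)
    row <- row + 1L
  }
  for (k in seq_len(n_ubq)) {
    sig[row, ] <- 5
    gene_names[row] <- sprintf("UBQ%02d", k)
    row <- row + 1L
  }
  gene_ids <- sprintf("gene-%03d", seq_len(n_genes))
  rownames(sig) <- gene_ids
  list(signature = sig, gene_ids = gene_ids, gene_names = gene_names)
}

#' Gene ids of the ubiquitous (UBQ) panel members
#'
#' Convenience accessor for planting colocalization pairs.
#' @param cfg a [sim_config()] using the default panel
#' @return character vector of gene ids
#' @export
ubiquitous_genes <- function(cfg = sim_config()) {
  cfg$gene_ids[grepl("^UBQ", cfg$gene_names)]
}

#' Hexagonal (triangular) spot lattice
#'
#' `n_rows * n_cols` points with odd rows offset by `pitch / 2` and row
#' spacing `pitch * sqrt(3) / 2`, so every interior point has exactly
#' six nearest neighbors at distance `pitch`.
#'
#' @param n_rows,n_cols lattice dimensions (>= 1)
#' @param pitch center-to-center spacing (> 0)
#' @return numeric matrix (n x 2) of x,y positions with attributes
#'   `array_row` and `array_col` (0-based lattice indices) and rownames
#'   `spot-0001` ...
#' @export
make_hex_grid <- function(n_rows, n_cols, pitch = 100) {
  if (n_rows < 1 || n_cols < 1) stop("lattice dims must be >= 1", call. = FALSE)
  if (pitch <= 0) stop("pitch must be > 0", call. = FALSE)
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  x <- (col + 0.5 * (row %% 2L)) * pitch
  y <- row * pitch * sqrt(3) / 2
  coords <- cbind(x = x, y = y)
  rownames(coords) <- sprintf("spot-%04d", seq_len(nrow(coords)))
  attr(coords, "array_row") <- row
  attr(coords, "array_col") <- col
  coords
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # pathological underflow guard
  g / sum(g)
}

#' Simulate per-spot cell-type proportions
#'
#' Each spot draws its cell count uniformly from the configured range,
#' then a Dirichlet composition for its domain (background vs the
#' infiltrated disc, where immune weights are raised), discretized by a
#' multinomial draw over that many cells; proportions are the resulting
#' cell fractions, so every row sums to 1 exactly.
#'
#' @param coords spot positions from [make_hex_grid()]
#' @param cfg a [sim_config()]
#' @param seed RNG seed (default `cfg$seed`)
#' @return list with `proportions` (a [proportion_table()]) and `truth`
#'   (domain labels, per-spot cell counts, the config and seed)
#' @export
simulate_proportions <- function(coords, cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  n <- nrow(coords)
  center <- cfg$domain_center
  if (is.null(center)) center <- colMeans(coords[, 1:2, drop = FALSE])
  extent <- min(diff(range(coords[, 1])), diff(range(coords[, 2])))
  if (!is.finite(extent) || extent == 0) extent <- cfg$pitch
  radius <- cfg$domain_radius_frac * extent
  d <- sqrt((coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2)
  domain <- ifelse(d <= radius, "infiltrated", "background")
  k <- length(cfg$cell_types)
  prop <- matrix(0, n, k)
  n_cells <- integer(n)
  with_seed(seed, {
    for (s in seq_len(n)) {
      alpha <- if (domain[s] == "infiltrated") cfg$alpha_infiltrated else cfg$alpha_background
      rng <- seq(cfg$cells_per_spot[1], cfg$cells_per_spot[2])
      nc <- if (length(rng) == 1L) rng else sample(rng, 1L)
      p <- rdirichlet1(alpha)
      cells <- as.integer(stats::rmultinom(1, nc, p))
      n_cells[s] <- nc
      prop[s, ] <- cells / nc
    }
  })
  pt <- proportion_table(rownames(coords), cfg$cell_types, prop)
  truth <- list(domain = stats::setNames(domain, rownames(coords)),
                n_cells = stats::setNames(n_cells, rownames(coords)),
                seed = as.integer(seed), config = cfg)
  list(proportions = pt, truth = truth)
}

gaussian_field <- function(coords, bandwidth) {
  # Gaussian kernel-smoothed white noise, standardized to mean 0 sd 1
  n <- nrow(coords)
  z <- stats::rnorm(n)
  d2 <- as.matrix(stats::dist(coords[, 1:2, drop = FALSE]))^2
  k <- exp(-d2 / (2 * bandwidth^2))
  f <- as.numeric(k %*% z) / rowSums(k)
  s <- stats::sd(f)
  if (s == 0 || !is.finite(s)) return(rep(0, n))
  (f - mean(f)) / s
}

#' Simulate NB counts over simulated proportions
#'
#' Per-spot, per-gene means are `library factor x sum_type
#' proportion x signature`, globally rescaled so the mean spot total
#' equals `target_umi` (unless `NA`). For every planted pair with
#' `gamma > 0`, one shared latent field `f` (Gaussian-smoothed,
#' standardized white noise) multiplies both genes' means by
#' `exp(gamma * f)`; `gamma = 0` pairs receive no field, so their genes
#' are independent NB noise by construction. Counts are drawn from a
#' negative binomial with the configured per-gene dispersion.
#'
#' @param coords spot positions
#' @param props a [proportion_table()] over the same spots
#' @param cfg a [sim_config()]
#' @param seed RNG seed (default `cfg$seed + 1` so proportions and
#'   counts drawn with the same config seed are independent streams)
#' @return list with `spots` (a [spot_matrix()] with coords and
#'   condition set) and `truth` (planted pairs, latent fields, library
#'   factors, seed)
#' @export
simulate_counts <- function(coords, props, cfg, seed = cfg$seed + 1L) {
  validate_sim_config(cfg)
  stopifnot(inherits(props, "proportion_table"))
  n <- nrow(coords)
  if (length(props$barcodes) != n) stop("props/coords spot mismatch", call. = FALSE)
  mu <- cfg$signature %*% t(props$proportions)  # genes x spots
  if (!is.null(cfg$target_umi) && is.finite(cfg$target_umi)) {
    mu <- mu * cfg$target_umi / mean(colSums(mu))
  }
  pairs <- cfg$coloc_pairs
  fields <- list()
  out <- with_seed(seed, {
    lib <- exp(stats::rnorm(n, 0, cfg$library_sdlog))
    if (nrow(pairs)) {
      for (q in seq_len(nrow(pairs))) {
        if (pairs$gamma[q] > 0) {
          f <- gaussian_field(coords, cfg$field_smoothness)
          fields[[paste(pairs$gene_a[q], pairs$gene_b[q], sep = "~")]] <- f
          ia <- match(pairs$gene_a[q], cfg$gene_ids)
          ib <- match(pairs$gene_b[q], cfg$gene_ids)
          mu[ia, ] <- mu[ia, ] * exp(pairs$gamma[q] * f)
          mu[ib, ] <- mu[ib, ] * exp(pairs$gamma[q] * f)
        }
      }
    }
    mu <- sweep(mu, 2, lib, "*")
    size <- rep_len(cfg$nb_dispersion, nrow(mu))
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.numeric(mu), size = rep(size, times = ncol(mu))),
      nrow = nrow(mu), ncol = ncol(mu)
    )
    list(counts = counts, lib = lib)
  })
  spots <- spot_matrix(out$counts, gene_ids = cfg$gene_ids,
                       gene_names = cfg$gene_names,
                       barcodes = props$barcodes,
                       coords = coords[, 1:2, drop = FALSE],
                       condition = cfg$condition)
  truth <- list(coloc_pairs = pairs, fields = fields,
                library_factors = stats::setNames(out$lib, props$barcodes),
                seed = as.integer(seed))
  list(spots = spots, truth = truth)
}

#' Simulate a complete Visium-like dataset
#'
#' Convenience wrapper: hex grid, proportions, counts, merged truth.
#'
#' @param cfg a [sim_config()]
#' @param seed RNG seed (default `cfg$seed`)
#' @return list with `spots`, `proportions`, `coords`, `truth`
#' @export
simulate_visium <- function(cfg = sim_config(), seed = cfg$seed) {
  coords <- make_hex_grid(cfg$n_rows, cfg$n_cols, cfg$pitch)
  pr <- simulate_proportions(coords, cfg, seed = seed)
  ct <- simulate_counts(coords, pr$proportions, cfg,
                        seed = derive_seed(seed, "counts"))
  truth <- c(pr$truth[c("domain", "n_cells")], ct$truth,
             list(sim_seed = as.integer(seed)))
  list(spots = ct$spots, proportions = pr$proportions, coords = coords,
       truth = truth)
}

#' Write a simulated dataset as an on-disk fixture
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv`,
#' `tissue_positions.csv` (headered SpaceRanger dialect),
#' `proportions.csv` and `truth.json`, all plain text and byte-stable
#' under a fixed seed; round-trippable through [read_counts()],
#' [read_positions()] and [read_proportions()].
#'
#' @param m a `spot_matrix` with coords
#' @param props a `proportion_table`
#' @param truth truth list from the simulators (serialized to JSON;
#'   the embedded config is reduced to its scalar fields)
#' @param dir output directory
#' @return invisibly, the paths written
#' @export
write_fixture <- function(m, props, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_counts(m, dir)
  pos <- file.path(dir, "tissue_positions.csv")
  arow <- attr(m$coords, "array_row")
  acol <- attr(m$coords, "array_col")
  if (is.null(arow)) { arow <- rep(0L, ncol(m$counts)); acol <- seq_len(ncol(m$counts)) - 1L }
  writeLines(c(
    "barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres",
    paste(m$barcodes, 1L, arow, acol,
          fmt_num(m$coords[, "y"]), fmt_num(m$coords[, "x"]), sep = ",")
  ), pos)
  prop_path <- file.path(dir, "proportions.csv")
  writeLines(c(
    paste(c("barcode", props$cell_types), collapse = ","),
    vapply(seq_along(props$barcodes), function(i) {
      paste(c(props$barcodes[i], fmt_num(props$proportions[i, ])), collapse = ",")
    }, character(1))
  ), prop_path)
  truth_path <- file.path(dir, "truth.json")
  ser <- truth
  if (!is.null(ser$config)) {
    keep <- !vapply(ser$config, is.matrix, logical(1))
    ser$config <- unclass(ser$config)[keep]
  }
  if (!is.null(ser$coloc_pairs)) {
    ser$coloc_pairs <- as.list(ser$coloc_pairs)
  }
  jsonlite::write_json(ser, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, positions = pos, proportions = prop_path,
              truth = truth_path))
}

#' Reload a truth JSON written by write_fixture
#' @param path path to `truth.json`
#' @return list
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
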