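# spotcoloc

Spot-level colocalization and composition analysis for 10x Visium
spatial transcriptomics.

## The problem

Visium captures mRNA on a hexagonal lattice of ~55 µm barcoded spots,
each covering a small mixture of 1–4 cells. Two questions recur in
studies of inflamed or remodelling tissue (e.g. myocarditis models,
where infiltrating myeloid cells and activated fibroblasts are thought
to cooperate):

1. **Spatial colocalization** — is gene *A* expressed at spots whose
   *neighborhood* expresses gene *B*? For spots `s` with expression
   vectors `x_A`, `x_B` and a parameter-free Delaunay adjacency
   (neighbors `N(s)`), the statistic is

   ```
   score(A, B) = cor( x_A[s] ,  mean_{t ∈ N(s)} x_B[t] )        (Pearson)
   ```

   with a one-sided empirical p-value from `n_perm` random shuffles
   π of the spots:

   ```
   p = (1 + #{ k : score(A, π_k(B)) ≥ score(A, B) }) / (1 + n_perm)
   ```

   (defaults `n_perm = 100`, significance mask at `α = 0.05`). The
   statistic is deliberately asymmetric: gene A is the anchor, gene B
   is neighborhood-averaged.

2. **Spot composition** — given per-spot cell-type proportions from a
   deconvolution tool, which type *dominates* each spot (argmax), which
   spots are *enriched* for a type (proportion ≥ threshold, default
   0.25), and how do subset frequencies shift between conditions?
   Marker genes for any spot grouping come from a two-sided Wilcoxon
   rank-sum test with a Seurat-style fold change
   `log2((mean₁+1)/(mean₂+1))` filtered at `|log2FC| > 0.25` and BH
   adjustment.

Everything is driven by a synthetic Visium generator with planted
ground truth (hex lattice, Dirichlet cell mixtures over 1–4 cells, a
patchy "infiltrated" domain, NB counts with log-normal library sizes,
and colocalized gene pairs with tunable effect size γ), so every stage
has a parameter-recovery test without any external dataset.

## Worked example

```r
library(spotcoloc)

# simulate a 20x20 Visium-like dataset with one planted pair (gamma = 1)
cfg <- sim_config(coloc_pairs = data.frame(gene_a = "gene-401",
                                           gene_b = "gene-402", gamma = 1))
sim <- simulate_visium(cfg, seed = 42)

m <- qc_filter(sim$spots)              # spots with >500 UMIs and >300 genes
m <- normalize_spots(m)                # median-library scaling + log1p
g <- build_delaunay_graph(m)           # parameter-free spot adjacency
degree_summary(g)$histogram

permutation_test(gene_vector(m, "gene-401"), gene_vector(m, "gene-402"),
                 g, n_perm = 100, seed = 1,
                 gene_a = "gene-401", gene_b = "gene-402")

dominant_type(sim$proportions) |> subset_frequencies(rep("day0", 400))
```

prints

```
spatial_graph: 400 spots, 1139 edges
deg
  3   4   5   6
  4  38  34 324
coloc_result: gene-401 ~ navg(gene-402)  score = 0.6836  p = 0.009901 (100 perms)
composition_summary over conditions: day0
               day0
Cardiomyocyte 0.685
Endothelial   0.082
Fibroblast    0.192
Macrophage    0.040
```

All 324 interior lattice spots have Delaunay degree 6, as hexagonal
geometry demands. The planted pair is detected at the smallest
attainable p-value, 1/101 ≈ 0.0099 (100 shuffles can resolve no
lower); an unplanted pair in the same dataset scores ≈ 0.02 with
p ≈ 0.37. The composition table shows the background tissue dominated
by cardiomyocytes with a fibroblast/macrophage component concentrated
in the infiltrated disc.

Real SpaceRanger output is read with `read_counts()` (MatrixMarket +
features/barcodes TSV, gzip auto-detected), `read_positions()` (both
tissue-positions dialects) and `read_proportions()` (deconvolution
CSV), then flows through the same functions. A multi-condition run —
one slide per condition, graphs built independently, never pooling
spots across slides — is orchestrated by `run_pipeline()` from a
JSON/YAML config, or from the shell:

```sh
spotcoloc run --config cfg.json
spotcoloc coloc --matrix matrix.mtx --features features.tsv \
  --barcodes barcodes.tsv --positions tissue_positions.csv \
  --row-genes myeloid.txt --col-genes fibro.txt --n-perm 100 --seed 1 \
  --out out/
```

(the executable is installed at
`system.file("exec", "spotcoloc", package = "spotcoloc")`).

## Scope notes

Regularized-NB normalization (SCTransform), deconvolution itself
(CARD), clustering/UMAP and ligand–receptor inference are *inputs or
out of scope*, not reimplemented; `normalize_spots()` accepts an
externally computed matrix via `external=`. See
`vignettes/spotcoloc-methods.Rmd` for the model, parameter choices and
known limitations.
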