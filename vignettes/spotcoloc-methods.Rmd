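---
title: "spotcoloc: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotcoloc: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and what a green test suite does and does
not establish. No number stated here is asserted that the tests or
`scripts/acceptance.R` do not themselves compute.

## 1. The model

### Spot data and quality control

The unit of observation is a Visium spot: a barcoded ~55 µm capture
area on a hexagonal lattice holding a small cell mixture (typically
1–4 cells in dense tissue). Counts are UMI-deduplicated and
non-negative integers. QC keeps spots with **strictly more than** 500
total UMIs and **strictly more than** 300 detected genes; the strict
inequality is deliberate and boundary spots (exactly 500 / exactly
300) are removed. Both thresholds are arguments of `qc_filter()`.

### Normalization

Downstream statistics run on `log1p` counts scaled so every spot's
total equals the median spot total. This is a deliberate
simplification: the regularized negative-binomial normalization used
by popular pipelines (SCTransform) is an external published method and
is not reimplemented here. Median-ratio scaling preserves zeros, is
monotone within a spot, and removes the dominant technical axis
(library size), which is what the rank-based and correlation-based
statistics downstream need. Users who want model-based residuals can
attach any externally computed matrix with
`normalize_spots(m, external = X)`; every downstream function then
uses it unchanged. Which expression source feeds the colocalization
statistic is an open choice (the original description does not pin it
down); the package default is the normalized matrix, with
`source = "raw"` exposed.

### The spatial graph

`build_delaunay_graph()` triangulates the 2-D spot positions and takes
the union of triangle edges: an undirected, self-loop-free, connected
neighbor graph with no radius or k parameter to tune. Pixel
coordinates are the default; when only array indices are available
they are mapped to a Cartesian hex lattice as `x = array_col * 0.5`,
`y = array_row * sqrt(3)/2`, because Visium interleaves columns across
rows.

**Degeneracy and determinism.** Regular lattices contain cocircular
and collinear point sets, where the Delaunay triangulation is not
unique. An earlier design applied a seed-fixed micro-jitter
(1e-9 × bounding-box diagonal) before triangulating; implementation
showed this to be wrong on two counts. First, a perturbation that
small sits below the triangulation engine's internal tolerance and
destabilizes it. Second — and more fundamentally — *any* jitter turns
the exactly-collinear chains on a lattice boundary into slightly
convex/concave arcs, which the triangulation must fill with fans of
sliver triangles: on a 20×20 lattice this adds roughly 4% spurious
long boundary edges (verified against an independent implementation,
which produces the identical sliver set on jittered input — the
slivers are a property of jittering, not an engine artifact). The
engine used (`deldir`) resolves degenerate ties deterministically on
its own, and its edge set on the raw lattice matches both an
independent implementation and the brute-force empty-circumcircle
definition. The default is therefore **no jitter**; `jitter > 0` is
retained as an escape hatch for pathological inputs and its magnitude
is recorded on the returned object. Long boundary edges are *not*
trimmed (configurable nowhere, noted as a limitation below).

### The colocalization statistic

For gene A (anchor) and gene B, with `N(s)` the Delaunay neighbors of
spot `s` (the focal spot **excluded** — adjacency has no self-edges;
`include_self` exposed, default off):

\[ \mathrm{score}(A,B) \;=\; \mathrm{cor}\Big( x_A(s),\;
   \tfrac{1}{|N(s)|}\textstyle\sum_{t\in N(s)} x_B(t) \Big) \]

Pearson correlation by default — the statistic's description says only
"correlating", and Pearson on log-normalized values is the common
reading; Spearman is exposed as `method = "spearman"`. The statistic
is **asymmetric**: in matrix form the column gene is the anchor (e.g.
fibroblast markers) and the row gene is neighborhood-averaged (e.g.
myeloid markers).

Significance: `n_perm` (default 100) uniform random permutations of
`x_B` across spots, and a **one-sided** add-one empirical p-value
\( p = (1 + \#\{r_k \ge r_{obs}\}) / (1 + n_\text{perm}) \), so
\(p \ge 1/(n_\text{perm}+1) \approx 0.0099\) and p is never 0.
One-sidedness and the pseudocount are documented choices (the original
description says only "empirical p-values"): colocalization is a
positive association, and 100 shuffles cannot resolve p below ~0.01
while the headline filter sits at 0.05. No multiple-testing correction
is applied to the significance mask (matching the raw-p 0.05
prefilter convention); BH-adjusted values are always reported in the
long-format output table.

Per-pair permutation streams are derived by hashing
`(master seed, gene_a, gene_b)` (a 31-bit polynomial rolling hash), so
results are order-independent: subsetting or reordering gene lists
never changes a surviving pair's p-value.

### Composition summaries

* *Dominant type*: strict argmax of the deconvolved proportion row;
  ties broken by lexicographically smallest type name ("dominant" has
  no published definition; argmax is the minimal one).
* *Enriched spots*: proportion ≥ threshold, default 0.25, exposed as
  config — the published enriched-spot count does not state its
  cutoff, so no default can reproduce it and none is claimed to.
* *Frequencies*: per-condition label counts and fractions; conditions
  with zero spots are rejected.
* *Markers*: two-sided Wilcoxon rank-sum per gene — exact by complete
  enumeration of rank-sum assignments when both groups have ≤ 10
  spots (ties handled by midranks; the null distribution is symmetric,
  so the symmetric-tail p equals the usual doubled-tail convention),
  otherwise the normal approximation with the standard tie correction
  and **no continuity correction**. Fold change is Seurat-style on
  de-logged normalized means, `log2((mean₁+1)/(mean₂+1))`; the filter
  keeps `|log2FC| > 0.25` in both directions by default (the published
  rule states the magnitude but not a direction convention), with
  `direction = "up"` available.

### Proportion-table tolerance

Rows must sum to 1. Two tolerances appear in the contract (renormalize
within 1e-6; reject beyond 1e-3); the implemented rule is the
permissive closure consistent with both: rows with |sum − 1| ≤ 1e-3
are renormalized to sum exactly 1, anything worse is an error.

## 2. The synthetic generator: the stated world

`sim_config()` defaults describe one fixed world, chosen once:

| parameter | default | why |
|---|---|---|
| lattice | 20 × 20, pitch 100 µm | Visium center-to-center spacing; 400 spots is the smallest grid with a robust interior |
| cell types | CM, FB, MAC, EC | minimal cardiac tissue palette |
| cells per spot | uniform 1–4 | matches the observed occupancy of dense tissue spots |
| Dirichlet α (background) | CM 8, FB 4, MAC 0.5, EC 1.5 | healthy myocardium: cardiomyocyte-dominated, sparse immune cells |
| Dirichlet α (infiltrated disc) | MAC 6, FB 6 (rest as background) | inflammation = coupled myeloid + fibroblast expansion |
| infiltrated domain | disc, radius 0.3 × min extent | a single patchy infiltrate |
| gene panel | 10 markers/type (mean 20 vs 0.5) + 360 background (mean 1) + 20 ubiquitous (mean 5) | 420 genes make the ">300 detected genes" QC threshold meaningful; UBQ genes host planted pairs because they carry no cell-type structure |
| library size | log-normal, sdlog 0.35, median total ≈ 5000 UMIs | realistic Visium depth; keeps the QC filter non-trivial |
| NB dispersion | size = 2 per gene | moderate overdispersion typical of spot data |
| field smoothness | 1.5 × pitch | patches a few spots wide — the scale a Delaunay neighborhood can see |

Proportions are Dirichlet draws **discretized over the spot's integer
cell count** (multinomial), so rows are exact cell fractions summing
to 1 — mirroring that a spot contains whole cells, not a continuous
mixture.

Planted colocalization: each pair with γ > 0 shares one latent field
`f` (Gaussian-kernel-smoothed white noise, standardized), and both
genes' NB means are multiplied by `exp(γ f)`. This is the simplest
mechanism that yields a spatially structured, tunably strong
association the neighborhood statistic should detect; it does *not*
model literal co-occurring cells. γ = 0 pairs receive no field, so
they are independent NB noise by construction.

**What the generator does not emulate** — and hence what a green test
does not establish: H&E images, transcript bleed/diffusion between
spots, doublet artifacts, batch effects across slides, cell-type
covariance beyond the Dirichlet, and genuine spatial autocorrelation
in *null* genes. That last point matters: the permutation null
destroys all spatial structure, so a gene pair that is merely
*smooth* (but not co-localized) can reject more often than α. The
calibration results here certify behavior under exchangeable nulls
only; spatially-restricted permutations (rotations, toroidal shifts)
are a known, deliberate non-goal.

## 3. Numerical choices

* Empirical p uses the add-one pseudocount; minimum attainable p is
  `1/(n_perm+1)`.
* Permuted neighborhood averages are computed by one sparse
  row-normalized adjacency multiplication per pair (batched across
  permutations); tests pin this fast path to the explicit
  loop-over-neighbors definition at 1e-12.
* A permuted `x_B` column that happens to be constant after averaging
  (possible only on tiny graphs) yields an `NA` correlation, counted
  as non-exceeding — conservative for p.
* Exact Wilcoxon enumerates `choose(n1+n2, n1)` assignments; the
  default `exact_limit = 10` caps this at 184,756.
* Text outputs format numbers with 15 significant digits via a single
  formatter, making pipeline re-runs byte-identical; the run report
  omits wall time from the serialized JSON for the same reason.
* All RNG flows through seeds derived from `(master seed, strings)`
  with 31-bit arithmetic, so derived seeds stay valid R integers.

## 4. Known limitations

* The shuffle null ignores spatial autocorrelation (above).
* No trimming of long boundary Delaunay edges; on convex tissue
  sections with bays, boundary spots can acquire distant neighbors.
* Median-scaling normalization does not stabilize variance across the
  mean range the way regularized-NB residuals do; strongly
  depth-confounded signals should use an external matrix.
* The enriched-spot threshold (0.25) is a convention, not an estimate;
  published enriched/dominant spot totals depend on an unstated cutoff
  and unstated clustering parameters and are consumed here only as an
  arithmetic-consistency input (`reported_spot_counts()`).
* Conditions are analyzed as independent single slides (n = 1 per
  condition); all cross-condition comparisons are descriptive
  spot-level summaries, not replicated statistics.
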