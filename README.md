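# scMCGF

Multi-view graph fusion clustering for single-cell RNA-seq data.

## What it does and for whom

Cell clustering is the first analysis step for most scRNA-seq studies, and
it is hard: the data are high-dimensional, sparse (dropout) and noisy, so
similarity graphs built from a single representation of the expression
matrix are often poor. scMCGF is for analysts who have a genes × cells
expression matrix (and optionally a pathway gene-set collection in GMT
format), know how many cell populations they expect, and want a clustering
that exploits several complementary representations of the same cells at
once.

The package builds four *views* of the data:

1. **expression** — the pre-processed matrix (conditional log2 transform,
   removal of genes zero in more than 95% of cells, median-scaled
   size-factor normalization, top 2000 highly variable genes);
2. **pathway** — AUCell-style per-cell gene-set activity scores (area
   under the gene-set recovery curve within the top 5% of each cell's
   expression ranking);
3. **pca** — principal-component coordinates of the pre-processed matrix;
4. **dm** — diffusion-map coordinates (Gaussian kernel, Markov
   normalization), capturing non-linear structure.

The PCA/diffusion dimensionality is chosen by a Levina–Bickel
maximum-likelihood intrinsic-dimension estimate.

## The model

For views X^v (v = 1..m) over n cells, scMCGF learns per-view similarity
graphs S^v, view weights w_v, and a unified graph U by alternating
minimization of

    min_{S^v, U, F}  Σ_v Σ_ij ||x_i^v − x_j^v||² s_ij^v
                   + γ Σ_v Σ_i ||s_i^v||²
                   + Σ_v w_v ||U − S^v||_F²
                   + 2λ Tr(Fᵀ L_U F)

subject to every row of every S^v and of U lying on the probability
simplex (nonnegative, summing to 1, zero self-similarity), and FᵀF = I.
Here L_U = D_U − (Uᵀ + U)/2 is the Laplacian of U and F ∈ ℝ^{n×c} its
spectral embedding. Each row subproblem has a closed form: the S^v rows
are k-sparse adaptive-neighbor weights, the weights are
w_v = 1 / (2‖U − S^v‖_F), and the U rows are Euclidean projections onto
the simplex computed by Newton root-finding. The trace term enforces a
rank constraint rank(L_U) = n − c: λ is adapted (doubled/halved) until
the Laplacian has exactly c zero eigenvalues, at which point the
connected components of U **are** the c clusters — no k-means or Louvain
step is needed (a seeded k-means on F is used only as a flagged fallback
if the rank constraint is never met).

The neighbor count defaults to k = 5 for data sets under 3000 cells and
k = 15 otherwise.

## Worked example

```r
library(scMCGF)

sim <- generateSynthetic(nCells = 300, nGenes = 1000, nClusters = 3,
                         effect = 8, dropout = 0.3, seed = 1)
fit <- scMCGF(sim$expression, c = 3, geneSets = sim$geneSets)
fit
#> SCMCGFFit: 300 cells, 4 view(s), 3 clusters requested
#>   iterations: 1 | converged: TRUE | fallback k-means: FALSE
#>   lambda: 491 | view weights: 0.0850 0.0986 0.0991 0.1110
#>   cluster sizes: 100 100 100

m <- evaluateClustering(clusterLabels(fit), sim$labels)
sprintf("CA = %.3f  NMI = %.3f  ARI = %.3f", m$CA, m$NMI, m$ARI)
#> "CA = 1.000  NMI = 1.000  ARI = 1.000"
```

`converged: TRUE` means the unified graph reached exactly 3 connected
components, so the reported clusters are graph components, not a
post-hoc k-means; the view weights show how strongly each view agreed
with the fused graph (here the diffusion-map view was closest). CA is
clustering accuracy under optimal cluster matching, NMI normalized
mutual information, ARI the adjusted Rand index — all 1.0 because the
three simulated populations (8-fold marker effect, 30% dropout) are
recovered exactly.

## Command line

A thin CLI wraps the same functions (after installation, see
`system.file("exec", "scmcgf", package = "scMCGF")`):

```sh
scmcgf synth --cells 300 --genes 1000 --clusters 3 --out data/
scmcgf run --input data/expression.csv --gmt data/genesets.gmt \
           --clusters 3 --truth data/truth.csv --out out/
scmcgf eval --pred out/labels.csv --truth data/truth.csv
```

`run` writes `labels.csv`, a per-iteration `run_log.tsv` (objective,
λ, zero-eigenvalue count, component count, view weights) and a
`summary.json`; `--views expression,pca,dm` style subsets reproduce the
ablation variants.

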