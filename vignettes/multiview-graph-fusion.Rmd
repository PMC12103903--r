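---
title: "Multi-view graph fusion clustering: model, parameters and design notes"
author: "scMCGF authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view graph fusion clustering: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scMCGF)
```

# The problem and the model

Clustering scRNA-seq data from a single representation of the expression
matrix is fragile: raw expression distances are dominated by technical
noise and dropout, dimension-reduced coordinates lose information, and
pathway-level signal is invisible to both. scMCGF clusters cells from
several representations ("views") at once, learning a similarity graph
per view and fusing them into one unified graph whose connected
components are the clusters.

For views $X^v \in \mathbb{R}^{d_v \times n}$, $v = 1..m$, over the same
$n$ cells, the coupled objective is

$$
\min_{\{S^v\}, U, F}
\sum_{v=1}^m \sum_{i,j=1}^n \lVert x_i^v - x_j^v \rVert_2^2\, s_{ij}^v
+ \gamma \sum_{v=1}^m \sum_i \lVert s_i^v \rVert_2^2
+ \sum_{v=1}^m w_v \lVert U - S^v \rVert_F^2
+ 2\lambda\, \mathrm{Tr}(F^\top L_U F)
$$

subject to $s_{ii}^v = 0$, $s_{ij}^v \ge 0$, $\mathbf{1}^\top s_i^v = 1$,
$u_{ij} \ge 0$, $\mathbf{1}^\top u_i = 1$, $F^\top F = I$, with
$L_U = D_U - (U^\top + U)/2$ the Laplacian of the unified graph and
$F \in \mathbb{R}^{n \times c}$ its spectral embedding.

The four terms are: (i) adaptive-neighbor graph construction — each cell
distributes a unit similarity budget over its neighbors, preferring close
ones; (ii) an $\ell_2$ regularizer that prevents the trivial
all-mass-on-one-neighbor solution, with $\gamma$ realized per row at the
closed-form value that makes each row exactly $k$-sparse; (iii) the
fusion term pulling the unified graph towards every view graph with
automatically learned weights $w_v = 1/(2\lVert U - S^v\rVert_F)$, so
views that agree with the consensus weigh more; (iv) the
constrained-Laplacian-rank (CLR) term. Since the multiplicity of the
zero eigenvalue of $L_U$ equals the number of connected components of
$U$, forcing the $c$ smallest eigenvalues to zero — via the Ky Fan
identity $\sum_{i=1}^c \lambda_i = \min_{F^\top F = I}
\mathrm{Tr}(F^\top L_U F)$ — partitions the cells into exactly $c$
clusters without any downstream clustering step.

## Assumptions

* Cells of a cluster are mutual near-neighbors in at least some views;
  the method cannot rescue structure that no view resolves.
* The target cluster count $c$ is known (taken from prior knowledge or
  ground truth); the method does not select it.
* All views observe the same cells in the same order.

# The four views

`buildViews()` assembles up to four views in fixed order:

1. **expression** — the pre-processed matrix from
   `preprocessPipeline()`: log2(x+1) if the raw range exceeds 100
   (discrete counts stay on their natural scale, already-logged or
   narrow-range data are not re-transformed); genes zero in *strictly
   more than* 95% of cells removed; columns divided by size factors
   $s_i/\mathrm{median}(s)$ computed on the post-log values; top 2000
   genes by variance of the normalized values (ties broken by ascending
   gene index).
2. **pathway** — AUCell-style scores: per cell, genes are ranked by
   expression (descending, ties by original gene order) and a gene set's
   score is the area under its recovery curve within the top 5% of the
   ranking, normalized to the maximum achievable area, hence in [0, 1].
   Scoring runs on the normalized matrix *before* HVG selection: keeping
   only 2000 genes would empty many sets, and set coverage matters more
   than per-gene variance here. A flag scores raw counts instead.
3. **pca** — SVD scores of the gene-centered pre-processed matrix, with
   a deterministic sign convention (largest-magnitude loading positive).
4. **dm** — diffusion maps: Gaussian kernel
   $K_{ij} = \exp(-\lVert x_i - x_j\rVert^2 / 2\sigma^2)$, Markov
   normalization $P = D^{-1}K$, coordinates $\lambda_l^t \psi_l$ from
   the top nontrivial right eigenvectors (computed through the symmetric
   conjugate $D^{-1/2} K D^{-1/2}$, same sign convention).

The PCA/DM dimensionality defaults to the Levina–Bickel
maximum-likelihood intrinsic-dimension estimate averaged over
neighborhood sizes 6–12 — the customary range for this estimator —
rounded and clipped to $[1, \min(d, n-1)]$.

# Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `k` | `"auto"`: 5 if $n < 3000$, else 15 | neighbors per graph row; small-data clustering is stable from $k = 5$ up, larger sets benefit from 15 |
| `nHVG` | 2000 | genes kept after variability ranking |
| `maxZeroFrac` | 0.95 | strict zero-fraction cutoff for gene removal |
| `logRangeThreshold` | 100 | raw range (max − min) above which log2(x+1) applies |
| `aucellTopFrac` | 0.05 | fraction of the ranking integrated by the recovery curve |
| `dmSigma` | `"auto"` | kernel bandwidth = median pairwise Euclidean distance |
| `dmT` | 1 | diffusion time; coordinates scale exactly by $\lambda_l^t$ |
| `maxIter` | 50 | alternating-optimization cap |
| `lambdaInit` | `"auto"` | mean of the initialization's per-row $\gamma_i$ |

On the diffusion bandwidth: a fixed $\sigma = 1$ is unusable on
preprocessed expression views, where squared cell–cell distances over
~2000 genes run into the thousands and $\exp(-d^2/2)$ underflows to an
identity kernel. The median-distance rule is the standard
scale-equivariant bandwidth choice and keeps the kernel well conditioned
on any input scale; a numeric $\sigma$ remains settable.

# Optimization and numerical choices

Initialization: $S^v$ from the adaptive-neighbor closed form
(`initSimilarityGraph()`), $w_v = 1/m$, $U$ = simplex-projected weighted
mean of the $S^v$ (the $\lambda \to 0$ fixed point, so it satisfies the
constraints by construction), $F$ from $L_U$. Each iteration then
updates $S^v \to w \to U \to F$ and adapts $\lambda$.

* **Graph rows.** Candidates are ranked by the *effective* cost
  $\hat e_{ij} = e_{ij} - 2 w_v u_{ij}$ (distance minus the fusion
  bonus), and the printed $k$-sparse formula is applied with "position
  $k{+}1$" read in that ordering. Ranking by distance alone can produce
  negative weights the formula does not guard against; with the combined
  ordering the formula is the exact minimizer of the row subproblem,
  which the tests verify against a generic constrained QP solver. The
  distance-only reading stays available (`ordering = "distance"`, with
  clamping and renormalization). Ties at the $k$-th/$(k{+}1)$-th
  boundary break by ascending index; a row whose $k$ nearest candidates
  are equidistant with the $(k{+}1)$-th falls back to uniform $1/k$.
* **Unified-graph rows.** $q^v = s_i^v - \frac{\lambda}{2 m w_v} d_i$
  with $d_{ij} = \lVert f_i - f_j \rVert^2$, and $u_i$ is the simplex
  projection of the unweighted mean of the $q^v$ — the printed closed
  form of the derivation (its exact-weighting variant would use the
  $w$-weighted mean; the unweighted form is kept as published and
  verified against the QP oracle as the minimizer of
  $\sum_v \lVert u - q^v \rVert^2$).
* **Simplex projection.** After shifting the input onto the
  $\mathbf{1}^\top p = 1$ hyperplane (which leaves the projection
  unchanged), the threshold is the root of
  $f(\varphi) = \frac{1}{n}\sum_j (\varphi - p_j)_+ - \varphi$, found by
  Newton iteration safeguarded by bisection ($f$ is piecewise linear and
  decreasing; the safeguard handles the flat piece where $f' = 0$).
  Convergence to $|f| < 10^{-12}$ or 100 iterations; tests cross-check
  against the independent sorting-based closed form and a QP solver.
* **$\lambda$ adaptation.** $\lambda$ needs no tuning: with $z$ the
  number of Laplacian eigenvalues below `eigTol` ($10^{-10} n$),
  $\lambda$ doubles while $z < c$, halves (and the $U$-update is redone)
  when $z > c$, and the run stops when the unified graph has exactly $c$
  components by graph traversal (edge threshold `edgeTol` $= 10^{-8}$ on
  the symmetrized adjacency). Component count and zero-eigenvalue
  multiplicity are computed independently and compared in
  `countComponents()`.
* **Degenerate inputs.** Duplicate points floor neighbor distances at
  machine-epsilon scale (with one warning); an all-equal input makes the
  diffusion kernel degenerate and errors; a cell with zero library size
  errors by name; if the rank constraint is never met within `maxIter`,
  a seeded k-means on the rows of $F$ supplies labels and the fit is
  flagged `fallbackUsed`.
* **Objective monotonicity.** Evaluated with $\gamma$ and $w$ frozen at
  their pre-sweep values — the only reading under which "the objective
  decreases" compares the same function at two states, since both
  $\gamma$ (re-derived per row to keep $k$-sparsity) and $w$ (the
  half-quadratic weight update) are themselves state-dependent. The test
  suite checks non-increase across a full sweep on random states.

# The synthetic generator

`generateSynthetic()` emulates the features of clustered scRNA-seq data
that the method actually exploits: per-gene log-normal baseline means;
disjoint marker-gene sets per cluster whose means are multiplied by
`effect` (default 8) in their cluster; Poisson counts (negative binomial
with selectable dispersion as an alternative — neither is claimed to be
the "true" single-cell noise model); independent dropout zeroing each
entry with probability `dropout` (default 0.3); default 300 cells, 1000
genes, 3 equally sized clusters (a Dirichlet option produces imbalance);
and a matching gene-set collection in which half the sets are enriched
for one cluster's markers. Everything is reproducible from `seed` and
label marginals match the requested proportions exactly.

What it does **not** emulate: batch effects, library-size gradients
confounded with cluster identity, mean–variance relationships beyond the
chosen count model, zero inflation structured by expression level,
doublets, or real pathway topology. Passing tests on this generator
therefore demonstrate correctness of the algorithm and its
implementation under clean cluster structure — not performance claims on
real tissues, where separability is far weaker than `effect = 8`
(`effect = 1` produces indistinguishable clusters and is used as the
null; `effect = 2` produces partial recovery).

# Problem sizes used by the tests

The test suite and the acceptance script run at desk scale, chosen so
the full battery completes in seconds while every property remains
non-trivial: end-to-end recovery at $n = 300$ cells × 1000 genes (and
$n = 120$–150 for secondary runs), QP-oracle equivalence on $n \le 12$
row instances (50 random instances), the component/eigenvalue duality on
100 random block-diagonal graphs, and Monte-Carlo nulls with ~1500
cells. The acceptance script regenerates a 200-cell data set and reports
the common row sum of all initialized graph rows.

# Known limitations

* Dense $n \times n$ distance, graph and Laplacian matrices and full
  eigendecompositions per iteration: memory $O(n^2)$, time $O(n^3)$ —
  fine to a few thousand cells, not for atlas-scale data.
* $c$ must be supplied; the rank constraint enforces, not estimates, it.
* The $\lambda$ doubling/halving heuristic almost always terminates
  quickly but carries no convergence proof; the k-means fallback is
  flagged so downstream code can tell.
* Per-view graphs are not symmetrized (only $L_U$ symmetrizes
  $U$), matching the published update equations.
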