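---
title: "Signature gating: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature gating: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markgate)
```

This vignette is the package's own account of the statistical procedure it
implements, the assumptions behind it, the tunable parameters that matter,
and the places where the design was genuinely open and a choice had to be
made.

## The annotation model

The input is a cell-by-marker matrix $A_{n \times m}$ and a marker-by-type
signature matrix $S_{m \times t}$ with entries $s_{ij} \in \{0\} \cup
(0, 1]$ encoding how strongly marker $i$ defines type $j$ (1 when no
grading is available). The cell-type relevance score is the weighted sum

$$\Gamma = A \cdot S,$$

computed on normalized features so that markers contribute on a common
scale. $\Gamma_{ij}$ is large when cell $i$'s profile matches type $j$'s
expected signature. The entire inferential burden then sits in one
question: *how large is large enough?* — i.e. a positivity threshold
$\theta_j$ per type.

### Why micro-clusters

Thresholding per cell directly is fragile: single-cell scores mix
biological signal with segmentation noise and bleed-through. Instead,
cells are first grouped into **micro-clusters** — Louvain communities on a
shared-nearest-neighbor (SNN) graph, with the resolution parameter tuned
so the *mean* cluster size lands between 0.1% and 0.5% of cells. At that
granularity a cluster is small enough to be essentially one cell
population, and its median CTR is a low-variance summary of that
population's affinity for each type. The within-cluster spread of scores
around those medians is exactly what the threshold search later exploits.

### Segmented regression on the rank curve

For one type, let $z$ be the micro-cluster median scores and $r$ their
ascending ranks. The curve $z(r)$ is monotone by construction; for a type
genuinely present in the tissue it shows a characteristic elbow — many
clusters with background-level scores, then a sharp rise. The package fits
the continuous piecewise-linear model

$$z = \alpha_0 + \beta_0 r + \sum_{i=1}^{g} \beta_i (r - \varphi_i)_+$$

for $g = 1, 2, 3$ breakpoints and keeps the fit minimizing
$\mathrm{AIC} = k \ln(\mathrm{SSE}/k) + 2(2 + 2g)$, counting the
intercept, base slope, $g$ slope changes and $g$ breakpoint positions as
parameters (ties go to smaller $g$; SSE is floored at $10^{-12}$ inside
the log so noiseless fits remain comparable). Clusters ranked below
$\varphi_1$ form the low-relevance group $\Phi_L$, clusters above
$\varphi_g$ the high-relevance group $\Phi_H$.

**Breakpoint optimization.** Breakpoints live on the half-integer rank
grid $(2.5, \dots, k - 1.5)$ with at least two data points per segment;
half-integers mean no rank ever equals a breakpoint, so $\Phi_L$ and
$\Phi_H$ are disjoint by construction. For $g = 1$ the grid is searched
exhaustively. For $g = 2, 3$ the package deliberately does *not* minimize
SSE globally: optimizing two or three free breakpoint positions against
residual noise reliably buys more than the 2% SSE reduction that the AIC
penalty of 4 demands at $k = 200$, so a global search makes AIC pick
spurious extra breakpoints on single-elbow data. Instead, breakpoints are
estimated by the standard iterative linearization of segmented regression
(refit with gap terms, update each $\varphi_i$ by the ratio of its gap
coefficient to its slope-change coefficient, iterate to convergence, snap
to the half-integer grid). To keep SSE monotone non-increasing in $g$ —
a property the AIC comparison relies on — the $(g{-}1)$-breakpoint optimum
augmented with one extra breakpoint at a segment midpoint is also
evaluated, and the better candidate wins: the augmented model nests the
smaller one, so its least-squares SSE can never be worse.

### The threshold

With member cells $C_L = \bigcup_{i \in \Phi_L} c_i$ and
$C_H = \bigcup_{i \in \Phi_H} c_i$, the threshold solves

$$\theta = \arg\min_\theta \; |\{i \in C_L : \tau_i > \theta\}| +
  |\{i \in C_H : \tau_i < \theta\}|.$$

The objective is a step function of $\theta$ that changes value only at
observed scores, so it suffices to evaluate a finite grid. Because both
inequalities are strict, a score value occurring in *both* groups can be
optimal exactly at that value; the candidate grid therefore contains the
observed unique scores **and** the midpoints between consecutive ones,
plus one sentinel below the minimum and one above the maximum. This grid
provably attains the global minimum over all real thresholds (the package
asserts equality against a brute-force oracle in its test suite). Ties are
broken toward the smallest candidate.

**Degenerate types.** Three situations yield $\theta = +\infty$ (no
positive calls) with a warning rather than an arbitrary threshold: an
empty relevance group; too few micro-clusters to fit any segmented model;
and a *flat* CTR curve, operationalized as the minimized misclassification
objective exceeding `max_overlap` (default 0.25) times the smaller group —
if a quarter of the smaller relevance group cannot be separated, the
"low"/"high" distinction is noise, which is the signature of a cell type
absent from the tissue.

### Categorization and mixed-cell resolution

Positivity is strict ($\Gamma_{ij} > \theta_j$). Cells positive for
exactly one type are **clean** and keep that label; zero positives means
**unknown** (and such cells are never revisited); two or more positives
make the cell **mixed** with candidate set $\xi$. Mixed cells are resolved
per distinct $\xi$: distances to the clean cells of the candidate types
are computed only over $M_\xi$, the union of those types' signature
markers — restricting the metric to relevant markers removes the noise of
the rest of the panel — and the cell takes the modal label of its $k = 10$
nearest clean anchors (Euclidean distance; $k$ is capped at the available
anchor count; vote ties break by the smaller mean distance to the tied
label's neighbors, then by candidate order; a $\xi$ with no clean anchors
at all stays `Unknown` as `unresolved_mixed`).

## Parameters

| parameter | default | units / domain | why this default |
|---|---|---|---|
| `band` | (0.001, 0.005) | fraction of n | mean micro-cluster size 0.1–0.5% of cells: small enough to be homogeneous, large enough for stable medians |
| `n_neighbors` | 20 | cells | SNN graph degree; common single-cell default |
| `n_pcs` | 30 | components | PCA rank before the kNN search; capped at min(n−1, m) |
| `max_breakpoints` | 3 | count | elbow curves rarely support more; AIC compares g = 1..3 |
| `max_overlap` | 0.25 | fraction | flat-curve guard (see above) |
| `k_deconv` | 10 | anchors | KNN vote size for mixed cells |
| `scale_factor` | 10,000 | counts | library-size target before log1p for transcript counts |
| `percentile` | 97 | percent | per-tissue Delaunay edge-length cutoff for interaction graphs |
| `pseudocount` | 0.01 | score units | guards zero/negative means in enrichment fold changes |
| `seed` | 1 | integer | pins every stochastic step (graph build, Louvain) |

Normalization choices: z-scores use the sample (n−1) standard deviation,
and zero-variance markers become all-zero columns (with a warning) rather
than being dropped, so signature alignment never silently loses a marker.
Transcript counts are scaled per cell to `scale_factor` and transformed
with the natural `log1p`; base and scale factor are conventions, exposed
as configuration. Multimodal data are column-bound after normalization
with `prot:`/`rna:` prefixes on colliding names — protein and RNA
measurements of the same gene stay distinct features.

## The resolution search

Mean cluster size is monotone decreasing in the Louvain resolution, so the
search starts at 1.0, brackets the target band geometrically (doubling or
halving), then bisects on the log scale, capped at 25 community-detection
runs. Every run restarts from the same seed, making the final partition a
deterministic function of (data, parameters, seed). If the band is
unreachable (tiny datasets, pathological graphs) the closest partition is
returned and flagged `in_band = FALSE` with a warning, rather than
failing the pipeline.

## What the synthetic generator does and does not emulate

`simulate_cells()` draws background marker values from
$\mathcal N(0, \sigma)$ and shifts each cell's signature markers by
`signal_shift` $\times\, \sigma \times$ weight (Poisson rates in counts
mode); doublets (an exact, seeded fraction of cells) carry two types'
shifts, emulating mixed identities; spillover adds a fraction of the
nearest spatial neighbor's signal, emulating segmentation bleed-through;
types can be laid out randomly or in spatial blobs. Cell counts per type
use largest-remainder rounding so they sum exactly to n.

It does **not** emulate: correlated marker noise (real antibody panels
share background), heavy-tailed intensity distributions, autofluorescence
gradients, panel-specific marker biology, or hierarchical type structure.
Passing tests on this generator therefore demonstrates the *mechanics* of
the pipeline — threshold recovery, deconvolution, determinism, metric
algebra — not performance on any real tissue; on real data the weighted-F1
figures will be lower and signature quality dominates.

Default study conditions used by the reference computations
(`scripts/acceptance.R`): 10,000 cells, 8 types with two at 1% abundance,
20 markers (2 unique signature markers per type, 4 background), signal
shift 3 sd, and a 10% doublet variant; breakpoint recovery uses k = 200
rank positions, one kink at rank 150 (slopes 0.1 and 2), noise at 2% of
the curve's dynamic range, 100 replicates. These sizes exercise rare-type
behavior and mixed-cell resolution while staying comfortable on a laptop.

## Numerical choices and edge cases

- Median of an even-sized cluster uses the midpoint convention; rank ties
  between identical medians break by micro-cluster index (deterministic).
- `.lm` fits use `stats::lm.fit`, which tolerates rank-deficient designs
  (possible when snapped breakpoints crowd); fitted values come from the
  fit, not from coefficients that may be aliased.
- Threshold ties go to the smallest candidate; binarization is strict, so
  a cell exactly at the threshold is negative.
- A single-cell dataset micro-clusters to one trivial cluster with a
  warning; n = 1 cannot be z-normalized and errors.
- Cells with zero total counts log-normalize to all-zero rows with a
  warning; `lognormalize` preserves the zero pattern exactly.
- Delaunay edges exactly at the percentile cutoff are kept (≤ convention);
  the cutoff is computed per tissue when a sample column is supplied.
- `"Unknown"` predictions count as false negatives for the reference type
  in every metric, never as true positives; reference classes can be
  excluded by name (ambiguous/artifact classes in benchmarks).

## Known limitations

- Thresholds are learned per type independently; no joint calibration
  across types, so panel-wide miscalibration shifts category proportions.
- The flat-curve guard is a heuristic: a genuinely present type whose
  signature markers are heavily shared with other types can, in
  pathological panels, be flagged degenerate.
- Louvain community detection, while seeded and deterministic here, can
  shift partitions between igraph versions; thresholds are robust to this
  (they depend on medians of many clusters) but exact hashes are not.
- Deconvolution assumes clean anchors exist for at least one candidate
  type; panels where nearly every cell is multi-positive leave cells
  unresolved rather than guessing.
- No multi-round hierarchical gating and no bootstrap stability analysis;
  one pass, one threshold per type.
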