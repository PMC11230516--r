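# markgate

Signature-driven cell-type annotation for single-cell-resolved spatial
omics (multiplexed proteomics such as CODEX/PhenoCycler, imaging
transcriptomics such as Xenium or MERFISH).

## The problem

Spatial omics experiments produce a cell-by-feature matrix **A** (n cells ×
m markers) after segmentation and quantification. Assigning a cell type to
every cell is usually done either by clustering plus manual annotation
(slow, subjective, does not transfer across tissues) or by supervised
transfer from a reference (needs a matched reference). `markgate`
implements an unsupervised middle road: expert knowledge enters only
through a marker-by-type **signature matrix** *S* (m × t), with weights
`s_ij = w ∈ (0, 1]` when marker *i* defines type *j* and 0 otherwise, and
everything else — per-type positivity thresholds, multi-label resolution —
is learned from the data at hand.

## The method

1. **Scoring.** Each cell's congruence with each type is its cell-type
   relevance (CTR) score, `Γ = A·S`, computed on normalized features
   (z-score for intensities, library-size + log1p for counts).
2. **Micro-clustering.** Cells are partitioned into micro-clusters
   (Louvain communities on a shared-nearest-neighbor graph, resolution
   tuned so the mean cluster holds 0.1–0.5 % of cells). Micro-clusters
   approximate the local spread of marker values within a homogeneous
   population.
3. **Threshold learning.** For each type, micro-cluster median CTR scores
   `z` are ranked, and a continuous piecewise-linear (segmented) model
   `z = α₀ + β₀ r + Σ βᵢ (r − φᵢ)₊` with g = 1, 2, 3 breakpoints is fit;
   the minimum-AIC fit wins. Clusters ranked below the lowest breakpoint
   form the low-relevance group, those above the highest breakpoint the
   high-relevance group, and the positivity threshold θ minimizes the
   misclassification count
   `|{τᵢ > θ, i ∈ C_L}| + |{τᵢ < θ, i ∈ C_H}|` over their member cells.
4. **Categorization and deconvolution.** Cells positive (`Γ_ij > θ_j`) for
   exactly one type are *clean*; for none, *unknown*; for several, *mixed*.
   Each mixed cell is resolved to the modal label of its k = 10 nearest
   clean cells, with distances computed only over the candidate types'
   signature markers.

The package also ships the evaluation metrics used to benchmark such
annotations (proportion-weighted recall/precision/F1 against a reference
labeling), marker-enrichment statistics (log2 fold change + one-sided
Wilcoxon, BH-adjusted), Delaunay-based cell-cell interaction matrices with
a per-tissue 97th-percentile edge filter, and a seeded synthetic-data
generator with doublets and signal spillover for testing.

## Worked example

```r
library(markgate)

sim <- simulate_cells(
  n_cells = 5000,
  cell_type_fractions = c(Tcell = 0.35, Bcell = 0.25, Macrophage = 0.2,
                          Epithelial = 0.15, NK = 0.05),
  n_markers = 14, signal_shift = 3, doublet_fraction = 0.05, seed = 42)

fit <- markgate(sim$features, sim$signatures, seed = 42)
#> normalized proteomics features
#> micro-clustering: k = 378 (mean size 13.2, resolution 32)
#>   Tcell: g = 3, theta = -0.5365 (objective 2)
#>   Bcell: g = 3, theta = 1.014 (objective 52)
#>   ...
#> categories: 2783 clean, 2167 mixed, 50 unknown

fit
#> markgate annotation model
#>   5000 cells, 14 markers, 5 cell types, 378 micro-clusters
#>   categories: clean = 2783, mixed_resolved = 2167, unknown = 50

coef(fit)            # learned CTR positivity thresholds, one per type
#>      Tcell      Bcell Macrophage Epithelial         NK
#> -0.5364697  1.0139978  1.5450795  1.8589501  0.1995048

evaluate_annotation(fit, sim$truth[, c("cell_id", "label")])
#> annotation metrics: accuracy 0.9764, weighted recall 0.9360,
#> weighted precision 0.9551, weighted F1 0.9455
```

The per-stage log reads as follows: 378 micro-clusters of ~13 cells each
fall inside the 0.1–0.5 % band; for every type the AIC selected a 3-kink
segmented fit of the rank-ordered median CTR curve, and the threshold that
best separates low- from high-relevance cells is reported with its
residual misclassification count (`objective`). 2,167 cells exceeded more
than one type's threshold (doublets and boundary bleed-through in the
simulation) and were resolved by KNN voting; 50 cells stayed below every
threshold and remain `Unknown`.

Downstream:

```r
labels(fit)                                   # final label per cell
plot(fit, cell_type = "Bcell")                # rank curve + fit + threshold
marker_enrichment(fit$features, fit, sim$signatures)   # unique-marker log2FC + BH p
cell_interactions(sim$features$coords, labels(fit))    # Delaunay interaction matrix
predict(fit, new_cells)                       # annotate new cells with learned thresholds
```

A command-line interface covering the same workflow
(`simulate`, `annotate`, `evaluate`, `neighborhood`) is installed at
`system.file("exec", "markgate", package = "markgate")`.

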