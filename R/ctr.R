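#' Compute cell-type relevance (CTR) scores
#'
#' The CTR matrix is the product `A %*% S` of the normalized cell-by-marker
#' matrix (restricted to the signature markers, in signature order) and the
#' marker-by-type signature matrix: each score sums a cell's marker values
#' weighted by their importance for the type. A higher score means the
#' cell's profile is more congruent with the type's expected signature.
#'
#' @param mat a normalized [feature_matrix()].
#' @param sig a [signature_matrix()]; every signature marker must be present
#'   in `mat`.
#' @return numeric `n x t` matrix of scores with cell IDs as row names and
#'   cell types as column names.
#' @export
compute_ctr <- function(mat, sig) {
  stopifnot(inherits(mat, "feature_matrix"), inherits(sig, "signature_matrix"))
  if (!mat$normalized)
    stop("feature matrix must be normalized before scoring")
  missing <- setdiff(rownames(sig), marker_names(mat))
  if (length(missing))
    stop("signature marker(s) absent from the feature matrix: ",
         paste(missing, collapse = ", "))
  mat$values[, rownames(sig), drop = FALSE] %*% unclass(sig)
}

#' Median CTR per micro-cluster and its rank
#'
#' For one cell type, computes the median CTR score within each
#' micro-cluster (midpoint convention for even counts) and the ascending
#' ranks of those medians. Rank ties are broken by micro-cluster index so
#' the ranking is always a deterministic permutation of `1..k`.
#'
#' @param ctr CTR matrix from [compute_ctr()].
#' @param mc a [microcluster()] partition covering the same cells.
#' @param cell_type column name of `ctr` to summarize.
#' @return list with `z` (length-k medians, in cluster-index order) and `r`
#'   (their ranks, 1 = lowest).
#' @export
cluster_median_ranks <- function(ctr, mc, cell_type) {
  stopifnot(inherits(mc, "microclustering"))
  if (!cell_type %in% colnames(ctr))
    stop("unknown cell type: ", cell_type)
  a <- mc$assignment[rownames(ctr)]
  if (anyNA(a)) stop("micro-clustering does not cover all scored cells")
  z <- as.numeric(tapply(ctr[, cell_type], a, stats::median))
  list(z = z, r = rank(z, ties.method = "first"))
}
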