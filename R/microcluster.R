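#' Build a shared-nearest-neighbor graph over cells
#'
#' Computes the top principal components of the normalized feature matrix,
#' finds each cell's `n_neighbors` nearest neighbors (kd-tree, exact), and
#' connects cells whose neighbor lists overlap, weighting edges by the
#' Jaccard similarity of the two neighbor sets (self included). Edges with
#' Jaccard weight below `prune` are dropped.
#'
#' @param mat a normalized [feature_matrix()].
#' @param n_neighbors neighbors per cell (default 20); must be `< n`.
#' @param n_pcs number of principal components (default 30); must not
#'   exceed `min(n - 1, m)`.
#' @param prune minimum Jaccard weight for an SNN edge (default 1/15).
#' @return an undirected weighted [igraph::graph] with one vertex per cell.
#' @export
build_snn_graph <- function(mat, n_neighbors = 20, n_pcs = 30, prune = 1 / 15) {
  stopifnot(inherits(mat, "feature_matrix"))
  if (!mat$normalized) stop("normalize the feature matrix before graph construction")
  v <- mat$values
  n <- nrow(v); m <- ncol(v)
  if (n < n_neighbors + 1L)
    stop("need at least n_neighbors + 1 cells (n = ", n, ")")
  if (n_pcs > min(n - 1L, m))
    stop("n_pcs must not exceed min(n - 1, m)")
  pcs <- if (m > n_pcs) {
    stats::prcomp(v, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
  } else v
  kk <- n_neighbors + 1L                     # neighbor set includes self
  nn <- RANN::nn2(pcs, k = kk)$nn.idx
  # shared-neighbor counts via sparse adjacency product
  adj <- Matrix::sparseMatrix(i = rep.int(seq_len(n), kk),
                              j = as.vector(nn), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  tri <- Matrix::which(shared > 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  cnt <- shared[tri]
  jac <- cnt / (2 * kk - cnt)
  keep <- jac >= prune
  if (!any(keep)) keep <- jac >= 0        # fully pruned graph: keep all
  g <- igraph::graph_from_edgelist(tri[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- jac[keep]
  igraph::V(g)$name <- rownames(v)
  g
}

#' Partition cells into micro-clusters
#'
#' Runs Louvain community detection on the SNN graph, searching the
#' resolution parameter until the mean cluster size `n / k` falls inside
#' the target band expressed as a fraction of `n` (default 0.1\% to 0.5\%
#' of cells per cluster). Micro-clusters are small, highly homogeneous
#' groups whose within-cluster score distribution approximates the local
#' variation of marker values.
#'
#' The search starts at resolution 1, brackets the band geometrically
#' (higher resolution gives more, smaller clusters), then bisects; at most
#' `max_iter` community-detection runs. If the band is unreachable the
#' closest partition is returned with `in_band = FALSE` and a warning.
#'
#' @param mat a normalized [feature_matrix()].
#' @param band fraction pair `(lo, hi)`; mean cluster size should land in
#'   `[lo * n, hi * n]`.
#' @param seed integer seed pinning every stochastic step.
#' @param n_neighbors,n_pcs,prune forwarded to [build_snn_graph()].
#' @param max_iter resolution-search budget (default 25).
#' @param graph optional pre-built SNN graph (skips graph construction).
#' @return an object of class `microclustering`: list with `assignment`
#'   (integer vector named by cell ID, values in `1..k`), `k`,
#'   `resolution`, `band`, `seed`, `in_band`.
#' @export
microcluster <- function(mat, band = c(0.001, 0.005), seed = 1L,
                         n_neighbors = 20, n_pcs = 30, prune = 1 / 15,
                         max_iter = 25, graph = NULL) {
  stopifnot(inherits(mat, "feature_matrix"))
  n <- nrow(mat$values)
  if (n == 0L) stop("empty feature matrix")
  if (length(band) != 2L || band[1] <= 0 || band[2] < band[1])
    stop("band must be an increasing pair of positive fractions")
  if (n == 1L) {
    warning("single cell: one trivial micro-cluster")
    return(structure(list(assignment = stats::setNames(1L, cell_ids(mat)),
                          k = 1L, resolution = NA_real_, band = band,
                          seed = seed, in_band = FALSE),
                     class = "microclustering"))
  }
  n_neighbors <- min(n_neighbors, n - 1L)
  n_pcs <- min(n_pcs, n - 1L, ncol(mat$values))
  if (is.null(graph))
    graph <- build_snn_graph(mat, n_neighbors = n_neighbors, n_pcs = n_pcs,
                             prune = prune)
  lo <- band[1] * n; hi <- band[2] * n

  run <- function(res) {
    set.seed(seed)
    cl <- igraph::cluster_louvain(graph, resolution = res)
    as.integer(igraph::membership(cl))
  }
  score <- function(memb) n / max(memb)      # mean cluster size

  res <- 1
  memb <- run(res); sz <- score(memb)
  best <- list(res = res, memb = memb, sz = sz)
  iter <- 1L
  # geometric bracketing: mean size decreases as resolution grows
  lo_res <- hi_res <- NULL
  if (sz > hi) { lo_res <- res } else if (sz < lo) { hi_res <- res }
  dist_band <- function(s) if (s > hi) s / hi else if (s < lo) lo / s else 1
  while (iter < max_iter && (sz > hi || sz < lo)) {
    if (is.null(hi_res)) {          # clusters too big: raise resolution
      res <- res * 2
    } else if (is.null(lo_res)) {   # clusters too small: lower resolution
      res <- res / 2
    } else {
      res <- sqrt(lo_res * hi_res)  # geometric bisection
    }
    memb <- run(res); sz <- score(memb); iter <- iter + 1L
    if (dist_band(sz) < dist_band(best$sz)) best <- list(res = res, memb = memb, sz = sz)
    if (sz > hi) lo_res <- res else if (sz < lo) hi_res <- res else {
      best <- list(res = res, memb = memb, sz = sz); break
    }
    if (!is.null(lo_res) && !is.null(hi_res) && hi_res / lo_res < 1 + 1e-6) break
  }
  in_band <- best$sz >= lo && best$sz <= hi
  if (!in_band)
    warning(sprintf("mean cluster size %.2f outside target [%.2f, %.2f]; closest partition returned",
                    best$sz, lo, hi))
  memb <- best$memb
  # relabel clusters 1..k in order of first appearance, drop gaps
  memb <- match(memb, unique(memb))
  structure(list(assignment = stats::setNames(as.integer(memb), cell_ids(mat)),
                 k = max(memb), resolution = best$res, band = band,
                 seed = seed, in_band = in_band),
            class = "microclustering")
}

#' @exportS3Method print microclustering
print.microclustering <- function(x, ...) {
  cat(sprintf("microclustering: %d cells in %d clusters (mean size %.1f, resolution %.4g%s)\n",
              length(x$assignment), x$k, length(x$assignment) / x$k,
              x$resolution, if (x$in_band) "" else ", outside target band"))
  invisible(x)
}
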