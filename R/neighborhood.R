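#' Cell-cell interaction graph and type-interaction matrix
#'
#' Builds the spatial interaction graph of annotated cells: nodes are
#' labeled cells (`"Unknown"` cells are excluded first), edges come from
#' the Delaunay triangulation of the cell centroids, and edges longer than
#' the given percentile of the tissue's own edge-length distribution are
#' removed as improbably long contacts (edges exactly at the cutoff are
#' kept). The symmetric type-by-type interaction matrix counts surviving
#' edges between each pair of types; each edge contributes once, also on
#' the diagonal.
#'
#' When `sample` is given, each sample/tissue is triangulated and
#' thresholded independently (per-tissue cutoffs) and a list is returned.
#'
#' @param coords numeric matrix/data frame of cell centroids (x, y), one
#'   row per cell.
#' @param labels character vector of cell labels aligned with `coords`.
#' @param percentile edge-length percentile cutoff (default 97).
#' @param sample optional sample/tissue identifier per cell.
#' @return object of class `interaction_graph`: list with `edges` (data
#'   frame: `from`, `to`, `length`, indices into the labeled subset),
#'   `matrix` (symmetric integer type-by-type counts), `cutoff`,
#'   `n_removed`, `labels`, `coords`; or a named list of such objects when
#'   `sample` is given.
#' @export
cell_interactions <- function(coords, labels, percentile = 97, sample = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) != length(labels))
    stop("coords must be an (x, y) matrix with one row per label")
  if (!is.null(sample)) {
    if (length(sample) != length(labels))
      stop("sample must align with labels")
    return(lapply(split(seq_along(labels), sample), function(i)
      cell_interactions(coords[i, , drop = FALSE], labels[i],
                        percentile = percentile)))
  }
  keep <- labels != "Unknown" & !is.na(labels)
  coords <- coords[keep, , drop = FALSE]
  labels <- labels[keep]
  if (nrow(coords) < 3L)
    stop("need at least 3 labeled cells with coordinates")
  if (qr(sweep(coords, 2, colMeans(coords)))$rank < 2L)
    stop("cells are collinear; triangulation is undefined")
  dd <- deldir::deldir(coords[, 1], coords[, 2])
  seg <- dd$delsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  cutoff <- stats::quantile(len, percentile / 100, names = FALSE)
  keep_e <- len <= cutoff
  edges <- data.frame(from = seg$ind1[keep_e], to = seg$ind2[keep_e],
                      length = len[keep_e])
  types <- sort(unique(labels))
  m <- matrix(0L, length(types), length(types), dimnames = list(types, types))
  li <- labels[edges$from]; lj <- labels[edges$to]
  for (e in seq_len(nrow(edges))) {
    a <- li[e]; b <- lj[e]
    if (a == b) m[a, a] <- m[a, a] + 1L
    else { m[a, b] <- m[a, b] + 1L; m[b, a] <- m[b, a] + 1L }
  }
  structure(list(edges = edges, matrix = m, cutoff = cutoff,
                 n_removed = sum(!keep_e), percentile = percentile,
                 labels = labels, coords = coords),
            class = "interaction_graph")
}

#' @exportS3Method print interaction_graph
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d cells, %d edges (%d removed above %.4g = p%.3g)\n",
              length(x$labels), nrow(x$edges), x$n_removed, x$cutoff,
              x$percentile))
  invisible(x)
}
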