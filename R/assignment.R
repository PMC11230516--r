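#' Categorize cells from the positivity matrix
#'
#' Cells positive for exactly one type are *clean* and get that label;
#' cells positive for more than one type are *mixed* and carry their
#' candidate set; cells positive for none are *unknown*.
#'
#' @param B binary positivity matrix from [binarize()].
#' @return object of class `cell_assignment`: data frame with columns
#'   `cell_id`, `label`, `category`, plus a `candidates` attribute (list of
#'   candidate type sets for mixed cells, in signature column order).
#' @export
categorize <- function(B) {
  rs <- rowSums(B)
  types <- colnames(B)
  label <- rep("Unknown", nrow(B))
  category <- rep("unknown", nrow(B))
  clean <- rs == 1L
  label[clean] <- types[max.col(B, ties.method = "first")[clean]]
  category[clean] <- "clean"
  mixed <- rs > 1L
  category[mixed] <- "mixed"
  candidates <- vector("list", nrow(B))
  candidates[mixed] <- lapply(which(mixed), function(i) types[B[i, ] == 1L])
  out <- data.frame(cell_id = rownames(B), label = label, category = category,
                    stringsAsFactors = FALSE)
  attr(out, "candidates") <- candidates
  class(out) <- c("cell_assignment", "data.frame")
  out
}

#' Resolve mixed cells by KNN voting in the relevant marker subspace
#'
#' For each distinct candidate set of types, the union of those types'
#' signature markers defines a feature subspace. Every mixed cell with that
#' candidate set is compared (Euclidean distance, restricted to the
#' subspace) to the *clean* cells of the candidate types, and receives the
#' modal label among its `k` nearest clean anchors. Restricting to the
#' candidate types' own markers removes noise from irrelevant features.
#'
#' `k` is capped at the available anchor count. Vote ties are broken by the
#' smallest mean distance to the tied label's neighbors, then by candidate
#' order. Candidate sets with no clean anchors for any member type stay
#' unresolved (`unresolved_mixed`, label `"Unknown"`).
#'
#' @param assign a [categorize()] result (clean labels are never altered).
#' @param mat the normalized [feature_matrix()] the assignment came from.
#' @param sig the [signature_matrix()].
#' @param k_neighbors anchors consulted per mixed cell (default 10).
#' @param anchors optional list(`values` = matrix, `labels` = character)
#'   overriding the clean-anchor pool, used when annotating new cells
#'   against a fitted model's anchors.
#' @return the updated `cell_assignment`; mixed cells become
#'   `mixed_resolved` or `unresolved_mixed`.
#' @export
deconvolve <- function(assign, mat, sig, k_neighbors = 10, anchors = NULL) {
  stopifnot(inherits(assign, "cell_assignment"))
  if (k_neighbors < 1) stop("k_neighbors must be at least 1")
  candidates <- attr(assign, "candidates")
  mixed_idx <- which(assign$category == "mixed")
  if (!length(mixed_idx)) return(assign)
  if (is.null(anchors)) {
    ci <- assign$category == "clean"
    anchors <- list(values = mat$values[assign$cell_id[ci], , drop = FALSE],
                    labels = assign$label[ci])
  }
  keys <- vapply(candidates[mixed_idx], paste, "", collapse = "\r")
  for (key in unique(keys)) {
    rows <- mixed_idx[keys == key]
    xi <- candidates[[rows[1]]]
    markers <- signature_markers(sig, xi)
    anch <- which(anchors$labels %in% xi)
    if (!length(anch)) {
      assign$category[rows] <- "unresolved_mixed"
      assign$label[rows] <- "Unknown"
      next
    }
    av <- anchors$values[anch, markers, drop = FALSE]
    al <- anchors$labels[anch]
    qv <- mat$values[assign$cell_id[rows], markers, drop = FALSE]
    k <- min(k_neighbors, nrow(av))
    nn <- RANN::nn2(av, qv, k = k)
    for (j in seq_along(rows)) {
      labs <- al[nn$nn.idx[j, ]]
      dists <- nn$nn.dists[j, ]
      tab <- table(factor(labs, levels = xi))
      top <- names(tab)[tab == max(tab)]
      if (length(top) > 1L) {
        md <- vapply(top, function(l) mean(dists[labs == l]), 0)
        top <- top[md == min(md)]          # then candidate order (first)
      }
      assign$label[rows[j]] <- top[1]
      assign$category[rows[j]] <- "mixed_resolved"
    }
  }
  assign
}

#' @exportS3Method print cell_assignment
print.cell_assignment <- function(x, ...) {
  cat(sprintf("cell_assignment: %d cells\n", nrow(x)))
  print(table(category = x$category))
  invisible(x)
}

#' Convert a cell assignment to a plain data frame
#'
#' @param x a `cell_assignment`.
#' @param ... unused.
#' @return data frame with `cell_id`, `label`, `category` and a
#'   semicolon-joined `candidate_set` column.
#' @exportS3Method as.data.frame cell_assignment
as.data.frame.cell_assignment <- function(x, ...) {
  cand <- attr(x, "candidates")
  out <- data.frame(cell_id = x$cell_id, label = x$label,
                    category = x$category,
                    candidate_set = vapply(cand, function(s)
                      if (is.null(s)) "" else paste(s, collapse = ";"), ""),
                    stringsAsFactors = FALSE)
  out
}
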