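#' Per-type confusion counts against a reference labeling
#'
#' For each cell type, over the cells shared by prediction and reference:
#' TP = predicted and referenced as the type; FP = predicted but referenced
#' otherwise; FN = referenced but predicted otherwise (cells the method
#' left `"Unknown"` count here, never as TP); TN = neither. Reference cells
#' whose label is in `exclude_labels` are dropped before counting, which
#' mirrors the common benchmark practice of excluding ambiguous or
#' artifactual reference classes.
#'
#' @param pred predicted labels: a fitted `markgate` model, a
#'   `cell_assignment`, or a character vector named by cell ID.
#' @param ref reference labels as a character vector named by cell ID (or a
#'   two-column data frame cell_id, label).
#' @param exclude_labels reference labels to drop entirely (default none).
#' @return data frame with one row per type: `cell_type`, `TP`, `FP`, `FN`,
#'   `TN`, `proportion` (reference fraction; 0 for types absent from the
#'   reference).
#' @export
confusion_counts <- function(pred, ref, exclude_labels = NULL) {
  pred <- as_label_vector(pred)
  ref <- as_label_vector(ref)
  shared <- intersect(names(pred), names(ref))
  if (!length(shared))
    stop("prediction and reference share no cell IDs")
  pred <- pred[shared]; ref <- ref[shared]
  if (length(exclude_labels)) {
    keep <- !ref %in% exclude_labels
    pred <- pred[keep]; ref <- ref[keep]
  }
  n <- length(ref)
  types <- sort(unique(c(ref, setdiff(pred, "Unknown"))))
  rows <- lapply(types, function(tt) {
    tp <- sum(pred == tt & ref == tt)
    fp <- sum(pred == tt & ref != tt)
    fn <- sum(ref == tt & pred != tt)
    data.frame(cell_type = tt, TP = tp, FP = fp, FN = fn,
               TN = n - tp - fp - fn,
               proportion = sum(ref == tt) / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

as_label_vector <- function(x) {
  if (inherits(x, "markgate")) return(labels(x))
  if (inherits(x, "cell_assignment"))
    return(stats::setNames(x$label, x$cell_id))
  if (is.data.frame(x)) {
    if (ncol(x) < 2) stop("labeling data frame needs cell IDs and labels")
    return(stats::setNames(as.character(x[[2]]), as.character(x[[1]])))
  }
  if (is.null(names(x))) stop("label vector must be named by cell ID")
  stats::setNames(as.character(x), names(x))
}

#' Proportion-weighted annotation metrics
#'
#' Computes per-type recall `TP/(TP+FN)` and precision `TP/(TP+FP)` (0 when
#' the denominator is 0), their averages weighted by each type's reference
#' proportion, the harmonic-mean weighted F1, and pooled accuracy
#' `(TP+TN)/(TP+FP+TN+FN)` summed over types. Weighting by reference
#' abundance keeps dominant types from masking failure on rare ones while
#' still reflecting the composition of the tissue.
#'
#' @param counts a [confusion_counts()] data frame.
#' @return object of class `annotation_metrics`: list with `accuracy`,
#'   `weighted_recall`, `weighted_precision`, `weighted_f1`, `per_type`
#'   (counts plus per-type recall/precision and the dominant/rare split at
#'   1\% reference proportion).
#' @export
weighted_metrics <- function(counts) {
  stopifnot(all(c("TP", "FP", "FN", "TN", "proportion") %in% names(counts)))
  rec <- ifelse(counts$TP + counts$FN > 0, counts$TP / (counts$TP + counts$FN), 0)
  prec <- ifelse(counts$TP + counts$FP > 0, counts$TP / (counts$TP + counts$FP), 0)
  wr <- sum(rec * counts$proportion)
  wp <- sum(prec * counts$proportion)
  wf1 <- if (wp + wr > 0) 2 * wp * wr / (wp + wr) else 0
  acc <- sum(counts$TP + counts$TN) /
    sum(counts$TP + counts$FP + counts$TN + counts$FN)
  per <- cbind(counts, recall = rec, precision = prec,
               abundance = ifelse(counts$proportion >= 0.01, "dominant", "rare"))
  structure(list(accuracy = acc, weighted_recall = wr,
                 weighted_precision = wp, weighted_f1 = wf1,
                 per_type = per),
            class = "annotation_metrics")
}

#' @exportS3Method print annotation_metrics
print.annotation_metrics <- function(x, ...) {
  cat(sprintf(paste0("annotation metrics: accuracy %.4f, weighted recall %.4f,",
                     " weighted precision %.4f, weighted F1 %.4f\n"),
              x$accuracy, x$weighted_recall, x$weighted_precision,
              x$weighted_f1))
  invisible(x)
}

#' Evaluate an annotation against a reference in one call
#'
#' @inheritParams confusion_counts
#' @return an `annotation_metrics` object.
#' @export
evaluate_annotation <- function(pred, ref, exclude_labels = NULL) {
  weighted_metrics(confusion_counts(pred, ref, exclude_labels = exclude_labels))
}

#' Marker enrichment strength of unique signature markers
#'
#' For each marker that is the signature of exactly one cell type, compares
#' its values in cells assigned to that type against cells assigned to any
#' other (non-Unknown) type: log2 fold change of means (with a pseudocount
#' guarding zero means) and a one-sided Wilcoxon rank-sum test
#' (alternative: greater), Benjamini-Hochberg adjusted across all tested
#' markers. Group means are clamped at zero before the ratio so the fold
#' change stays defined on z-normalized data, where means can be negative.
#'
#' @param mat the normalized [feature_matrix()].
#' @param labels cell labels (any form accepted by [confusion_counts()]).
#' @param sig the [signature_matrix()].
#' @param pseudocount added to both means before the ratio (default 0.01).
#' @return data frame: `marker`, `cell_type`, `log2fc`, `p_value`,
#'   `p_adjusted`. Markers whose type has no assigned cells are skipped
#'   with a warning.
#' @export
marker_enrichment <- function(mat, labels, sig, pseudocount = 0.01) {
  stopifnot(inherits(mat, "feature_matrix"), inherits(sig, "signature_matrix"))
  labels <- as_label_vector(labels)
  labels <- labels[intersect(names(labels), cell_ids(mat))]
  uniq <- rownames(sig)[rowSums(sig > 0) == 1L]
  rows <- list()
  skipped <- character()
  for (mk in uniq) {
    tt <- colnames(sig)[sig[mk, ] > 0]
    inside <- names(labels)[labels == tt]
    outside <- names(labels)[labels != tt & labels != "Unknown"]
    if (!length(inside)) { skipped <- c(skipped, mk); next }
    if (!length(outside)) { skipped <- c(skipped, mk); next }
    xi <- mat$values[inside, mk]
    xo <- mat$values[outside, mk]
    p <- stats::wilcox.test(xi, xo, alternative = "greater", exact = FALSE)$p.value
    rows[[mk]] <- data.frame(
      marker = mk, cell_type = tt,
      log2fc = log2((max(mean(xi), 0) + pseudocount) /
                    (max(mean(xo), 0) + pseudocount)),
      p_value = p, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("marker(s) skipped (no assigned cells to compare): ",
            paste(skipped, collapse = ", "))
  if (!length(rows))
    return(data.frame(marker = character(), cell_type = character(),
                      log2fc = numeric(), p_value = numeric(),
                      p_adjusted = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
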