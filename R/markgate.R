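#' Fit a signature-gating annotation model
#'
#' `markgate()` is the package's main entry point. It runs the full
#' annotation pipeline on a cell-by-feature matrix and a marker signature
#' table:
#'
#' 1. normalize the features (z-score for proteomics, library-size +
#'    `log1p` for transcriptomics) unless already normalized;
#' 2. partition cells into micro-clusters ([microcluster()]);
#' 3. score every cell against every type ([compute_ctr()]);
#' 4. per type, rank the micro-cluster median scores, fit segmented
#'    regressions with 1-3 breakpoints, keep the minimum-AIC fit, split
#'    clusters into low/high relevance groups and learn the
#'    misclassification-minimizing positivity threshold
#'    ([select_fit()], [relevance_groups()], [optimal_threshold()]);
#' 5. binarize, categorize cells as clean / mixed / unknown, and resolve
#'    mixed cells by KNN voting in the candidate types' marker subspace
#'    ([categorize()], [deconvolve()]).
#'
#' @param features a [feature_matrix()] (raw or normalized).
#' @param signatures a [signature_matrix()].
#' @param normalize `"auto"` normalizes raw input by modality; `"none"`
#'   requires pre-normalized input.
#' @param scale_factor library-size target for transcriptomics (default 1e4).
#' @param band micro-cluster mean-size band as fractions of n.
#' @param n_neighbors,n_pcs SNN graph parameters (defaults 20 and 30;
#'   capped at the data's dimensions).
#' @param max_breakpoints largest breakpoint count tried per type.
#' @param max_overlap separability guard: a cell type whose minimized
#'   misclassification objective exceeds `max_overlap` times the smaller
#'   relevance group is treated as degenerate (flat CTR curve, no positive
#'   calls). Default 0.25.
#' @param k_deconv KNN size for mixed-cell resolution (default 10).
#' @param seed integer governing every stochastic step.
#' @param verbose print per-stage progress.
#' @return an object of class `markgate`: list with `assignment`
#'   (a [categorize()]/[deconvolve()] result), `thresholds` (per-type data
#'   frame: `theta`, `g`, `breakpoints`, `objective`, `degenerate`),
#'   `fits` (per-type `segfit` + rank data), `clusters`
#'   (`microclustering`), `ctr`, `features` (normalized), `signatures`,
#'   `config`, `call`.
#' @examples
#' sim <- simulate_cells(n_cells = 600,
#'                       cell_type_fractions = c(A = 0.5, B = 0.3, C = 0.2),
#'                       n_markers = 10, seed = 7)
#' fit <- markgate(sim$features, sim$signatures,
#'                 band = c(0.01, 0.05), verbose = FALSE)
#' table(labels(fit), sim$truth$label)
#' coef(fit)
#' @export
markgate <- function(features, signatures,
                     normalize = c("auto", "none"),
                     scale_factor = 1e4,
                     band = c(0.001, 0.005),
                     n_neighbors = 20, n_pcs = 30,
                     max_breakpoints = 3,
                     max_overlap = 0.25,
                     k_deconv = 10,
                     seed = 1L,
                     verbose = TRUE) {
  cl <- match.call()
  normalize <- match.arg(normalize)
  stopifnot(inherits(features, "feature_matrix"),
            inherits(signatures, "signature_matrix"))
  say <- function(...) if (verbose) message(...)

  if (!features$normalized) {
    if (normalize == "none")
      stop("features are raw; pass normalize = \"auto\" or normalize beforehand")
    features <- switch(features$modality,
      proteomics = znormalize(features),
      transcriptomics = lognormalize(features, scale_factor = scale_factor),
      stop("multimodal input must be normalized before fitting"))
    say("normalized ", features$modality, " features")
  }

  mc <- microcluster(features, band = band, seed = seed,
                     n_neighbors = n_neighbors, n_pcs = n_pcs)
  say(sprintf("micro-clustering: k = %d (mean size %.1f, resolution %.3g)",
              mc$k, nrow(features$values) / mc$k, mc$resolution))

  ctr <- compute_ctr(features, signatures)

  types <- colnames(signatures)
  fits <- vector("list", length(types)); names(fits) <- types
  th <- stats::setNames(numeric(length(types)), types)
  info <- data.frame(cell_type = types, theta = NA_real_, g = NA_integer_,
                     breakpoints = NA_character_, objective = NA_integer_,
                     degenerate = FALSE, stringsAsFactors = FALSE)
  clus <- mc$assignment[rownames(ctr)]
  for (tname in types) {
    zr <- cluster_median_ranks(ctr, mc, tname)
    res <- tryCatch({
      fit <- select_fit(zr$z, zr$r, max_g = max_breakpoints)
      grp <- relevance_groups(fit, zr$r)
      opt <- withCallingHandlers(
        optimal_threshold(ctr[, tname], grp, clus),
        warning = function(w) invokeRestart("muffleWarning"))
      list(fit = fit, opt = opt)
    }, error = function(e) NULL)
    # a type whose low/high relevance groups barely separate (flat CTR
    # curve, e.g. a signature absent from the tissue) is degenerate too
    if (!is.null(res) && !res$opt$degenerate &&
        res$opt$objective > max_overlap * min(res$opt$n_low, res$opt$n_high)) {
      res$opt$degenerate <- TRUE
    }
    if (is.null(res) || res$opt$degenerate) {
      th[tname] <- Inf
      info[info$cell_type == tname, c("degenerate")] <- TRUE
      info[info$cell_type == tname, "theta"] <- Inf
      if (!is.null(res)) fits[[tname]] <- c(res["fit"], list(z = zr$z, r = zr$r))
      warning("cell type '", tname,
              "' is degenerate: threshold +Inf, no positive calls")
      next
    }
    th[tname] <- res$opt$theta
    fits[[tname]] <- c(res["fit"], list(z = zr$z, r = zr$r))
    i <- info$cell_type == tname
    info$theta[i] <- res$opt$theta
    info$g[i] <- res$fit$g
    info$breakpoints[i] <- paste(res$fit$breakpoints, collapse = ";")
    info$objective[i] <- res$opt$objective
    say(sprintf("  %s: g = %d, theta = %.4g (objective %d)",
                tname, res$fit$g, res$opt$theta, res$opt$objective))
  }

  B <- binarize(ctr, th)
  assign <- categorize(B)
  pre_counts <- table(factor(assign$category,
                             levels = c("clean", "mixed", "unknown")))
  say(sprintf("categories: %d clean, %d mixed, %d unknown",
              pre_counts["clean"], pre_counts["mixed"], pre_counts["unknown"]))
  assign <- deconvolve(assign, features, signatures, k_neighbors = k_deconv)

  structure(list(assignment = assign, thresholds = info, fits = fits,
                 clusters = mc, ctr = ctr, positivity = B,
                 features = features, signatures = signatures,
                 pre_deconvolution = pre_counts,
                 config = list(band = band, n_neighbors = n_neighbors,
                               n_pcs = n_pcs, max_breakpoints = max_breakpoints,
                               max_overlap = max_overlap,
                               k_deconv = k_deconv, scale_factor = scale_factor,
                               seed = seed),
                 call = cl),
            class = "markgate")
}

#' @exportS3Method print markgate
print.markgate <- function(x, ...) {
  cat("markgate annotation model\n")
  cat(sprintf("  %d cells, %d markers, %d cell types, %d micro-clusters\n",
              nrow(x$ctr), ncol(x$features$values), ncol(x$ctr), x$clusters$k))
  cat("  categories:", paste(sprintf("%s = %d",
      names(table(x$assignment$category)), table(x$assignment$category)),
      collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method summary markgate
summary.markgate <- function(object, ...) {
  lab <- table(object$assignment$label)
  structure(list(thresholds = object$thresholds,
                 categories = table(object$assignment$category),
                 labels = sort(lab, decreasing = TRUE),
                 k = object$clusters$k,
                 resolution = object$clusters$resolution,
                 n = nrow(object$ctr)),
            class = "summary.markgate")
}

#' @exportS3Method print summary.markgate
print.summary.markgate <- function(x, ...) {
  cat(sprintf("markgate fit: %d cells, %d micro-clusters (resolution %.3g)\n\n",
              x$n, x$k, x$resolution))
  cat("Per-type thresholds:\n")
  print(x$thresholds, row.names = FALSE)
  cat("\nCategories:\n"); print(x$categories)
  cat("\nLabel counts:\n"); print(x$labels)
  invisible(x)
}

#' Extract the learned positivity thresholds
#'
#' @param object a fitted `markgate` model.
#' @param ... unused.
#' @return named numeric vector of per-type CTR thresholds (`+Inf` for
#'   degenerate types).
#' @exportS3Method coef markgate
coef.markgate <- function(object, ...) {
  stats::setNames(object$thresholds$theta, object$thresholds$cell_type)
}

#' Final cell labels of a fitted model
#'
#' @param object a fitted `markgate` model.
#' @param ... unused.
#' @return character vector of labels named by cell ID.
#' @exportS3Method labels markgate
labels.markgate <- function(object, ...) {
  stats::setNames(object$assignment$label, object$assignment$cell_id)
}

#' Annotate new cells with a fitted model
#'
#' Applies the learned per-type thresholds to new cells: scores them
#' against the stored signatures, binarizes, categorizes, and resolves
#' mixed cells against the *training* clean anchors. The new data must be
#' normalized the same way as the training data.
#'
#' @param object a fitted `markgate` model.
#' @param newdata a normalized [feature_matrix()] containing every
#'   signature marker. Defaults to the training data.
#' @param ... unused.
#' @return a `cell_assignment` for the new cells.
#' @exportS3Method predict markgate
predict.markgate <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$assignment)
  stopifnot(inherits(newdata, "feature_matrix"))
  if (!newdata$normalized) stop("newdata must be normalized")
  ctr <- compute_ctr(newdata, object$signatures)
  B <- binarize(ctr, coef(object))
  assign <- categorize(B)
  ci <- object$assignment$category == "clean"
  anchors <- list(values = object$features$values[object$assignment$cell_id[ci], ,
                                                  drop = FALSE],
                  labels = object$assignment$label[ci])
  deconvolve(assign, newdata, object$signatures,
             k_neighbors = object$config$k_deconv, anchors = anchors)
}

#' Diagnostic plot of the learned threshold for one cell type
#'
#' Plots the rank-ordered micro-cluster median CTR curve with the fitted
#' segmented regression, its breakpoints (vertical dashed lines) and the
#' learned positivity threshold (horizontal line).
#'
#' @param x a fitted `markgate` model.
#' @param cell_type type to plot; defaults to the first non-degenerate one.
#' @param ... passed to [graphics::plot()].
#' @exportS3Method plot markgate
plot.markgate <- function(x, cell_type = NULL, ...) {
  ok <- x$thresholds$cell_type[!x$thresholds$degenerate]
  if (is.null(cell_type)) cell_type <- ok[1]
  f <- x$fits[[cell_type]]
  if (is.null(f)) stop("no fit stored for cell type ", cell_type)
  o <- order(f$r)
  graphics::plot(f$r[o], f$z[o], xlab = "micro-cluster rank",
                 ylab = "median CTR", main = cell_type, pch = 16,
                 col = "grey40", ...)
  graphics::lines(f$r[o], f$fit$fitted[o], col = "firebrick", lwd = 2)
  graphics::abline(v = f$fit$breakpoints, lty = 2, col = "steelblue")
  th <- x$thresholds$theta[x$thresholds$cell_type == cell_type]
  if (is.finite(th)) graphics::abline(h = th, col = "darkgreen")
  invisible(x)
}
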