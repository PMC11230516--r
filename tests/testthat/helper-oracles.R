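# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own code paths.

# small normalized feature matrix built directly
fm <- function(values, modality = "proteomics", coords = NULL,
               normalized = TRUE) {
  feature_matrix(values, modality = modality, coords = coords,
                 normalized = normalized)
}

named_matrix <- function(data, nrow, cells = NULL, markers = NULL) {
  m <- matrix(data, nrow = nrow)
  rownames(m) <- cells %||% sprintf("c%d", seq_len(nrow(m)))
  colnames(m) <- markers %||% sprintf("m%d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

quiet_sig <- function(weights) suppressWarnings(signature_matrix(weights))

# exhaustive threshold oracle: scans a dense sweep of real thresholds,
# including every candidate the step function can distinguish
brute_threshold_objective <- function(tau_L, tau_H) {
  pts <- sort(unique(c(tau_L, tau_H)))
  cand <- sort(c(pts - 1e-9, pts + 1e-9, pts,
                 min(pts) - 1, max(pts) + 1,
                 (pts[-1] + pts[-length(pts)]) / 2))
  min(vapply(cand, function(th) sum(tau_L > th) + sum(tau_H < th), 0))
}

# plain-loop KNN majority vote with the package's tie rules
brute_knn_labels <- function(anchor_values, anchor_labels, query_values,
                             k, xi) {
  out <- character(nrow(query_values))
  k <- min(k, nrow(anchor_values))
  for (i in seq_len(nrow(query_values))) {
    d <- sqrt(rowSums(sweep(anchor_values, 2, query_values[i, ])^2))
    o <- order(d)[seq_len(k)]
    labs <- anchor_labels[o]
    tab <- table(factor(labs, levels = xi))
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      md <- vapply(top, function(l) mean(d[o][labs == l]), 0)
      top <- top[md == min(md)]
    }
    out[i] <- top[1]
  }
  out
}

# BH step-up written independently of stats::p.adjust
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# segmented-model SSE at fixed breakpoints via lm(), for cross-checks
lm_seg_sse <- function(z, r, phis) {
  X <- do.call(cbind, lapply(phis, function(p) pmax(0, r - p)))
  sum(stats::resid(stats::lm(z ~ r + X))^2)
}

# piecewise rank curve with kinks at the given (possibly half-integer)
# positions, for breakpoint-recovery tests
kink_curve <- function(k, kinks, slopes, noise_sd = 0) {
  r <- seq_len(k)
  mu <- slopes[1] * r
  for (i in seq_along(kinks))
    mu <- mu + (slopes[i + 1] - slopes[i]) * pmax(0, r - kinks[i])
  mu + stats::rnorm(k, 0, noise_sd)
}
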