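#' Fit a continuous piecewise-linear (segmented) regression
#'
#' Fits `z = a0 + b0*r + sum_i b_i * (r - phi_i)_+` by least squares, with
#' `g` breakpoints optimized over the half-integer rank grid
#' `(2.5, 3.5, ..., k - 1.5)` subject to a minimum segment size of two data
#' points. Half-integer breakpoints guarantee no rank ever coincides with a
#' breakpoint, which keeps the low/high relevance groups disjoint by
#' construction.
#'
#' For `g = 1` the grid is searched exhaustively. For `g = 2, 3` the
#' breakpoints are estimated by the standard iterative linearization of
#' segmented regression: starting from evenly spaced positions, the model
#' is refit with gap terms and each breakpoint is updated by the ratio of
#' the gap coefficient to the slope-change coefficient until the positions
#' stabilize, then snapped to the half-integer grid. A global SSE search
#' is deliberately avoided for multiple breakpoints: optimizing extra
#' breakpoint positions against the residual noise systematically inflates
#' the apparent SSE gain and defeats AIC model selection. To keep SSE
#' monotone non-increasing in `g`, the `(g-1)`-breakpoint optimum
#' augmented with one extra breakpoint at a segment midpoint is also
#' evaluated (the nested model guarantees its SSE is no worse), and the
#' better of the two candidates wins.
#'
#' AIC follows the Gaussian profile form `k*log(SSE/k) + 2*(2 + 2g)`,
#' counting the intercept, base slope, `g` slope changes and `g` breakpoint
#' locations as parameters. SSE is floored at 1e-12 inside the log so
#' noiseless fits stay comparable.
#'
#' @param z numeric vector of micro-cluster median CTR scores.
#' @param r integer vector of their ranks (a permutation of `1..k`).
#' @param g number of breakpoints, 1, 2 or 3; needs `k >= 2g + 2`.
#' @return object of class `segfit`: list with `g`, `breakpoints`,
#'   `coefficients` (`alpha0`, `beta0`, `beta1..betag`), `fitted`, `sse`,
#'   `aic`, `k`.
#' @export
fit_segmented <- function(z, r, g) {
  k <- length(z)
  if (length(r) != k) stop("z and r must have the same length")
  if (!g %in% 1:3) stop("g must be 1, 2 or 3")
  if (k < 2 * g + 2)
    stop("insufficient clusters for ", g, " breakpoints (k = ", k, ")")
  grid <- seq(2.5, k - 1.5, by = 1)
  lo <- grid[1]; hi <- grid[length(grid)]
  sse_at <- function(phis) {
    X <- cbind(1, r, vapply(phis, function(p) pmax(0, r - p), numeric(k)))
    sum(stats::lm.fit(X, z)$residuals^2)
  }
  snap <- function(phi) {
    # nearest half-integers in [lo, hi] with pairwise separation >= 2
    phi <- sort(pmin(pmax(floor(phi) + 0.5, lo), hi))
    ng <- length(phi)
    for (i in seq_len(ng)[-1])
      if (phi[i] - phi[i - 1] < 2) phi[i] <- phi[i - 1] + 2
    if (phi[ng] > hi) {
      phi[ng] <- hi
      for (i in rev(seq_len(ng - 1)))
        if (phi[i + 1] - phi[i] < 2) phi[i] <- phi[i + 1] - 2
    }
    phi
  }
  if (g == 1) {
    sses <- vapply(grid, sse_at, 0)
    best_phi <- grid[which.min(sses)]      # first minimum = smallest phi
    best_sse <- min(sses)
  } else {
    # iterative linearized estimation (gap-term updates)
    iterate <- function(phi) {
      for (it in 1:30) {
        U <- vapply(phi, function(p) pmax(0, r - p), numeric(k))
        V <- vapply(phi, function(p) -as.numeric(r > p), numeric(k))
        cf <- stats::lm.fit(cbind(1, r, U, V), z)$coefficients
        beta <- cf[3:(2 + g)]; gam <- cf[(3 + g):(2 + 2 * g)]
        step <- ifelse(is.na(beta) | is.na(gam) | abs(beta) < 1e-10,
                       0, gam / beta)
        new_phi <- sort(pmin(pmax(phi + step, lo), hi))
        if (max(abs(new_phi - phi)) < 1e-3) { phi <- new_phi; break }
        phi <- new_phi
      }
      snap(phi)
    }
    cand <- list(iterate(lo + seq_len(g) * (hi - lo) / (g + 1)))
    # nested augmentation of the (g-1)-optimum keeps SSE monotone in g
    prev <- fit_segmented(z, r, g - 1L)$breakpoints
    bounds <- c(lo - 2, prev, hi + 2)
    for (i in seq_len(length(bounds) - 1)) {
      mid <- floor((bounds[i] + bounds[i + 1]) / 2) + 0.5
      if (mid >= lo && mid <= hi && all(abs(mid - prev) >= 2))
        cand[[length(cand) + 1]] <- sort(c(prev, mid))
    }
    sses <- vapply(cand, sse_at, 0)
    best_phi <- cand[[which.min(sses)]]
    best_sse <- min(sses)
  }
  X <- cbind(1, r, vapply(best_phi, function(p) pmax(0, r - p), numeric(k)))
  fit <- stats::lm.fit(X, z)
  cf <- fit$coefficients
  names(cf) <- c("alpha0", "beta0", paste0("beta", seq_len(g)))
  structure(list(g = g, breakpoints = unname(best_phi), coefficients = cf,
                 fitted = as.numeric(fit$fitted.values), sse = best_sse,
                 aic = k * log(max(best_sse, 1e-12) / k) + 2 * (2 + 2 * g),
                 k = k),
            class = "segfit")
}

#' @exportS3Method print segfit
print.segfit <- function(x, ...) {
  cat(sprintf("segmented fit: g = %d breakpoint(s) at rank %s; SSE = %.4g, AIC = %.2f\n",
              x$g, paste(x$breakpoints, collapse = ", "), x$sse, x$aic))
  invisible(x)
}

#' Select the segmented fit with minimal AIC
#'
#' Fits models with 1, 2 and 3 breakpoints (where `k >= 2g + 2` allows) and
#' returns the minimum-AIC fit, breaking ties toward fewer breakpoints.
#'
#' @inheritParams fit_segmented
#' @param max_g largest breakpoint count to try (default 3).
#' @return the winning `segfit`.
#' @export
select_fit <- function(z, r, max_g = 3) {
  k <- length(z)
  gs <- (1:max_g)[k >= 2 * (1:max_g) + 2]
  if (!length(gs)) stop("no g feasible: too few clusters (k = ", k, ")")
  fits <- lapply(gs, function(g) fit_segmented(z, r, g))
  fits[[which.min(vapply(fits, `[[`, 0, "aic"))]]
}

#' Split micro-clusters into low and high relevance groups
#'
#' Clusters ranking below the lowest breakpoint form the low-relevance
#' group `phi_low`; those above the highest breakpoint form `phi_high`.
#' Half-integer breakpoints make the boundary unambiguous and the groups
#' disjoint. An empty group marks the cell type degenerate (its threshold
#' will fall back to `+Inf`, i.e. no positive calls).
#'
#' @param fit a `segfit` from [fit_segmented()] or [select_fit()].
#' @param r rank vector the fit was computed on.
#' @return list with integer index sets `phi_low`, `phi_high` (positions in
#'   cluster-index order) and `degenerate` flag.
#' @export
relevance_groups <- function(fit, r) {
  stopifnot(inherits(fit, "segfit"))
  lo <- which(r <= fit$breakpoints[1])
  hi <- which(r >= fit$breakpoints[length(fit$breakpoints)])
  degenerate <- length(lo) == 0L || length(hi) == 0L
  list(phi_low = lo, phi_high = hi, degenerate = degenerate)
}

#' Misclassification-minimizing CTR threshold
#'
#' Given the CTR scores of the cells in the low-relevance clusters (`C_L`)
#' and high-relevance clusters (`C_H`), finds the threshold `theta`
#' minimizing `|{i in C_L : tau_i > theta}| + |{i in C_H : tau_i < theta}|`
#' over the candidate grid of midpoints between consecutive sorted unique
#' scores of `C_L + C_H`, plus one candidate below the minimum and one
#' above the maximum. The objective is a step function that only changes at
#' observed scores, so this grid provably contains a global minimizer.
#' Ties go to the smallest candidate.
#'
#' @param ctr_column numeric vector of per-cell scores for one type, named
#'   by cell ID (or indexable by the group cell indices).
#' @param groups a [relevance_groups()] result.
#' @param clusters micro-cluster assignment vector aligned with
#'   `ctr_column` (as in [microcluster()]`$assignment`).
#' @return list with `theta`, `objective` (verified minimum count) and
#'   `degenerate`.
#' @export
optimal_threshold <- function(ctr_column, groups, clusters) {
  if (groups$degenerate || !length(groups$phi_low) || !length(groups$phi_high)) {
    warning("degenerate relevance groups: threshold set to +Inf (no positive calls)")
    return(list(theta = Inf, objective = NA_integer_, degenerate = TRUE))
  }
  tau_L <- ctr_column[clusters %in% groups$phi_low]
  tau_H <- ctr_column[clusters %in% groups$phi_high]
  res <- threshold_scores(tau_L, tau_H)
  res
}

# core grid search on the two score sets; candidates are the observed
# unique scores and the midpoints between them (plus one below and one
# above), which exhausts the step function of the strict-inequality
# objective: a value occurring in both groups can be optimal exactly AT
# that value, so midpoints alone are not enough
threshold_scores <- function(tau_L, tau_H) {
  u <- sort(unique(c(tau_L, tau_H)))
  cand <- sort(c(u[1] - 1, u,
                 if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                 u[length(u)] + 1))
  sL <- sort(tau_L); sH <- sort(tau_H)
  obj <- (length(sL) - findInterval(cand, sL)) +          # #{L > theta}
    findInterval(cand, sH, left.open = TRUE)              # #{H < theta}
  i <- which.min(obj)                         # first minimum = smallest theta
  list(theta = cand[i], objective = as.integer(obj[i]),
       n_low = length(sL), n_high = length(sH), degenerate = FALSE)
}

#' Binarize CTR scores into a positivity matrix
#'
#' A cell is positive for a type when its score strictly exceeds the type's
#' threshold. A threshold of `+Inf` (degenerate type) yields no positives;
#' `-Inf` marks every cell positive.
#'
#' @param ctr CTR matrix from [compute_ctr()].
#' @param thresholds named numeric vector, one threshold per CTR column.
#' @return integer 0/1 matrix of the same shape as `ctr`.
#' @export
binarize <- function(ctr, thresholds) {
  if (is.list(thresholds)) thresholds <- unlist(thresholds)
  if (!all(colnames(ctr) %in% names(thresholds)))
    stop("need one threshold per cell type")
  th <- thresholds[colnames(ctr)]
  B <- matrix(0L, nrow(ctr), ncol(ctr), dimnames = dimnames(ctr))
  B[sweep(ctr, 2, th, ">")] <- 1L
  B
}
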