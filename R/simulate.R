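#' Simulate a spatial-omics dataset with known ground truth
#'
#' Generates a seeded synthetic cell-by-marker matrix, a matching signature
#' matrix and a truth table, emulating the failure modes the annotation
#' pipeline must survive: background noise, doublets (cells carrying two
#' types' signals, exercising mixed-cell deconvolution) and spillover
#' (a fraction of the nearest spatial neighbor's signal bleeding in,
#' mimicking imperfect segmentation).
#'
#' Intensity mode draws background values from `Normal(0, noise_sd)` and
#' shifts each cell's signature markers by `signal_shift * noise_sd *
#' weight`; the returned matrix is raw (`normalized = FALSE`) so the
#' pipeline's z-normalization applies. Counts mode draws Poisson counts
#' with a background rate and an elevated rate on signature markers, for
#' transcriptomics testing.
#'
#' @param n_cells number of cells.
#' @param cell_type_fractions named numeric vector summing to 1; rare types
#'   (< 1\%) are allowed. Cell counts use largest-remainder rounding so
#'   they sum exactly to `n_cells`.
#' @param n_markers total markers; defaults to
#'   `markers_per_type * n_types + 4` background markers.
#' @param markers_per_type unique signature markers per type (weight 1).
#' @param signal_shift mean shift on signature markers, in units of
#'   `noise_sd` (default 3).
#' @param noise_sd background standard deviation (default 1).
#' @param doublet_fraction fraction of cells given a second type's signal;
#'   exactly `round(doublet_fraction * n_cells)` cells.
#' @param spillover_rate fraction of the nearest spatial neighbor's signal
#'   added to each cell.
#' @param spatial_layout `"random"` uniform coordinates or `"clustered"`
#'   per-type Gaussian blobs.
#' @param mode `"intensity"` (Gaussian, proteomics) or `"counts"`
#'   (Poisson, transcriptomics).
#' @param field side length of the square tissue, image units.
#' @param seed integer; identical seeds give byte-identical output.
#' @return list with `features` (raw [feature_matrix()] with coordinates),
#'   `signatures` ([signature_matrix()]), `truth` (data frame: `cell_id`,
#'   `label`, `parent2` (second type of doublets, else `NA`),
#'   `is_doublet`), and `spec` (the resolved parameters).
#' @export
simulate_cells <- function(n_cells = 1000,
                           cell_type_fractions = c(A = 0.5, B = 0.3, C = 0.2),
                           n_markers = NULL,
                           markers_per_type = 2,
                           signal_shift = 3,
                           noise_sd = 1,
                           doublet_fraction = 0,
                           spillover_rate = 0,
                           spatial_layout = c("random", "clustered"),
                           mode = c("intensity", "counts"),
                           field = 1000,
                           seed = 1L) {
  spatial_layout <- match.arg(spatial_layout)
  mode <- match.arg(mode)
  if (abs(sum(cell_type_fractions) - 1) > 1e-8)
    stop("cell_type_fractions must sum to 1")
  if (doublet_fraction < 0 || doublet_fraction > 1 ||
      spillover_rate < 0 || spillover_rate > 1)
    stop("rates must lie in [0, 1]")
  types <- names(cell_type_fractions)
  if (is.null(types)) types <- paste0("Type", seq_along(cell_type_fractions))
  t_n <- length(types)
  need <- markers_per_type * t_n
  if (is.null(n_markers)) n_markers <- need + 4L
  if (n_markers < need)
    stop("n_markers too small for ", markers_per_type, " markers per type")
  set.seed(seed)

  # largest-remainder allocation of cells to types
  raw <- cell_type_fractions * n_cells
  cnt <- floor(raw)
  rem <- n_cells - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  label <- rep(types, cnt)

  markers <- sprintf("M%02d", seq_len(n_markers))
  sigw <- matrix(0, n_markers, t_n, dimnames = list(markers, types))
  for (j in seq_len(t_n))
    sigw[(j - 1) * markers_per_type + seq_len(markers_per_type), j] <- 1
  # background markers are intentionally in no signature
  sig <- suppressWarnings(signature_matrix(sigw))

  # doublets: a second type's full signature signal
  nd <- round(doublet_fraction * n_cells)
  parent2 <- rep(NA_character_, n_cells)
  if (nd > 0) {
    dbl <- sample.int(n_cells, nd)
    parent2[dbl] <- vapply(label[dbl], function(l)
      sample(setdiff(types, l), 1L), "")
  }

  # coordinates
  coords <- if (spatial_layout == "random") {
    cbind(x = stats::runif(n_cells, 0, field),
          y = stats::runif(n_cells, 0, field))
  } else {
    ctr <- cbind(stats::runif(t_n, 0.2, 0.8) * field,
                 stats::runif(t_n, 0.2, 0.8) * field)
    idx <- match(label, types)
    cbind(x = stats::rnorm(n_cells, ctr[idx, 1], field / 10),
          y = stats::rnorm(n_cells, ctr[idx, 2], field / 10))
  }

  shift <- signal_shift * noise_sd
  signal <- matrix(0, n_cells, n_markers, dimnames = list(NULL, markers))
  for (j in seq_len(t_n)) {
    rows <- label == types[j] |
      (!is.na(parent2) & parent2 == types[j])
    signal[rows, ] <- signal[rows, ] +
      rep(shift * sigw[, j], each = sum(rows))
  }
  if (spillover_rate > 0) {
    nn <- RANN::nn2(coords, k = 2)$nn.idx[, 2]
    signal <- signal + spillover_rate * signal[nn, , drop = FALSE]
  }

  values <- if (mode == "intensity") {
    signal + matrix(stats::rnorm(n_cells * n_markers, 0, noise_sd),
                    n_cells, n_markers)
  } else {
    lambda0 <- 0.2
    matrix(stats::rpois(n_cells * n_markers, lambda0 + signal),
           n_cells, n_markers)
  }
  ids <- sprintf("cell_%05d", seq_len(n_cells))
  dimnames(values) <- list(ids, markers)
  feats <- feature_matrix(values,
                          modality = if (mode == "intensity") "proteomics"
                                     else "transcriptomics",
                          coords = coords, normalized = FALSE)
  truth <- data.frame(cell_id = ids, label = label, parent2 = parent2,
                      is_doublet = !is.na(parent2), stringsAsFactors = FALSE)
  list(features = feats, signatures = sig, truth = truth,
       spec = list(n_cells = n_cells, cell_type_fractions = cell_type_fractions,
                   n_markers = n_markers, markers_per_type = markers_per_type,
                   signal_shift = signal_shift, noise_sd = noise_sd,
                   doublet_fraction = doublet_fraction,
                   spillover_rate = spillover_rate,
                   spatial_layout = spatial_layout, mode = mode,
                   field = field, seed = seed))
}
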