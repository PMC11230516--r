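#' Construct a cell-by-feature matrix
#'
#' The central data container of the package: an `n x m` matrix of per-cell
#' marker values (antibody intensities for proteomics, transcript counts for
#' transcriptomics) with unique cell identifiers as row names and unique
#' marker names as column names. Optional spatial centroids (`x`, `y` in
#' image units) travel with the matrix and are used by the neighborhood
#' module.
#'
#' @param values numeric matrix, cells in rows, markers in columns. Row and
#'   column names are required and must be unique.
#' @param modality one of `"proteomics"`, `"transcriptomics"`,
#'   `"multimodal"`. Raw transcriptomics values must be non-negative
#'   integers.
#' @param coords optional numeric matrix or data frame with one `(x, y)` row
#'   per cell.
#' @param normalized logical; `TRUE` once the matrix has been normalized
#'   (see [znormalize()] and [lognormalize()]).
#' @return an object of class `feature_matrix`: a list with elements
#'   `values`, `modality`, `coords`, `normalized`.
#' @seealso [read_features()], [znormalize()], [lognormalize()],
#'   [bind_modalities()]
#' @export
feature_matrix <- function(values,
                           modality = c("proteomics", "transcriptomics", "multimodal"),
                           coords = NULL,
                           normalized = FALSE) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("feature values must be numeric")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("feature matrix must have at least one cell and one marker")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature matrix requires cell IDs as row names and marker names as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate cell identifier: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate marker name: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature matrix contains missing or non-finite values")
  if (modality == "transcriptomics" && !normalized) {
    if (any(values < 0))
      stop("raw transcript counts must be non-negative")
    if (any(values != round(values)))
      stop("raw transcript counts must be integers")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != nrow(values) || ncol(coords) != 2L)
      stop("coords must have exactly one (x, y) row per cell")
    if (!is.numeric(coords) || anyNA(coords))
      stop("coords must be numeric and complete")
    rownames(coords) <- rownames(values)
    colnames(coords) <- c("x", "y")
  }
  structure(
    list(values = values, modality = modality, coords = coords,
         normalized = isTRUE(normalized)),
    class = "feature_matrix"
  )
}

#' @exportS3Method print feature_matrix
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d cells x %d markers (%s%s%s)\n",
              nrow(x$values), ncol(x$values), x$modality,
              if (x$normalized) ", normalized" else ", raw",
              if (!is.null(x$coords)) ", with coordinates" else ""))
  invisible(x)
}

#' @exportS3Method dim feature_matrix
dim.feature_matrix <- function(x) dim(x$values)

cell_ids <- function(mat) rownames(mat$values)
marker_names <- function(mat) colnames(mat$values)

#' Read a cell-by-feature table from disk
#'
#' Reads a delimited table (CSV/TSV; one row per cell, one column per
#' marker) or a MatrixMarket coordinate triplet of transcript counts with
#' sidecar row-name and column-name files.
#'
#' @param path path to the CSV/TSV file, or to the `.mtx` file for
#'   `format = "mtx"`.
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @param id_column name of the cell-identifier column (CSV/TSV only).
#' @param coord_columns optional character pair naming the x and y centroid
#'   columns; set to `NULL` when no coordinates are present.
#' @param modality forwarded to [feature_matrix()].
#' @param row_names,col_names for `format = "mtx"`: newline-delimited files
#'   holding the cell IDs (rows) and marker names (columns).
#' @return a raw (`normalized = FALSE`) [feature_matrix()]; row order is
#'   preserved from the file and markers are all non-ID, non-coordinate
#'   columns.
#' @export
read_features <- function(path, format = c("csv", "tsv", "mtx"),
                          id_column = "cell_id",
                          coord_columns = c("x", "y"),
                          modality = "proteomics",
                          row_names = NULL, col_names = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    if (is.null(row_names) || is.null(col_names))
      stop("mtx format requires row_names and col_names sidecar files")
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(row_names)
    cn <- readLines(col_names)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar name files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
    return(feature_matrix(m, modality = modality))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path)
  if (!id_column %in% names(df))
    stop("id column '", id_column, "' not found in ", path)
  ids <- as.character(df[[id_column]])
  if (anyDuplicated(ids))
    stop("duplicate cell identifier: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  coords <- NULL
  drop <- id_column
  if (!is.null(coord_columns) && all(coord_columns %in% names(df))) {
    coords <- as.matrix(df[coord_columns])
    drop <- c(drop, coord_columns)
  }
  mk <- setdiff(names(df), drop)
  if (!length(mk)) stop("no marker columns found in ", path)
  for (col in mk) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric marker value in column '", col, "', row ",
           if (length(bad)) bad else "?")
    }
  }
  m <- as.matrix(df[mk])
  rownames(m) <- ids
  feature_matrix(m, modality = modality, coords = coords)
}

#' Write a cell-by-feature matrix to CSV
#'
#' Inverse of [read_features()]: values round-trip at full precision.
#'
#' @param mat a [feature_matrix()].
#' @param path output CSV path.
#' @param id_column name used for the cell-ID column.
#' @export
write_features <- function(mat, path, id_column = "cell_id") {
  stopifnot(inherits(mat, "feature_matrix"))
  df <- data.frame(cell_ids(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- id_column
  if (!is.null(mat$coords)) {
    df$x <- mat$coords[, 1]
    df$y <- mat$coords[, 2]
  }
  vals <- as.data.frame(mat$values, check.names = FALSE)
  df <- cbind(df, vals)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Z-normalize a proteomics feature matrix
#'
#' Centers and scales every marker column to mean 0 and sample standard
#' deviation 1 (the `n - 1` denominator). Zero-variance markers are kept as
#' all-zero columns with a warning so downstream signature alignment never
#' silently loses a marker.
#'
#' @param mat a raw [feature_matrix()] of modality `"proteomics"` (or a
#'   proteomics block of a multimodal dataset).
#' @return the normalized `feature_matrix` (`normalized = TRUE`).
#' @export
znormalize <- function(mat) {
  stopifnot(inherits(mat, "feature_matrix"))
  if (mat$normalized) stop("matrix is already normalized")
  if (mat$modality == "transcriptomics")
    stop("znormalize applies to proteomics intensities; use lognormalize() for counts")
  v <- mat$values
  if (nrow(v) < 2L) stop("cannot z-normalize one observation")
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning("zero-variance marker(s) mapped to zero: ",
            paste(colnames(v)[flat], collapse = ", "))
    sdv[flat] <- 1
  }
  out <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
  out[, flat] <- 0
  feature_matrix(out, modality = mat$modality, coords = mat$coords,
                 normalized = TRUE)
}

#' Log-normalize a transcriptomics feature matrix
#'
#' Per cell: counts are divided by the cell's total count, multiplied by
#' `scale_factor`, then transformed with `log(1 + x)` (natural log). Cells
#' with zero total count become all-zero rows with a warning.
#'
#' @param mat a raw [feature_matrix()] of modality `"transcriptomics"`.
#' @param scale_factor positive library-size target (default 10,000).
#' @return the normalized `feature_matrix`.
#' @export
lognormalize <- function(mat, scale_factor = 1e4) {
  stopifnot(inherits(mat, "feature_matrix"))
  if (mat$normalized) stop("matrix is already normalized")
  if (mat$modality != "transcriptomics")
    stop("lognormalize applies to transcript counts")
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L || scale_factor <= 0)
    stop("scale_factor must be a positive number")
  v <- mat$values
  if (any(v < 0)) stop("negative counts are not allowed")
  tot <- rowSums(v)
  empty <- tot == 0
  if (any(empty)) {
    warning(sum(empty), " cell(s) with zero total count become all-zero rows")
    tot[empty] <- 1
  }
  out <- log1p(v / tot * scale_factor)
  feature_matrix(out, modality = mat$modality, coords = mat$coords,
                 normalized = TRUE)
}

#' Column-bind protein and transcript measurements of the same cells
#'
#' Both inputs must be normalized and share an identical cell-ID set (cells
#' are matched by ID, the protein row order wins). Colliding marker names
#' are disambiguated with `prot:`/`rna:` prefixes rather than merged:
#' protein and RNA measurements of the same gene are distinct features.
#'
#' @param proteo,transcripto normalized [feature_matrix()] objects.
#' @return a `feature_matrix` of modality `"multimodal"`.
#' @export
bind_modalities <- function(proteo, transcripto) {
  stopifnot(inherits(proteo, "feature_matrix"),
            inherits(transcripto, "feature_matrix"))
  if (!proteo$normalized || !transcripto$normalized)
    stop("both matrices must be normalized before binding")
  ap <- cell_ids(proteo); at <- cell_ids(transcripto)
  if (!setequal(ap, at)) {
    d <- c(setdiff(ap, at), setdiff(at, ap))
    stop("cell-ID sets differ; symmetric difference: ",
         paste(d, collapse = ", "))
  }
  vt <- transcripto$values[ap, , drop = FALSE]
  vp <- proteo$values
  shared <- intersect(colnames(vp), colnames(vt))
  if (length(shared)) {
    colnames(vp)[colnames(vp) %in% shared] <-
      paste0("prot:", colnames(vp)[colnames(vp) %in% shared])
    colnames(vt)[colnames(vt) %in% shared] <-
      paste0("rna:", colnames(vt)[colnames(vt) %in% shared])
  }
  coords <- if (!is.null(proteo$coords)) proteo$coords else transcripto$coords
  feature_matrix(cbind(vp, vt), modality = "multimodal", coords = coords,
                 normalized = TRUE)
}
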