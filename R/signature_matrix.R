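#' Construct a marker-by-cell-type signature matrix
#'
#' Encodes expert knowledge of which markers define each cell type. Entry
#' `s_ij` is either 0 (marker i is not a signature of type j) or a weight
#' `w` in `(0, 1]` expressing the marker's importance for that type
#' (`w = 1` when no grading is available).
#'
#' @param weights numeric matrix, markers in rows, cell types in columns,
#'   with row and column names.
#' @return an object of class `signature_matrix` (a validated matrix).
#' @export
signature_matrix <- function(weights) {
  weights <- as.matrix(weights)
  if (!is.numeric(weights)) stop("signature weights must be numeric")
  if (is.null(rownames(weights)) || is.null(colnames(weights)))
    stop("signature matrix requires marker row names and cell-type column names")
  if (anyDuplicated(colnames(weights)))
    stop("duplicate cell-type name")
  if (anyDuplicated(rownames(weights)))
    stop("duplicate marker name")
  if (anyNA(weights)) stop("signature matrix contains missing values")
  if (any(weights < 0 | weights > 1))
    stop("signature weights must be 0 or in (0, 1]")
  dead <- colSums(weights > 0) == 0
  if (any(dead))
    stop("cell type has no signature markers: ",
         paste(colnames(weights)[dead], collapse = ", "))
  idle <- rowSums(weights > 0) == 0
  if (any(idle))
    warning("marker(s) in no signature: ",
            paste(rownames(weights)[idle], collapse = ", "))
  structure(weights, class = c("signature_matrix", "matrix", "array"))
}

#' Read a signature matrix from CSV/TSV
#'
#' The first column holds marker names; the remaining numeric columns are
#' cell types. Blank or zero entries mean "not a signature marker".
#'
#' @param path file path.
#' @param sep field separator (`,` default; use `"\t"` for TSV).
#' @return a [signature_matrix()].
#' @export
read_signatures <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("signature file needs a marker column and at least one cell type")
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("signature entries must be numeric")
  m[is.na(m)] <- 0
  rownames(m) <- as.character(df[[1]])
  signature_matrix(m)
}

#' @exportS3Method print signature_matrix
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix: %d markers x %d cell types\n",
              nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

# markers with weight > 0 for any of the given types
signature_markers <- function(sig, types) {
  rownames(sig)[rowSums(sig[, types, drop = FALSE] > 0) > 0]
}
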