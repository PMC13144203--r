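# Count-matrix data model: the canonical representation of the observed data
# X (n documents/cells by m terms/genes) is a sparse non-negative integer
# matrix stored as a Matrix::dgCMatrix. Dense matrices are accepted as input
# views and converted; zeros are never stored explicitly.

#' Validate and coerce a count matrix
#'
#' Coerces a dense or sparse numeric matrix to the canonical sparse
#' representation used throughout the package, checking that all entries are
#' finite, non-negative and integer-valued (within a small tolerance for
#' values read from text files).
#'
#' @param X A numeric matrix or a sparse \code{Matrix} of counts, with rows
#'   indexing samples (documents, cells) and columns indexing features
#'   (terms, genes).
#' @param tol Tolerance for deviation from integer values; entries further
#'   than this from the nearest integer are an error.
#'
#' @return A \code{\link[Matrix]{dgCMatrix-class}} object with integral
#'   entries and no explicit zeros.
#'
#' @examples
#' X <- as_count_matrix(rbind(c(0, 2, 1), c(3, 0, 0)))
#' Matrix::rowSums(X)
#'
#' @importFrom methods as is
#' @importFrom Matrix drop0 rowSums colSums
#' @export
as_count_matrix <- function(X, tol = 1e-9) {
  if (is.data.frame(X))
    X <- as.matrix(X)
  if (is(X, "sparseMatrix"))
    X <- as(as(as(X, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  else if (is.matrix(X)) {
    storage.mode(X) <- "double"
    X <- as(as(as(X, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  } else
    stop("X must be a matrix, data frame or sparse Matrix")
  if (nrow(X) < 1 || ncol(X) < 1 || length(X@x) == 0)
    stop("count matrix is empty (no rows, no columns, or all zeros)")
  v <- X@x
  if (any(!is.finite(v)))
    stop("count matrix contains non-finite entries")
  if (any(v < 0)) {
    ij <- nonzero_coords(X)[which(v < 0)[1], ]
    stop(sprintf("negative entry at (%d, %d)", ij[1], ij[2]))
  }
  r <- round(v)
  if (any(abs(v - r) > tol)) {
    bad <- which(abs(v - r) > tol)[1]
    ij <- nonzero_coords(X)[bad, ]
    stop(sprintf("non-integer entry %g at (%d, %d)", v[bad], ij[1], ij[2]))
  }
  X@x <- r
  drop0(X)
}

# Row/column coordinates (1-based) of the stored nonzeros of a dgCMatrix, in
# storage (column-major) order.
nonzero_coords <- function(X) {
  Xt <- as(X, "TsparseMatrix")
  cbind(i = Xt@i + 1L, j = Xt@j + 1L)
}

# Triplet view (i, j, x) of a count matrix, used by the solvers so that all
# per-entry work scales with nnz(X).
count_triplets <- function(X) {
  Xt <- as(X, "TsparseMatrix")
  list(i = Xt@i + 1L, j = Xt@j + 1L, x = Xt@x,
       n = nrow(X), m = ncol(X))
}

#' Read a count matrix from a file
#'
#' Reads a sparse MatrixMarket coordinate file or a dense CSV table into the
#' canonical sparse count-matrix representation. Real-valued entries are
#' accepted only if they are within \code{1e-9} of an integer.
#'
#' @param path Path to the file.
#' @param format One of \code{"auto"} (decide from the file extension),
#'   \code{"matrixmarket"} or \code{"csv"}. CSV files may have a single
#'   header line and an optional leading row-name column; both are
#'   auto-detected.
#'
#' @return A sparse count matrix (see \code{\link{as_count_matrix}}).
#'
#' @seealso \code{\link{write_count_matrix}}, \code{\link{validate_counts}}
#'
#' @importFrom Matrix readMM
#' @importFrom utils read.csv
#' @export
read_count_matrix <- function(path, format = c("auto", "matrixmarket", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE))
      "matrixmarket" else "csv"
  if (format == "matrixmarket") {
    X <- readMM(path)
    return(as_count_matrix(X))
  }
  first <- readLines(path, n = 1)
  fields <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  tab <- read.csv(path, header = has_header, check.names = FALSE)
  # drop a leading row-name column if it is non-numeric
  if (ncol(tab) > 1 && !is.numeric(tab[[1]]))
    tab <- tab[, -1, drop = FALSE]
  X <- as.matrix(tab)
  if (!is.numeric(X))
    stop("CSV file does not contain a numeric table")
  as_count_matrix(X)
}

#' Write a count matrix to a file
#'
#' @param X A count matrix (dense or sparse; validated first).
#' @param path Output file path.
#' @param format \code{"auto"}, \code{"matrixmarket"} or \code{"csv"} as in
#'   \code{\link{read_count_matrix}}.
#'
#' @return Invisibly, the path written.
#'
#' @importFrom Matrix writeMM
#' @importFrom utils write.table
#' @export
write_count_matrix <- function(X, path,
                               format = c("auto", "matrixmarket", "csv")) {
  format <- match.arg(format)
  X <- as_count_matrix(X)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE))
      "matrixmarket" else "csv"
  if (format == "matrixmarket")
    writeMM(X, path)
  else
    write.table(as.matrix(X), path, sep = ",", row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Report degenerate rows and columns of a count matrix
#'
#' All-zero rows (documents with no counts, t_i = 0) and all-zero columns
#' make parts of the model unidentifiable; the fitting functions refuse such
#' input, and this helper reports which rows/columns to filter.
#'
#' @param X A count matrix.
#'
#' @return A character vector of warnings, empty when the matrix has no
#'   all-zero rows or columns.
#'
#' @examples
#' X <- as_count_matrix(rbind(c(3, 0), c(0, 0), c(2, 0)))
#' validate_counts(X)
#'
#' @export
validate_counts <- function(X) {
  X <- as_count_matrix(X)
  out <- character(0)
  zr <- which(Matrix::rowSums(X) == 0)
  zc <- which(Matrix::colSums(X) == 0)
  if (length(zr) > 0)
    out <- c(out, sprintf("all-zero row %d (t_i = 0)", zr))
  if (length(zc) > 0)
    out <- c(out, sprintf("all-zero column %d", zc))
  out
}

# Stop unless X has no all-zero rows or columns (fitting precondition).
require_positive_margins <- function(X) {
  w <- validate_counts(X)
  if (length(w) > 0)
    stop("count matrix has degenerate margins; filter these first:\n  ",
         paste(w, collapse = "\n  "))
  invisible(X)
}
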