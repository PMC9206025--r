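#' Read a cell-by-gene expression matrix
#'
#' Reads a normalized expression matrix from either a dense CSV (header row of
#' gene names, first column of cell barcodes) or a MatrixMarket `.mtx` triplet
#' file with sidecar `genes.tsv` / `barcodes.tsv` id files. The returned matrix
#' always has cells as rows and genes as columns. Matrices stored genes-by-cells
#' on disk (the common 10x convention for `.mtx`) are transposed automatically
#' when the stored row count matches the number of gene ids.
#'
#' @param path Path to the CSV or MatrixMarket file.
#' @param format Either `"csv"` or `"mtx"`.
#' @param genes_file,barcodes_file Sidecar id files for `format = "mtx"`.
#'   Default to `genes.tsv` and `barcodes.tsv` next to `path`.
#' @param sparse For `"mtx"`, return a `Matrix::sparseMatrix` instead of a
#'   dense matrix. All downstream functions accept either.
#' @return A numeric matrix (cells x genes) with unique row and column names.
#' @examples
#' sim <- simulate_cells(n_cells = 20, n_genes = 10, n_clusters = 2,
#'                       n_informative = 4, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_expression(sim$matrix, f, format = "csv")
#' m <- read_expression(f, format = "csv")
#' dim(m)
#' @export
read_expression <- function(path, format = c("csv", "mtx"),
                            genes_file = NULL, barcodes_file = NULL,
                            sparse = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("malformed header: expected a cell-id column and at least 2 genes")
    cells <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("malformed header: non-numeric expression values")
    rownames(m) <- cells
    genes <- colnames(m)
    if (is.null(genes) || any(!nzchar(genes)))
      stop("malformed header: missing gene names")
  } else {
    dir <- dirname(path)
    if (is.null(genes_file)) genes_file <- file.path(dir, "genes.tsv")
    if (is.null(barcodes_file)) barcodes_file <- file.path(dir, "barcodes.tsv")
    if (!file.exists(genes_file)) stop("missing companion gene id file: ", genes_file)
    if (!file.exists(barcodes_file)) stop("missing companion barcode file: ", barcodes_file)
    mm <- Matrix::readMM(path)
    genes <- readLines(genes_file)
    genes <- genes[nzchar(genes)]
    # keep only the first tab-separated field (10x gene files carry id + symbol)
    genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[[`, "", 1L)
    cells <- readLines(barcodes_file)
    cells <- cells[nzchar(cells)]
    if (nrow(mm) == length(genes) && ncol(mm) == length(cells)) {
      mm <- Matrix::t(mm)            # stored genes x cells
    } else if (!(nrow(mm) == length(cells) && ncol(mm) == length(genes))) {
      stop("dimension mismatch between matrix (", nrow(mm), " x ", ncol(mm),
           ") and id files (", length(cells), " cells, ", length(genes), " genes)")
    }
    m <- if (sparse) methods::as(mm, "CsparseMatrix") else as.matrix(mm)
    rownames(m) <- cells
    colnames(m) <- genes
  }
  validate_expression(m)
  m
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; used for round-tripping and exporting.
#'
#' @param m Cells x genes matrix with row and column names.
#' @param path Output file path. For `"mtx"`, `genes.tsv` and `barcodes.tsv`
#'   are written next to it.
#' @param format `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(cell = rownames(m), as.matrix(m), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    dir <- dirname(path)
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    writeLines(colnames(m), file.path(dir, "genes.tsv"))
    writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

#' @keywords internal
validate_expression <- function(m) {
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("expression matrix must have at least 2 cells and 2 genes")
  v <- if (methods::is(m, "sparseMatrix")) m@x else m
  if (anyNA(v) || any(!is.finite(v))) stop("expression matrix contains missing or non-finite values")
  if (any(v < 0)) stop("negative expression values are not allowed")
  if (anyDuplicated(rownames(m))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(m))) stop("duplicate gene ids")
  # crude raw-count signal: per-cell totals spanning more than one order of
  # magnitude suggests library sizes were never normalized
  tot <- Matrix::rowSums(m)
  tot <- tot[tot > 0]
  if (length(tot) && max(tot) > 10 * min(tot))
    warning("per-cell totals vary by more than 10x; input may be un-normalized counts",
            call. = FALSE)
  invisible(m)
}

#' Conditional log transform
#'
#' Applies `log2(x + 1)` entry-wise when the dynamic range of the matrix
#' (max - min) exceeds 100, and returns the matrix unchanged otherwise. This
#' mirrors the standard preprocessing used before min-max scaling: data already
#' on a compressed scale are left alone.
#'
#' @param m Non-negative cells x genes matrix.
#' @return Matrix of the same shape (dense).
#' @export
conditional_log2 <- function(m) {
  m <- as.matrix(m)
  rng <- range(m)
  if (rng[2L] - rng[1L] > 100) log2(m + 1) else m
}

#' Row-wise min-max scaling
#'
#' Rescales each cell (row) linearly to `[0, 1]`:
#' `X_ij = (M_ij - min(M_i.)) / (max(M_i.) - min(M_i.))`.
#' Rows with constant input (max = min) map to all zeros, preserving the range
#' contract for degenerate cells.
#'
#' @param m Non-negative cells x genes matrix.
#' @return Dense matrix with every entry in `[0, 1]`; non-constant rows attain
#'   both 0 and 1.
#' @export
minmax_scale <- function(m) {
  m <- as.matrix(m)
  lo <- apply(m, 1L, min)
  hi <- apply(m, 1L, max)
  span <- hi - lo
  const <- span <= 0
  span[const] <- 1
  x <- (m - lo) / span
  if (any(const)) x[const, ] <- 0
  x
}
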