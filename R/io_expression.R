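#' Read a gene-by-cell count matrix (Matrix Market + sidecars)
#'
#' @param mtx_path Matrix Market coordinate file (genes x cells).
#' @param features_path TSV of features, one row per gene; the second column
#'   is taken as the gene symbol when present (10x convention), else the
#'   first. Duplicate symbols are disambiguated deterministically in file
#'   order (`X`, `X.1`, `X.2`, ...).
#' @param barcodes_path TSV of cell barcodes, one per row.
#'
#' @return An object of class `expression_matrix`: a list with `counts`
#'   (sparse `dgCMatrix`, genes x cells, dimnames set) and `normalized`
#'   (`NULL` until [log_normalize()] is applied).
#' @export
read_expression_matrix <- function(mtx_path, features_path, barcodes_path) {
  for (p in c(mtx_path, features_path, barcodes_path)) {
    if (!file.exists(p)) stop_format("file not found: ", p)
  }
  counts <- as(Matrix::readMM(mtx_path), "CsparseMatrix")
  feats <- read.delim(features_path, header = FALSE,
                      colClasses = "character")
  genes <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  barcodes <- read.delim(barcodes_path, header = FALSE,
                         colClasses = "character")[[1]]
  if (nrow(counts) != length(genes)) {
    stop_format("feature sidecar has ", length(genes), " rows but matrix ",
                "declares ", nrow(counts), " genes")
  }
  if (ncol(counts) != length(barcodes)) {
    stop_format("barcode sidecar has ", length(barcodes), " rows but matrix ",
                "declares ", ncol(counts), " cells")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop_format("counts must be nonnegative integers")
  }
  dimnames(counts) <- list(make.unique(genes, sep = "."), barcodes)
  new_expression_matrix(counts)
}

new_expression_matrix <- function(counts, normalized = NULL) {
  structure(list(counts = counts, normalized = normalized),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells; normalized layer: ",
      if (is.null(x$normalized)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Write an expression matrix as Matrix Market + sidecars
#'
#' Inverse of [read_expression_matrix()].
#'
#' @param expr An `expression_matrix`.
#' @param dir Output directory (created if needed). Writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return The directory path, invisibly.
#' @export
write_expression_matrix <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(expr$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(expr$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(expr$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
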