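#' QC thresholds
#'
#' Low-quality cells are defined by a mitochondrial-fraction ceiling and a
#' detected-genes floor. Both bounds are strict: a cell at exactly the
#' mitochondrial ceiling, or with exactly `min_genes` genes, is kept.
#'
#' @param max_mito_fraction Cells with `mito_fraction > max_mito_fraction`
#'   are removed (default 0.10).
#' @param min_genes Cells with `n_genes < min_genes` are removed (default 200).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.10, min_genes = 200L) {
  if (!(max_mito_fraction > 0 && max_mito_fraction < 1)) {
    stop_validation("max_mito_fraction must lie strictly between 0 and 1")
  }
  if (min_genes < 0) stop_validation("min_genes must be >= 0")
  structure(list(max_mito_fraction = max_mito_fraction,
                 min_genes = as.integer(min_genes)),
            class = "qc_thresholds")
}

#' Apply cell-level QC
#'
#' Partitions cells into kept and removed sets. A cell is removed iff its
#' mitochondrial fraction exceeds the ceiling or its detected-gene count
#' falls below the floor (both strictly).
#'
#' @param cells Cell-record data frame (needs `mito_fraction`, `n_genes`).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with elements `kept` and `removed`, each a data frame;
#'   their union is the input, disjoint.
#' @export
apply_cell_qc <- function(cells, thresholds = qc_thresholds()) {
  missing_qc <- is.na(cells$mito_fraction) | is.na(cells$n_genes)
  if (any(missing_qc)) {
    stop_validation("cells with missing QC fields: ",
                    paste(head(cells$barcode[missing_qc], 10), collapse = ", "))
  }
  removed <- cells$mito_fraction > thresholds$max_mito_fraction |
    cells$n_genes < thresholds$min_genes
  list(kept = cells[!removed, , drop = FALSE],
       removed = cells[removed, , drop = FALSE])
}

#' Library-size log-normalisation
#'
#' Sets `normalized[g, c] = ln(1 + scale * counts[g, c] / total_counts[c])`.
#' Cells with zero total counts get an all-zero normalized column and a
#' warning.
#'
#' @param expr An `expression_matrix`.
#' @param scale Target library size (default `1e4`).
#' @return The `expression_matrix` with its `normalized` layer filled in.
#' @export
log_normalize <- function(expr, scale = 1e4) {
  stopifnot(scale > 0)
  totals <- Matrix::colSums(expr$counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts; normalized values set to 0")
  }
  fac <- ifelse(zero, 0, scale / totals)
  norm <- expr$counts %*% Matrix::Diagonal(x = fac)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(expr$counts)
  expr$normalized <- as(norm, "CsparseMatrix")
  expr
}

#' Gene-set signature score per cell
#'
#' The score of a cell is the mean normalized expression over the signature's
#' genes present in the matrix; absent genes are dropped (their count is
#' messaged).
#'
#' @param expr A normalised `expression_matrix`.
#' @param gene_set Character vector of gene symbols.
#' @param name Signature name carried into the output.
#' @return Data frame with columns `barcode`, `signature_name`, `score`.
#' @export
score_signature <- function(expr, gene_set, name) {
  if (is.null(expr$normalized)) {
    stop_validation("normalized layer missing; run log_normalize() first")
  }
  present <- intersect(gene_set, rownames(expr$normalized))
  if (length(present) == 0) {
    stop_validation("signature '", name, "': no gene of the set is present ",
                    "in the matrix")
  }
  n_dropped <- length(setdiff(gene_set, present))
  if (n_dropped > 0) {
    message("signature '", name, "': ", n_dropped, " gene(s) absent from the ",
            "matrix dropped")
  }
  scores <- Matrix::colMeans(expr$normalized[present, , drop = FALSE])
  data.frame(barcode = colnames(expr$normalized), signature_name = name,
             score = as.numeric(scores), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read signature definitions from TSV
#'
#' @param path TSV with columns `signature_name`, `gene_symbol`.
#' @return Named list of character vectors.
#' @export
read_signatures <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("signature_name", "gene_symbol") %in% names(tab))) {
    stop_format("signature file needs columns signature_name, gene_symbol")
  }
  split(tab$gene_symbol, tab$signature_name)
}

#' Per-gene differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test on normalized values per gene, with a
#' Benjamini-Hochberg adjusted FDR over the genes of the contrast. The log
#' fold change is the ln-scale difference of group means of normalized
#' values. A gene with identical values in every cell gets `p = 1` and
#' `log_fold_change = 0` by convention.
#'
#' @param expr A normalised `expression_matrix`.
#' @param group_a_barcodes,group_b_barcodes Disjoint barcode vectors, each of
#'   at least 3 cells.
#' @return Data frame with columns `gene`, `log_fold_change`, `p_value`,
#'   `fdr`, ordered as the matrix genes.
#' @export
differential_expression <- function(expr, group_a_barcodes, group_b_barcodes) {
  if (is.null(expr$normalized)) {
    stop_validation("normalized layer missing; run log_normalize() first")
  }
  if (length(intersect(group_a_barcodes, group_b_barcodes)) > 0) {
    stop_validation("groups overlap")
  }
  if (length(group_a_barcodes) < 3 || length(group_b_barcodes) < 3) {
    stop_validation("both groups need at least 3 cells")
  }
  a <- as.matrix(expr$normalized[, group_a_barcodes, drop = FALSE])
  b <- as.matrix(expr$normalized[, group_b_barcodes, drop = FALSE])
  genes <- rownames(a)
  p <- numeric(length(genes))
  lfc <- numeric(length(genes))
  for (i in seq_along(genes)) {
    xa <- a[i, ]
    xb <- b[i, ]
    lfc[i] <- mean(xa) - mean(xb)
    vals <- c(xa, xb)
    if (all(vals == vals[[1]])) {
      p[i] <- 1
    } else {
      p[i] <- suppressWarnings(
        wilcox.test(xa, xb, alternative = "two.sided", exact = FALSE)$p.value)
      if (is.na(p[i])) p[i] <- 1
    }
  }
  data.frame(gene = genes, log_fold_change = lfc, p_value = p,
             fdr = p.adjust(p, method = "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Subject-level composition statistics
#'
#' Compares per-subject cell-type proportions between two groups with a
#' two-sided Wilcoxon rank-sum test per cell type and Benjamini-Hochberg
#' correction across the cell types of the family. `n` refers to subjects,
#' never to cells.
#'
#' @param proportions Numeric matrix (subjects x cell types, rownames =
#'   subject ids); every row must sum to 1 over the cell types considered
#'   (tolerance 1e-9).
#' @param groups Named character/factor vector mapping subject id to group;
#'   exactly two groups, each with at least 2 subjects.
#' @return Data frame with columns `cell_type`, `p_value`, `fdr`.
#' @export
composition_stats <- function(proportions, groups) {
  proportions <- as.matrix(proportions)
  row_sums <- rowSums(proportions)
  if (any(abs(row_sums - 1) > 1e-9)) {
    stop_validation("per-subject proportions must sum to 1 over the cell ",
                    "types considered")
  }
  groups <- groups[rownames(proportions)]
  lev <- unique(as.character(groups))
  if (length(lev) != 2) stop_validation("exactly two groups required")
  if (any(table(groups) < 2)) {
    stop_validation("each group needs at least 2 subjects")
  }
  in_a <- groups == lev[[1]]
  p <- vapply(colnames(proportions), function(ct) {
    xa <- proportions[in_a, ct]
    xb <- proportions[!in_a, ct]
    if (all(c(xa, xb) == c(xa, xb)[[1]])) return(1)
    pv <- suppressWarnings(
      wilcox.test(xa, xb, alternative = "two.sided", exact = FALSE)$p.value)
    if (is.na(pv)) 1 else pv
  }, numeric(1))
  data.frame(cell_type = colnames(proportions), p_value = unname(p),
             fdr = p.adjust(p, method = "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pearson correlation between two cell-type proportion vectors
#'
#' @param type_a,type_b Per-subject proportion vectors of equal length.
#' @return A list with `r` (Pearson correlation) and `p` (two-sided p-value).
#' @export
correlate_proportions <- function(type_a, type_b) {
  ct <- cor.test(type_a, type_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
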