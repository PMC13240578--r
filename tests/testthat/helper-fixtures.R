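# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

# Minimal cell-record data frame.
make_cells <- function(barcode, subject_id = "S1", compartment = "LUNG",
                       group = "PNEUMONIA", cluster = "T8_rm",
                       mito_fraction = 0.05, n_genes = 1000L) {
  data.frame(barcode = barcode,
             subject_id = rep_len(subject_id, length(barcode)),
             compartment = rep_len(compartment, length(barcode)),
             group = rep_len(group, length(barcode)),
             cluster = rep_len(cluster, length(barcode)),
             mito_fraction = rep_len(mito_fraction, length(barcode)),
             n_genes = rep_len(n_genes, length(barcode)),
             stringsAsFactors = FALSE)
}

# Canonical contig row(s).
make_contigs <- function(barcode, chain = "TRB", v_gene = "TRBV7",
                         j_gene = "TRBJ2-1", cdr3_nt = "TGTGCCAGC",
                         cdr3_aa = "CAS", productive = TRUE, umis = 5L,
                         c_gene = "", raw_clonotype_id = "clonotype1") {
  n <- max(length(barcode), length(chain), length(cdr3_nt))
  data.frame(barcode = rep_len(barcode, n), chain = rep_len(chain, n),
             v_gene = rep_len(v_gene, n), j_gene = rep_len(j_gene, n),
             cdr3_nt = rep_len(cdr3_nt, n), cdr3_aa = rep_len(cdr3_aa, n),
             productive = rep_len(productive, n), umis = rep_len(umis, n),
             c_gene = rep_len(c_gene, n),
             raw_clonotype_id = rep_len(raw_clonotype_id, n),
             stringsAsFactors = FALSE)
}

# Small dense expression_matrix with a normalized layer.
make_expr <- function(counts, genes = NULL, barcodes = NULL, normalize = TRUE) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(counts)))
  if (is.null(barcodes)) barcodes <- sprintf("BC%03d", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, barcodes)
  expr <- clonoshare:::new_expression_matrix(
    as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"))
  if (normalize) expr <- log_normalize(expr) else expr
}

# Random clone table: n_clones clones with random sizes spread over random
# compartments and clusters within one or more subjects.
random_clone_table <- function(n_clones, n_subjects = 1,
                               clusters = c("T8_rm", "Cycling", "T8_eff"),
                               max_size = 6) {
  rows <- list()
  for (s in seq_len(n_subjects)) {
    subj <- paste0("S", s)
    for (i in seq_len(n_clones)) {
      size <- sample.int(max_size, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        barcode = sprintf("%s_c%d_%d", subj, i, seq_len(size)),
        subject_id = subj,
        clone_id = sprintf("%s:clone%03d", subj, i),
        compartment = sample(c("LUNG", "BALF", "PBMC"), size, replace = TRUE),
        cluster = sample(clusters, size, replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  assignments <- data.frame(barcode = cells$barcode,
                            subject_id = cells$subject_id,
                            clone_id = cells$clone_id,
                            receptor_type = "TCR", isotype = NA_character_,
                            stringsAsFactors = FALSE)
  meta <- make_cells(cells$barcode, subject_id = cells$subject_id,
                     compartment = cells$compartment, cluster = cells$cluster)
  build_clone_table(assignments, meta)
}

# Well-separated program set for the reference-scoring recovery checks
# (marker log2-fold effects of 3, i.e. 8-fold shifts).
separated_programs <- function(effect = 3) {
  list(P1A = c(ITGAE = effect, CXCR6 = effect, CXCR3 = effect,
               GZMB = effect, GNLY = effect, MKI67 = effect),
       P1B = c(ITGAE = effect, CXCR6 = effect),
       P2 = c(CX3CR1 = effect, FGFBP2 = effect, KLRG1 = effect),
       OTHER = c())
}
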