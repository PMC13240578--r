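#' Read a receptor contig table
#'
#' Parses per-chain receptor contigs from either a 10x Genomics
#' `filtered_contig_annotations.csv` or an AIRR Rearrangement TSV into a
#' canonical contig data frame with one receptor chain per row.
#'
#' @param path Path to the contig file.
#' @param dialect `"TENX_CSV"` (10x CSV) or `"AIRR_TSV"` (AIRR Rearrangement).
#'
#' @return A data frame with columns `barcode`, `chain`, `v_gene`, `j_gene`,
#'   `cdr3_nt`, `cdr3_aa`, `productive` (logical), `umis` (integer),
#'   `c_gene`, and `raw_clonotype_id` (`NA` when the dialect carries none).
#'   Unknown columns in the input are ignored.
#'
#' @details Mandatory columns are, for the 10x dialect: `barcode`, `chain`,
#'   `v_gene`, `j_gene`, `cdr3`, `cdr3_nt`, `productive`, `umis`, `c_gene`,
#'   `raw_clonotype_id`; for AIRR: `cell_id`, `locus`, `v_call`, `j_call`,
#'   `junction`, `junction_aa`, `productive`, `consensus_count`, `c_call`.
#'   `productive` is parsed from `"True"`/`"true"`/`"T"` (10x) or
#'   `"T"`/`"TRUE"` (AIRR); anything else is non-productive.
#'
#' @seealso [collapse_to_clonotypes()], [write_contig_table()]
#' @export
read_contig_table <- function(path, dialect = c("TENX_CSV", "AIRR_TSV")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format("contig file not found: ", path)
  mandatory <- switch(dialect,
    TENX_CSV = c("barcode", "chain", "v_gene", "j_gene", "cdr3", "cdr3_nt",
                 "productive", "umis", "c_gene", "raw_clonotype_id"),
    AIRR_TSV = c("cell_id", "locus", "v_call", "j_call", "junction",
                 "junction_aa", "productive", "consensus_count", "c_call"))
  raw <- if (dialect == "TENX_CSV") {
    read.csv(path, colClasses = "character", check.names = FALSE)
  } else {
    read.delim(path, colClasses = "character", check.names = FALSE)
  }
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop_format("contig file ", path, " (", dialect, ") is missing mandatory ",
                "column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) stop_format("contig file ", path, " has no data rows")

  if (dialect == "TENX_CSV") {
    out <- data.frame(
      barcode = raw$barcode,
      chain = raw$chain,
      v_gene = raw$v_gene,
      j_gene = raw$j_gene,
      cdr3_nt = raw$cdr3_nt,
      cdr3_aa = raw$cdr3,
      productive = raw$productive %in% c("True", "true", "T"),
      umis = as.integer(raw$umis),
      c_gene = raw$c_gene,
      raw_clonotype_id = raw$raw_clonotype_id,
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      barcode = raw$cell_id,
      chain = raw$locus,
      v_gene = raw$v_call,
      j_gene = raw$j_call,
      cdr3_nt = raw$junction,
      cdr3_aa = raw$junction_aa,
      productive = raw$productive %in% c("T", "TRUE"),
      umis = as.integer(raw$consensus_count),
      c_gene = raw$c_call,
      raw_clonotype_id = if ("clone_id" %in% names(raw)) raw$clone_id
                         else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (any(is.na(out$umis)) || any(out$umis < 0)) {
    stop_format("contig file ", path, ": UMI counts must be nonnegative integers")
  }
  bad_nt <- out$productive & (is.na(out$cdr3_nt) | out$cdr3_nt == "")
  if (any(bad_nt)) {
    stop_format("contig file ", path, ": ", sum(bad_nt),
                " productive contig(s) with empty nucleotide CDR3")
  }
  out
}

#' Write a contig table
#'
#' Inverse of [read_contig_table()]; serialises a canonical contig data frame
#' in either supported dialect so that read(write(x)) is the identity.
#'
#' @param contigs Canonical contig data frame.
#' @param path Output path.
#' @param dialect `"TENX_CSV"` or `"AIRR_TSV"`.
#' @return `path`, invisibly.
#' @export
write_contig_table <- function(contigs, path, dialect = c("TENX_CSV", "AIRR_TSV")) {
  dialect <- match.arg(dialect)
  if (dialect == "TENX_CSV") {
    out <- data.frame(
      barcode = contigs$barcode,
      chain = contigs$chain,
      v_gene = contigs$v_gene,
      j_gene = contigs$j_gene,
      cdr3 = contigs$cdr3_aa,
      cdr3_nt = contigs$cdr3_nt,
      productive = ifelse(contigs$productive, "True", "False"),
      umis = contigs$umis,
      c_gene = contigs$c_gene,
      raw_clonotype_id = ifelse(is.na(contigs$raw_clonotype_id), "",
                                contigs$raw_clonotype_id),
      stringsAsFactors = FALSE)
    write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(
      cell_id = contigs$barcode,
      locus = contigs$chain,
      v_call = contigs$v_gene,
      j_call = contigs$j_gene,
      junction = contigs$cdr3_nt,
      junction_aa = contigs$cdr3_aa,
      productive = ifelse(contigs$productive, "T", "F"),
      consensus_count = contigs$umis,
      c_call = contigs$c_gene,
      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read the cell metadata table
#'
#' @param path TSV with required columns `barcode`, `subject_id`,
#'   `compartment` (LUNG/BALF/PBMC), `group` (PNEUMONIA/CONTROL), `cluster`,
#'   `mito_fraction`, `n_genes`.
#' @return A validated data frame of cell records.
#' @export
read_cell_metadata <- function(path) {
  if (!file.exists(path)) stop_format("metadata file not found: ", path)
  required <- c("barcode", "subject_id", "compartment", "group", "cluster",
                "mito_fraction", "n_genes")
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_format("metadata file ", path, " is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  validate_cells(raw[required])
}

#' Validate a cell-record data frame
#'
#' Checks compartment/group levels, QC-field ranges and uniqueness of the
#' (subject, barcode) pair.
#'
#' @param cells Data frame of cell records.
#' @return The validated (possibly re-typed) data frame.
#' @export
validate_cells <- function(cells) {
  cells$compartment <- match_enum(cells$compartment, COMPARTMENTS, "compartment")
  cells$group <- match_enum(cells$group, GROUPS, "group")
  if (anyNA(cells$compartment) || anyNA(cells$group)) {
    stop_validation("compartment and group must be non-missing")
  }
  key <- paste(cells$subject_id, cells$barcode)
  if (anyDuplicated(key)) {
    stop_validation("duplicated (subject_id, barcode) pair(s): ",
                    paste(head(unique(key[duplicated(key)]), 5), collapse = ", "))
  }
  cells$mito_fraction <- as.numeric(cells$mito_fraction)
  cells$n_genes <- as.integer(cells$n_genes)
  if (any(!is.na(cells$mito_fraction) &
          (cells$mito_fraction < 0 | cells$mito_fraction > 1))) {
    stop_validation("mito_fraction must lie in [0, 1]")
  }
  cells
}

#' Collapse receptor chains into subject-scoped clonotypes
#'
#' Per barcode, builds a clone key from its productive chains only; keys are
#' prefixed with the subject id so a clone id can never span two subjects
#' (public clones are deliberately out of reach). Barcodes with more than two
#' productive chains of one locus keep the two with the most UMIs. Barcodes
#' with no productive chain receive no assignment.
#'
#' @param contigs Contig data frame from [read_contig_table()].
#' @param cells Cell metadata (provides the subject of each barcode); contigs
#'   whose barcode is absent are dropped with a message.
#' @param policy Clone-identity policy: `"NT_VJ"` (default; sorted set of
#'   (chain, V, J, nucleotide CDR3) tuples), `"AA_VJ"` (amino-acid CDR3), or
#'   `"RAW_ID"` (the vendor clonotype id).
#'
#' @return Data frame with columns `barcode`, `subject_id`, `clone_id`,
#'   `receptor_type` (`"TCR"`/`"BCR"`), `isotype` (heavy-chain constant gene
#'   for BCR; `NA` otherwise).
#' @export
collapse_to_clonotypes <- function(contigs, cells,
                                   policy = c("NT_VJ", "AA_VJ", "RAW_ID")) {
  policy <- match.arg(policy)
  subj_of <- cells$subject_id[!duplicated(cells$barcode)]
  names(subj_of) <- cells$barcode[!duplicated(cells$barcode)]
  multi <- tapply(cells$subject_id, cells$barcode,
                  function(s) length(unique(s)))
  if (any(multi > 1)) {
    stop_integrity("barcode(s) mapped to more than one subject: ",
                   paste(head(names(multi)[multi > 1], 5), collapse = ", "))
  }

  known <- contigs$barcode %in% names(subj_of)
  n_dropped <- sum(!known)
  if (n_dropped > 0) {
    message(n_dropped, " contig(s) with barcodes absent from the cell table dropped")
  }
  contigs <- contigs[known & contigs$productive, , drop = FALSE]
  if (nrow(contigs) == 0) {
    return(data.frame(barcode = character(), subject_id = character(),
                      clone_id = character(), receptor_type = character(),
                      isotype = character(), stringsAsFactors = FALSE))
  }

  # doublet-chain rule: keep the two highest-UMI productive chains per locus
  ord <- order(contigs$barcode, contigs$chain, -contigs$umis,
               contigs$cdr3_nt, contigs$cdr3_aa, contigs$v_gene, contigs$j_gene)
  contigs <- contigs[ord, , drop = FALSE]
  within_locus <- stats::ave(seq_len(nrow(contigs)),
                             paste(contigs$barcode, contigs$chain),
                             FUN = seq_along)
  contigs <- contigs[within_locus <= 2, , drop = FALSE]

  chain_desc <- switch(policy,
    NT_VJ = paste(contigs$chain, contigs$v_gene, contigs$j_gene,
                  contigs$cdr3_nt, sep = "_"),
    AA_VJ = paste(contigs$chain, contigs$v_gene, contigs$j_gene,
                  contigs$cdr3_aa, sep = "_"),
    RAW_ID = NA_character_)

  split_idx <- split(seq_len(nrow(contigs)), contigs$barcode)
  res <- lapply(names(split_idx), function(bc) {
    idx <- split_idx[[bc]]
    subject <- unname(subj_of[bc])
    if (policy == "RAW_ID") {
      rid <- unique(contigs$raw_clonotype_id[idx])
      rid <- rid[!is.na(rid) & rid != ""]
      if (length(rid) == 0) return(NULL)
      key <- rid[[1]]
    } else {
      key <- paste(sort(unique(chain_desc[idx])), collapse = "|")
    }
    is_bcr <- any(contigs$chain[idx] %in% BCR_CHAINS)
    isotype <- NA_character_
    if (is_bcr) {
      heavy <- idx[contigs$chain[idx] == "IGH"]
      if (length(heavy) > 0) {
        cg <- contigs$c_gene[heavy[[1]]]  # chains pre-sorted by UMIs
        if (!is.na(cg) && cg != "") isotype <- cg
      }
    }
    data.frame(barcode = bc, subject_id = subject,
               clone_id = paste0(subject, ":", key),
               receptor_type = if (is_bcr) "BCR" else "TCR",
               isotype = isotype, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Write clone assignments as TSV
#'
#' @param assignments Output of [collapse_to_clonotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clone_assignments <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
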