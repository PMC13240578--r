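#' Build the clone table
#'
#' Joins clone assignments with cell records into the central repertoire
#' object: per subject, each clone's cell counts by compartment and by
#' cluster. Every assigned cell is counted exactly once; cells without an
#' assignment are excluded.
#'
#' @param assignments Data frame from [collapse_to_clonotypes()].
#' @param cells Cell-record data frame (typically the QC-passing set).
#' @return An object of class `clone_table`: a list with
#'   \describe{
#'     \item{cells}{one row per assigned cell: `barcode`, `subject_id`,
#'       `clone_id`, `compartment`, `cluster`, `receptor_type`, `isotype`.}
#'     \item{clones}{one row per subject x clone: `subject_id`, `clone_id`,
#'       `receptor_type`, `isotype`, `size_total`, `n_lung`, `n_balf`,
#'       `n_pbmc`.}
#'   }
#' @export
build_clone_table <- function(assignments, cells) {
  if (nrow(assignments) == 0) {
    empty_cells <- data.frame(barcode = character(), subject_id = character(),
                              clone_id = character(), compartment = character(),
                              cluster = character(), receptor_type = character(),
                              isotype = character(), stringsAsFactors = FALSE)
    empty_clones <- data.frame(subject_id = character(), clone_id = character(),
                               receptor_type = character(), isotype = character(),
                               size_total = integer(), n_lung = integer(),
                               n_balf = integer(), n_pbmc = integer(),
                               stringsAsFactors = FALSE)
    return(structure(list(cells = empty_cells, clones = empty_clones),
                     class = "clone_table"))
  }
  idx <- match(assignments$barcode, cells$barcode)
  if (anyNA(idx)) {
    stop_integrity("assignment(s) reference unknown barcode(s): ",
                   paste(head(assignments$barcode[is.na(idx)], 5), collapse = ", "))
  }
  cell_tab <- data.frame(
    barcode = assignments$barcode,
    subject_id = assignments$subject_id,
    clone_id = assignments$clone_id,
    compartment = cells$compartment[idx],
    cluster = cells$cluster[idx],
    receptor_type = assignments$receptor_type,
    isotype = assignments$isotype,
    stringsAsFactors = FALSE)

  key <- paste(cell_tab$subject_id, cell_tab$clone_id, sep = "\r")
  comp_counts <- table(key, factor(cell_tab$compartment, levels = COMPARTMENTS))
  keys <- rownames(comp_counts)
  first <- match(keys, key)
  clones <- data.frame(
    subject_id = cell_tab$subject_id[first],
    clone_id = cell_tab$clone_id[first],
    receptor_type = cell_tab$receptor_type[first],
    isotype = cell_tab$isotype[first],
    size_total = as.integer(rowSums(comp_counts)),
    n_lung = as.integer(comp_counts[, "LUNG"]),
    n_balf = as.integer(comp_counts[, "BALF"]),
    n_pbmc = as.integer(comp_counts[, "PBMC"]),
    row.names = NULL, stringsAsFactors = FALSE)
  clones <- clones[order(clones$subject_id, clones$clone_id), , drop = FALSE]
  rownames(clones) <- NULL
  structure(list(cells = cell_tab, clones = clones), class = "clone_table")
}

#' @export
print.clone_table <- function(x, ...) {
  cat("<clone_table> ", nrow(x$clones), " clones, ", nrow(x$cells), " cells, ",
      length(unique(x$clones$subject_id)), " subject(s)\n", sep = "")
  invisible(x)
}

#' Write the clone table as TSV
#'
#' @param tab A `clone_table`.
#' @param path Output path (one row per subject x clone).
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(tab, path) {
  write.table(tab$clones, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cells belonging to expanded clones, per stratum
#'
#' A cell is "expanded" iff its clone's total size within its subject (all
#' compartments pooled) is at least `min_size`. Counts of such cells are
#' returned per cluster or per compartment.
#'
#' @param tab A `clone_table`.
#' @param min_size Expansion threshold on clone size (default 2).
#' @param by Stratify by `"cluster"` or `"compartment"`.
#' @return Data frame with columns `stratum`, `n_cells`.
#' @export
expansion_counts <- function(tab, min_size = 2L, by = c("cluster", "compartment")) {
  by <- match.arg(by)
  if (min_size < 2) stop_validation("min_size must be >= 2")
  sizes <- setNames(tab$clones$size_total,
                    paste(tab$clones$subject_id, tab$clones$clone_id, sep = "\r"))
  cell_key <- paste(tab$cells$subject_id, tab$cells$clone_id, sep = "\r")
  expanded <- sizes[cell_key] >= min_size
  strata <- tab$cells[[by]]
  counts <- table(strata[expanded])
  all_strata <- sort(unique(strata))
  n <- as.integer(counts[all_strata])
  n[is.na(n)] <- 0L
  data.frame(stratum = all_strata, n_cells = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Repertoire overlap between two strata
#'
#' Shared clones are counted within subject then summed; the Jaccard index is
#' pooled over the union of subject-scoped clone ids (clone ids never span
#' subjects, so pooling cannot conflate repertoires).
#'
#' @param tab A `clone_table`.
#' @param stratum_a,stratum_b Cluster labels or compartment names.
#' @param by `"cluster"` or `"compartment"`; inferred from the stratum names
#'   when they are compartments.
#' @return List with `shared_clones`, `jaccard`, `shared_cell_fraction_a`,
#'   `shared_cell_fraction_b`.
#' @export
repertoire_overlap <- function(tab, stratum_a, stratum_b,
                               by = if (all(c(stratum_a, stratum_b) %in%
                                            COMPARTMENTS)) "compartment"
                                    else "cluster") {
  strata <- tab$cells[[by]]
  if (!stratum_a %in% strata) stop_validation("unknown stratum: ", stratum_a)
  if (!stratum_b %in% strata) stop_validation("unknown stratum: ", stratum_b)
  cid <- paste(tab$cells$subject_id, tab$cells$clone_id, sep = "\r")
  in_a <- strata == stratum_a
  in_b <- strata == stratum_b
  set_a <- unique(cid[in_a])
  set_b <- unique(cid[in_b])
  shared <- intersect(set_a, set_b)
  list(shared_clones = length(shared),
       jaccard = if (length(union(set_a, set_b)) == 0) 0 else
         length(shared) / length(union(set_a, set_b)),
       shared_cell_fraction_a = if (sum(in_a) == 0) 0 else
         sum(in_a & cid %in% shared) / sum(in_a),
       shared_cell_fraction_b = if (sum(in_b) == 0) 0 else
         sum(in_b & cid %in% shared) / sum(in_b))
}

#' BCR isotype composition
#'
#' Maps heavy-chain constant genes to isotype classes (IGHA, IGHG, IGHM,
#' IGHD, IGHE; cells without a heavy chain are "missing") and counts cells
#' (not clones) per cluster and in total.
#'
#' @param tab A `clone_table`; only `receptor_type == "BCR"` cells are used.
#' @return List with `by_cluster` (data frame `cluster`, `isotype_class`,
#'   `n_cells`) and `total` (named integer vector over classes).
#' @export
isotype_composition <- function(tab) {
  cells <- tab$cells[tab$cells$receptor_type == "BCR", , drop = FALSE]
  cls <- rep("missing", nrow(cells))
  iso <- cells$isotype
  for (prefix in c("IGHA", "IGHG", "IGHM", "IGHD", "IGHE")) {
    cls[!is.na(iso) & startsWith(iso, prefix)] <- prefix
  }
  cls <- factor(cls, levels = ISOTYPE_CLASSES)
  by_cluster <- as.data.frame(table(cluster = cells$cluster,
                                    isotype_class = cls),
                              stringsAsFactors = FALSE)
  names(by_cluster)[[3]] <- "n_cells"
  total <- table(cls)
  list(by_cluster = by_cluster,
       total = setNames(as.integer(total), names(total)))
}
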