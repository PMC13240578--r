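#' Shannon entropy (natural log)
#'
#' `H(p) = -sum(p_i * ln(p_i))` with the convention `0 * ln(0) = 0`.
#'
#' @param p Probability vector: nonnegative, summing to 1 (tolerance 1e-9).
#' @return Nonnegative entropy in nats.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop_validation("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop_validation("probabilities must sum to 1")
  pos <- p[p > 0]
  -sum(pos * log(pos))
}

#' Clonal expansion index of a stratum
#'
#' One minus the Pielou evenness of the clone-frequency vector:
#' `1 - H(p) / ln(N)` with `N` distinct clones. 0 means all clones are
#' singletons (maximal evenness); 1 means a monoclonal stratum. With a single
#' clone the index is 1 if that clone has at least 2 cells, else 0.
#'
#' @param sizes Positive integer vector of clone cell counts in the stratum.
#' @return Value in \[0, 1\].
#' @export
expansion_index <- function(sizes) {
  if (length(sizes) == 0) stop_validation("empty stratum")
  if (any(sizes <= 0)) stop_validation("clone sizes must be positive")
  n_clones <- length(sizes)
  if (n_clones == 1) return(if (sizes[[1]] >= 2) 1 else 0)
  1 - shannon_entropy(sizes / sum(sizes)) / log(n_clones)
}

# Clone-size-weighted mean entropy of per-clone category distributions,
# computed within one subject's stratum. `category` is a factor over the
# categories considered.
weighted_clone_entropy <- function(clone_id, category) {
  counts <- table(clone_id, category)
  h <- apply(counts, 1, function(ct) shannon_entropy(ct / sum(ct)))
  w <- rowSums(counts) / sum(counts)
  list(value = sum(w * h), n_clones = nrow(counts), n_cells = sum(counts))
}

# Shared machinery for the migration and transition indices: per subject,
# clone-size-weighted mean entropy of each clone's distribution over
# `category`; subjects then averaged weighted by stratum cell count.
index_over_subjects <- function(cells, category_col, n_categories, normalize,
                                aggregate) {
  per_subj <- lapply(split(cells, cells$subject_id), function(sc) {
    wce <- weighted_clone_entropy(sc$clone_id,
                                  factor(sc[[category_col]]))
    # a single category admits no sharing; its normalized index is 0
    if (normalize) {
      wce$value <- if (n_categories < 2) 0 else wce$value / log(n_categories)
    }
    wce
  })
  subjects <- names(per_subj)
  vals <- vapply(per_subj, `[[`, numeric(1), "value")
  ncl <- vapply(per_subj, `[[`, numeric(1), "n_clones")
  ncell <- vapply(per_subj, `[[`, numeric(1), "n_cells")
  if (aggregate) {
    data.frame(subject_id = "pooled",
               value = sum(vals * ncell) / sum(ncell),
               n_clones = as.integer(sum(ncl)), n_cells = as.integer(sum(ncell)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = subjects, value = unname(vals),
               n_clones = as.integer(ncl), n_cells = as.integer(ncell),
               row.names = NULL, stringsAsFactors = FALSE)
  }
}

#' Cross-compartment migration index
#'
#' For each phenotype cluster (the stratum), every clone's cells in that
#' cluster define a distribution over compartments; the index is the
#' clone-size-weighted mean Shannon entropy of those distributions. 0 means
#' every clone is confined to one compartment. For a pairwise call, cells are
#' restricted to the two compartments (clones absent from both drop out),
#' and normalisation divides by `ln(2)` instead of `ln(3)`.
#'
#' Values are computed per subject and then averaged weighted by the
#' subject's stratum cell count; because clone ids are subject-scoped this
#' equals the pooled computation.
#'
#' @param tab A `clone_table`.
#' @param clusters Cluster labels to report (default: all present).
#' @param compartments `NULL` for all three, or a pair such as
#'   `c("LUNG", "BALF")`.
#' @param normalize Divide by the log of the number of compartments
#'   considered so values live in \[0, 1\] (default `TRUE`).
#' @param aggregate Average across subjects (default) or return per-subject
#'   rows.
#' @return Data frame with columns `subject_id`, `cluster`, `index_kind`,
#'   `pair`, `value`, `n_clones`, `n_cells`. Strata with zero cells are
#'   omitted with a warning.
#' @export
migration_index <- function(tab, clusters = NULL, compartments = NULL,
                            normalize = TRUE, aggregate = TRUE) {
  cells <- tab$cells
  if (is.null(compartments)) {
    compartments <- COMPARTMENTS
  } else {
    compartments <- match_enum(compartments, COMPARTMENTS, "compartments")
    cells <- cells[cells$compartment %in% compartments, , drop = FALSE]
  }
  cells$compartment <- factor(cells$compartment, levels = compartments)
  if (is.null(clusters)) clusters <- sort(unique(tab$cells$cluster))
  pair_label <- paste(compartments, collapse = "-")
  out <- lapply(clusters, function(cl) {
    sub <- cells[cells$cluster == cl, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("cluster '", cl, "' has no cells in the compartments ",
              "considered; omitted")
      return(NULL)
    }
    res <- index_over_subjects(sub, "compartment", length(compartments),
                               normalize, aggregate)
    cbind(cluster = cl, index_kind = "MIGRATION", pair = pair_label, res,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) stop_validation("no stratum with cells")
  out[c("subject_id", "cluster", "index_kind", "pair", "value",
        "n_clones", "n_cells")]
}

#' Cross-cluster transition index
#'
#' Identical machinery to [migration_index()] with phenotype clusters in
#' place of compartments: each clone's cells define a distribution over
#' clusters; the index is the clone-size-weighted mean entropy. A pairwise
#' call restricts cells to the two clusters.
#'
#' @param tab A `clone_table`.
#' @param clusters `NULL` for all clusters, or a pair of cluster labels.
#' @param normalize Divide by log(number of clusters considered).
#' @param aggregate Average across subjects (default) or per-subject rows.
#' @return Data frame as in [migration_index()] with
#'   `index_kind = "TRANSITION"` and `cluster = "ALL"`.
#' @export
transition_index <- function(tab, clusters = NULL, normalize = TRUE,
                             aggregate = TRUE) {
  cells <- tab$cells
  if (is.null(clusters)) {
    clusters <- sort(unique(cells$cluster))
  } else {
    unknown <- setdiff(clusters, cells$cluster)
    if (length(unknown) > 0) {
      stop_validation("unknown cluster(s): ", paste(unknown, collapse = ", "))
    }
    cells <- cells[cells$cluster %in% clusters, , drop = FALSE]
  }
  if (nrow(cells) == 0) stop_validation("no cells in the clusters considered")
  cells$cluster <- factor(cells$cluster, levels = clusters)
  res <- index_over_subjects(cells, "cluster", length(clusters),
                             normalize, aggregate)
  out <- cbind(cluster = "ALL", index_kind = "TRANSITION",
               pair = paste(clusters, collapse = "-"), res,
               stringsAsFactors = FALSE)
  out[c("subject_id", "cluster", "index_kind", "pair", "value",
        "n_clones", "n_cells")]
}

#' Expansion index per cluster
#'
#' Applies [expansion_index()] to each cluster's within-subject clone-size
#' vector, then averages across subjects weighted by stratum cell count.
#'
#' @param tab A `clone_table`.
#' @param clusters Cluster labels to report (default: all present).
#' @param aggregate Average across subjects (default) or per-subject rows.
#' @return Data frame with columns `subject_id`, `cluster`, `index_kind`,
#'   `value`, `n_clones`, `n_cells`.
#' @export
expansion_index_by_cluster <- function(tab, clusters = NULL, aggregate = TRUE) {
  cells <- tab$cells
  if (is.null(clusters)) clusters <- sort(unique(cells$cluster))
  out <- lapply(clusters, function(cl) {
    sub <- cells[cells$cluster == cl, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("cluster '", cl, "' has no cells; omitted")
      return(NULL)
    }
    per_subj <- lapply(split(sub, sub$subject_id), function(sc) {
      sizes <- as.integer(table(sc$clone_id))
      list(value = expansion_index(sizes), n_clones = length(sizes),
           n_cells = sum(sizes))
    })
    vals <- vapply(per_subj, `[[`, numeric(1), "value")
    ncl <- vapply(per_subj, `[[`, numeric(1), "n_clones")
    ncell <- vapply(per_subj, `[[`, numeric(1), "n_cells")
    res <- if (aggregate) {
      data.frame(subject_id = "pooled",
                 value = sum(vals * ncell) / sum(ncell),
                 n_clones = as.integer(sum(ncl)),
                 n_cells = as.integer(sum(ncell)), stringsAsFactors = FALSE)
    } else {
      data.frame(subject_id = names(per_subj), value = unname(vals),
                 n_clones = as.integer(ncl), n_cells = as.integer(ncell),
                 row.names = NULL, stringsAsFactors = FALSE)
    }
    cbind(cluster = cl, index_kind = "EXPANSION", res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  out[c("subject_id", "cluster", "index_kind", "value", "n_clones", "n_cells")]
}
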