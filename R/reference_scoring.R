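#' Build pattern-level reference profiles
#'
#' Aggregates the normalized expression of labelled cells into one
#' pseudo-bulk profile per sharing pattern (per-gene median by default), and
#' selects, for every ordered pattern pair (A, B), the genes most
#' over-expressed in A relative to B as pairwise marker genes. Patterns with
#' fewer than `min_cells` labelled cells are dropped with a warning.
#'
#' @param expr A normalised `expression_matrix` of the reference cells.
#' @param cell_labels Data frame with columns `barcode`, `pattern`
#'   (`UNCLASSIFIED` cells are ignored).
#' @param genes_per_pair Number of marker genes per ordered pair (default 50);
#'   only genes with a strictly positive profile difference are eligible, so
#'   constant genes are never selected.
#' @param min_cells Minimum labelled cells per pattern (default 10).
#' @param aggregate `"median"` (default, robust) or `"mean"`.
#' @return Object of class `reference_profile_set`: list with `patterns`,
#'   `profiles` (genes x patterns matrix) and `marker_genes` (named list over
#'   ordered pairs `"A|B"`).
#' @export
build_references <- function(expr, cell_labels, genes_per_pair = 50L,
                             min_cells = 10L,
                             aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.null(expr$normalized)) {
    stop_validation("normalized layer missing; run log_normalize() first")
  }
  cell_labels <- cell_labels[cell_labels$pattern != "UNCLASSIFIED", , drop = FALSE]
  cell_labels <- cell_labels[cell_labels$barcode %in% colnames(expr$normalized), ,
                             drop = FALSE]
  sizes <- table(cell_labels$pattern)
  small <- names(sizes)[sizes < min_cells]
  if (length(small) > 0) {
    warning("pattern(s) below ", min_cells, " labelled cells dropped: ",
            paste(small, collapse = ", "))
  }
  patterns <- sort(names(sizes)[sizes >= min_cells])
  if (length(patterns) < 2) {
    stop_validation("fewer than 2 patterns with at least ", min_cells,
                    " labelled cells")
  }
  agg_fun <- if (aggregate == "median") median else mean
  profiles <- vapply(patterns, function(p) {
    bcs <- cell_labels$barcode[cell_labels$pattern == p]
    apply(as.matrix(expr$normalized[, bcs, drop = FALSE]), 1, agg_fun)
  }, numeric(nrow(expr$normalized)))
  rownames(profiles) <- rownames(expr$normalized)

  marker_genes <- list()
  for (a in patterns) {
    for (b in setdiff(patterns, a)) {
      d <- profiles[, a] - profiles[, b]
      pos <- which(d > 0)
      ord <- pos[order(-d[pos], rownames(profiles)[pos])]
      marker_genes[[paste(a, b, sep = "|")]] <-
        rownames(profiles)[head(ord, genes_per_pair)]
    }
  }
  structure(list(patterns = patterns, profiles = profiles,
                 marker_genes = marker_genes),
            class = "reference_profile_set")
}

#' @export
print.reference_profile_set <- function(x, ...) {
  cat("<reference_profile_set> patterns: ", paste(x$patterns, collapse = ", "),
      "; ", nrow(x$profiles), " genes\n", sep = "")
  invisible(x)
}

marker_union <- function(refs, patterns) {
  pairs <- outer(patterns, patterns, paste, sep = "|")
  unique(unlist(refs$marker_genes[pairs[pairs %in% names(refs$marker_genes)]]))
}

#' Score query cells against reference profiles
#'
#' The score of a cell for a pattern is the Spearman rank correlation (ties
#' mid-ranked) between the cell's normalized expression and the pattern's
#' profile, over the evaluation gene set: the union of all pairwise marker
#' genes intersected with the query's genes.
#'
#' @param query A normalised `expression_matrix`, or a genes x cells
#'   numeric matrix of normalized values.
#' @param refs A [build_references()] object.
#' @param min_genes Minimum size of the evaluation gene set (default 20).
#' @return Numeric matrix (cells x patterns) of Spearman correlations.
#' @export
score_cells <- function(query, refs, min_genes = 20L) {
  qm <- if (inherits(query, "expression_matrix")) {
    if (is.null(query$normalized)) {
      stop_validation("normalized layer missing; run log_normalize() first")
    }
    query$normalized
  } else query
  eval_genes <- intersect(marker_union(refs, refs$patterns), rownames(qm))
  if (length(eval_genes) < min_genes) {
    stop_validation("evaluation gene set too small (", length(eval_genes),
                    " < ", min_genes, ")")
  }
  scores <- cor(as.matrix(qm[eval_genes, , drop = FALSE]),
                refs$profiles[eval_genes, , drop = FALSE],
                method = "spearman")
  rownames(scores) <- colnames(qm)
  scores
}

# Spearman scores of one query vector against a subset of patterns over the
# markers that discriminate within that subset. Returns NULL when the
# discriminating set cannot score (too few genes or zero variance).
score_retained <- function(qv, refs, retained) {
  genes <- intersect(marker_union(refs, retained), names(qv))
  if (length(genes) < 2) return(NULL)
  x <- qv[genes]
  if (length(unique(x)) < 2) return(NULL)
  s <- suppressWarnings(
    cor(x, refs$profiles[genes, retained, drop = FALSE], method = "spearman"))
  s <- drop(s)
  names(s) <- retained
  s
}

#' Fine-tune per-cell pattern labels
#'
#' Iterative elimination: starting from the full score vector, patterns
#' scoring within `margin` of the top are retained and re-scored using only
#' the marker genes that discriminate among the retained patterns; the loop
#' repeats until a single pattern remains or the retained set stops
#' shrinking. On a stall the label is the retained pattern with the highest
#' current score (ties broken by the highest initial score, then
#' lexicographically); if the retained patterns cannot be discriminated at
#' all (exactly tied scores, e.g. identical reference profiles) the cell is
#' labelled `AMBIGUOUS` and flagged as pruned.
#'
#' @param query A normalised `expression_matrix` or genes x cells matrix.
#' @param refs A [build_references()] object.
#' @param margin Retention margin below the top score (default 0.05).
#' @param min_genes Passed to [score_cells()].
#' @return Data frame with columns `barcode`, `initial_label`, `final_label`,
#'   `pruned`, plus the initial score columns `score.<pattern>`.
#' @export
fine_tune <- function(query, refs, margin = 0.05, min_genes = 20L) {
  qm <- if (inherits(query, "expression_matrix")) query$normalized else query
  initial <- score_cells(qm, refs, min_genes = min_genes)
  qdense <- as.matrix(qm)
  n_ties_logged <- 0L
  res <- lapply(seq_len(ncol(qdense)), function(i) {
    qv <- qdense[, i]
    names(qv) <- rownames(qdense)
    s0 <- initial[i, ]
    initial_label <- refs$patterns[which.max(s0)]
    s <- s0
    retained <- refs$patterns[s >= max(s) - margin]
    repeat {
      if (length(retained) == 1) {
        return(list(label = retained, pruned = FALSE))
      }
      s_new <- score_retained(qv, refs, retained)
      stalled <- is.null(s_new) || any(is.na(s_new))
      if (!stalled) {
        s <- s_new
        new_retained <- retained[s >= max(s) - margin]
        stalled <- setequal(new_retained, retained)
        retained <- new_retained
      }
      if (stalled) break
    }
    if (length(retained) == 1) return(list(label = retained, pruned = FALSE))
    cur <- s[retained]
    cur[is.na(cur)] <- -Inf
    if (diff(range(cur)) < 1e-12) {
      return(list(label = "AMBIGUOUS", pruned = TRUE))
    }
    best <- retained[cur == max(cur)]
    if (length(best) > 1) {
      raw <- s0[match(best, refs$patterns)]
      best <- best[raw == max(raw)]
      best <- sort(best)[[1]]
      n_ties_logged <<- n_ties_logged + 1L
    }
    list(label = best[[1]], pruned = FALSE)
  })
  if (n_ties_logged > 0) {
    message(n_ties_logged, " cell(s) labelled by tie-break")
  }
  out <- data.frame(
    barcode = colnames(qdense),
    initial_label = refs$patterns[apply(initial, 1, which.max)],
    final_label = vapply(res, `[[`, character(1), "label"),
    pruned = vapply(res, `[[`, logical(1), "pruned"),
    row.names = NULL, stringsAsFactors = FALSE)
  cbind(out, setNames(as.data.frame(initial, row.names = NULL),
                      paste0("score.", colnames(initial))))
}

#' Summarise fine-tuned predictions
#'
#' @param results Output of [fine_tune()].
#' @return Data frame with columns `final_label`, `n_cells`, `proportion`;
#'   counts sum to the number of queries.
#' @export
summarize_predictions <- function(results) {
  if (nrow(results) == 0) {
    return(data.frame(final_label = character(), n_cells = integer(),
                      proportion = numeric(), stringsAsFactors = FALSE))
  }
  counts <- table(results$final_label)
  data.frame(final_label = names(counts), n_cells = as.integer(counts),
             proportion = as.numeric(counts) / nrow(results),
             row.names = NULL, stringsAsFactors = FALSE)
}
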