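#' Compartment occupancy of clones
#'
#' A clone is present in a compartment iff it has at least `min_cells` cells
#' there.
#'
#' @param clones The `clones` data frame of a [build_clone_table()] object
#'   (needs `n_lung`, `n_balf`, `n_pbmc`).
#' @param min_cells Detection floor per compartment (default 1).
#' @return Data frame with logical columns `lung`, `pbmc`, `balf`, row-aligned
#'   with `clones`.
#' @export
occupancy <- function(clones, min_cells = 1L) {
  if (min_cells < 1) stop_validation("min_cells must be >= 1")
  data.frame(lung = clones$n_lung >= min_cells,
             pbmc = clones$n_pbmc >= min_cells,
             balf = clones$n_balf >= min_cells,
             stringsAsFactors = FALSE)
}

#' Classify an occupancy state into a sharing pattern
#'
#' The three enumerated occupancy states map to named patterns:
#' \describe{
#'   \item{P1A}{lung and BALF, without blood -- interstitium-to-airway
#'     sharing (activated, cross-compartment).}
#'   \item{P1B}{lung only -- resting resident cells.}
#'   \item{P2}{lung and blood, without BALF -- circulating effectors seeding
#'     the interstitium.}
#' }
#' The four remaining non-empty occupancy states (BALF-only, PBMC-only,
#' PBMC+BALF, triple-positive) form an explicit `OTHER` class rather than
#' being forced into the nearest pattern; the empty state is `UNCLASSIFIED`.
#' The mapping is a total function on all 8 occupancy states and is
#' idempotent by construction.
#'
#' @param lung,pbmc,balf Logical vectors (recycled to a common length).
#' @return Character vector of pattern labels.
#' @export
classify_pattern <- function(lung, pbmc, balf) {
  n <- max(length(lung), length(pbmc), length(balf))
  lung <- rep_len(lung, n); pbmc <- rep_len(pbmc, n); balf <- rep_len(balf, n)
  out <- rep("OTHER", n)
  out[lung & !pbmc & balf] <- "P1A"
  out[lung & !pbmc & !balf] <- "P1B"
  out[lung & pbmc & !balf] <- "P2"
  out[!lung & !pbmc & !balf] <- "UNCLASSIFIED"
  out
}

#' Classify expanded clones into sharing patterns
#'
#' Applies the expansion gate (clone size within subject, all compartments
#' pooled, at least `min_size`) and the occupancy threshold, then
#' [classify_pattern()]. Clones failing the gate, or with empty occupancy at
#' `min_cells`, are `UNCLASSIFIED`.
#'
#' @param tab A `clone_table`.
#' @param min_size Expansion threshold (default 2).
#' @param min_cells Occupancy detection floor (default 1).
#' @return The `clones` data frame with added logical columns `lung`, `pbmc`,
#'   `balf` and a `pattern` column.
#' @export
classify_clones <- function(tab, min_size = 2L, min_cells = 1L) {
  clones <- tab$clones
  occ <- occupancy(clones, min_cells = min_cells)
  pattern <- classify_pattern(occ$lung, occ$pbmc, occ$balf)
  pattern[clones$size_total < min_size] <- "UNCLASSIFIED"
  cbind(clones, occ, pattern = pattern, stringsAsFactors = FALSE)
}

#' Per-subject sharing-pattern proportions
#'
#' Proportions over `{P1A, P1B, P2, OTHER}` per subject, weighting either by
#' clone count or by member-cell count. `UNCLASSIFIED` clones are excluded;
#' subjects with no classified clone are omitted with a warning.
#'
#' @param clone_patterns Output of [classify_clones()].
#' @param weight `"clones"` or `"cells"`.
#' @return Data frame with columns `subject_id`, `P1A`, `P1B`, `P2`, `OTHER`;
#'   rows sum to 1.
#' @export
pattern_proportions <- function(clone_patterns, weight = c("clones", "cells")) {
  weight <- match.arg(weight)
  keep <- clone_patterns$pattern != "UNCLASSIFIED"
  dropped <- setdiff(unique(clone_patterns$subject_id),
                     unique(clone_patterns$subject_id[keep]))
  if (length(dropped) > 0) {
    warning("subject(s) with no classified clone omitted: ",
            paste(dropped, collapse = ", "))
  }
  cp <- clone_patterns[keep, , drop = FALSE]
  w <- if (weight == "clones") rep(1, nrow(cp)) else cp$size_total
  lev <- c("P1A", "P1B", "P2", "OTHER")
  subjects <- sort(unique(cp$subject_id))
  mat <- t(vapply(subjects, function(s) {
    sel <- cp$subject_id == s
    tot <- tapply(w[sel], factor(cp$pattern[sel], levels = lev), sum)
    tot[is.na(tot)] <- 0
    as.numeric(tot / sum(tot))
  }, numeric(4)))
  colnames(mat) <- lev
  data.frame(subject_id = subjects, mat, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Project clone pattern labels onto cells
#'
#' Each cell inherits its clone's pattern label; cells without a clone
#' assignment, or whose clone is `UNCLASSIFIED`, are labelled `UNCLASSIFIED`.
#'
#' @param clone_patterns Output of [classify_clones()].
#' @param assignments Clone assignments ([collapse_to_clonotypes()]).
#' @param cells Optional cell-record data frame; when given, all its barcodes
#'   appear in the output (receptor-negative cells as `UNCLASSIFIED`).
#' @return Data frame with columns `barcode`, `pattern`.
#' @export
project_to_cells <- function(clone_patterns, assignments, cells = NULL) {
  label_of <- setNames(clone_patterns$pattern, clone_patterns$clone_id)
  barcodes <- if (is.null(cells)) assignments$barcode else cells$barcode
  pat <- rep("UNCLASSIFIED", length(barcodes))
  idx <- match(barcodes, assignments$barcode)
  has <- !is.na(idx)
  lab <- label_of[assignments$clone_id[idx[has]]]
  lab[is.na(lab)] <- "UNCLASSIFIED"
  pat[has] <- lab
  data.frame(barcode = barcodes, pattern = pat, row.names = NULL,
             stringsAsFactors = FALSE)
}
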