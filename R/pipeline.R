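#' Read a run configuration (YAML or JSON)
#'
#' @param path Config file; `.json` is parsed with jsonlite, anything else
#'   with yaml.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

default_run_config <- function() {
  list(
    dialect = "TENX_CSV",
    clone_policy = "NT_VJ",
    qc = list(max_mito_fraction = 0.10, min_genes = 200),
    min_size = 2,
    min_cells = 1,
    normalize_scale = 1e4,
    indices = list(normalize = TRUE,
                   pairs = list(c("LUNG", "BALF"), c("LUNG", "PBMC"),
                                c("BALF", "PBMC"))),
    scoring = list(enabled = TRUE, genes_per_pair = 50, margin = 0.05,
                   min_ref_cells = 10, min_eval_genes = 20,
                   query_compartment = "LUNG"))
}

merge_config <- function(user, defaults) {
  for (k in names(defaults)) {
    if (is.null(user[[k]])) {
      user[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
               !is.null(names(defaults[[k]]))) {
      user[[k]] <- merge_config(user[[k]], defaults[[k]])
    }
  }
  user
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- input reading, QC, clonotype collapse,
#' clone table, pattern classification, entropy indices, and (when both
#' groups are present and scoring is enabled) reference scoring of the
#' control cells against the pneumonia patterns -- writing every output
#' table plus a JSON run report into `output_dir`. Any stage error aborts
#' with the stage name and cause.
#'
#' @param config Configuration list or path to a YAML/JSON file. Required
#'   fields: `contigs`, `mtx`, `features`, `barcodes`, `metadata`,
#'   `output_dir`; everything else has defaults (see the run report, which
#'   records all parameters used).
#' @return The run report, invisibly (also written as `report.json`).
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(config, default_run_config())
  for (f in c("contigs", "mtx", "features", "barcodes", "metadata",
              "output_dir")) {
    if (is.null(config[[f]])) stop_validation("config field missing: ", f)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = config[setdiff(names(config), "output_dir")],
                 stages = list(), warnings = character())
  run_stage <- function(name, fun) {
    withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        report$warnings <<- c(report$warnings,
                              paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  # io ------------------------------------------------------------------
  io <- run_stage("io", function() {
    list(contigs = read_contig_table(config$contigs, config$dialect),
         expr = read_expression_matrix(config$mtx, config$features,
                                       config$barcodes),
         cells = read_cell_metadata(config$metadata))
  })
  report$stages$io <- list(n_contigs = nrow(io$contigs),
                           n_cells = nrow(io$cells),
                           n_genes = nrow(io$expr$counts))

  # qc ------------------------------------------------------------------
  qc <- run_stage("qc", function() {
    thr <- qc_thresholds(config$qc$max_mito_fraction, config$qc$min_genes)
    parts <- apply_cell_qc(io$cells, thr)
    expr <- io$expr
    keep_bc <- intersect(colnames(expr$counts), parts$kept$barcode)
    expr$counts <- expr$counts[, keep_bc, drop = FALSE]
    expr <- log_normalize(expr, config$normalize_scale)
    c(parts, list(expr = expr))
  })
  report$stages$qc <- list(n_kept = nrow(qc$kept), n_removed = nrow(qc$removed))

  # clones --------------------------------------------------------------
  clones <- run_stage("clones", function() {
    assignments <- collapse_to_clonotypes(io$contigs, qc$kept,
                                          policy = config$clone_policy)
    tab <- build_clone_table(assignments, qc$kept)
    write_clone_assignments(assignments,
                            file.path(config$output_dir, "assignments.tsv"))
    write_clone_table(tab, file.path(config$output_dir, "clone_table.tsv"))
    list(assignments = assignments, tab = tab)
  })
  report$stages$clones <- list(n_assignments = nrow(clones$assignments),
                               n_clones = nrow(clones$tab$clones))

  # patterns ------------------------------------------------------------
  patterns <- run_stage("patterns", function() {
    cp <- classify_clones(clones$tab, min_size = config$min_size,
                          min_cells = config$min_cells)
    write_tsv(cp[c("subject_id", "clone_id", "size_total", "n_lung",
                   "n_pbmc", "n_balf", "pattern")],
              file.path(config$output_dir, "patterns.tsv"))
    props <- pattern_proportions(cp, weight = "clones")
    write_tsv(props, file.path(config$output_dir, "pattern_proportions.tsv"))
    cell_labels <- project_to_cells(cp, clones$assignments, qc$kept)
    write_tsv(cell_labels, file.path(config$output_dir, "cell_patterns.tsv"))
    list(clone_patterns = cp, proportions = props, cell_labels = cell_labels)
  })
  report$stages$patterns <- list(
    n_classified = sum(patterns$clone_patterns$pattern != "UNCLASSIFIED"),
    n_clones = nrow(patterns$clone_patterns))

  # indices -------------------------------------------------------------
  indices <- run_stage("indices", function() {
    norm <- isTRUE(config$indices$normalize)
    rows <- list(expansion_index_by_cluster(clones$tab))
    mig_all <- migration_index(clones$tab, normalize = norm)
    rows <- c(rows, list(mig_all))
    for (pair in config$indices$pairs) {
      rows <- c(rows, list(migration_index(clones$tab,
                                           compartments = unlist(pair),
                                           normalize = norm)))
    }
    rows <- c(rows, list(transition_index(clones$tab, normalize = norm)))
    tab <- do.call(rbind, lapply(rows, function(r) {
      if (!"pair" %in% names(r)) r$pair <- ""
      r[c("subject_id", "cluster", "index_kind", "pair", "value",
          "n_clones", "n_cells")]
    }))
    write_tsv(tab, file.path(config$output_dir, "indices.tsv"))
    tab
  })
  report$stages$indices <- list(n_rows = nrow(indices))

  # scoring -------------------------------------------------------------
  if (isTRUE(config$scoring$enabled) &&
      all(c("PNEUMONIA", "CONTROL") %in% qc$kept$group)) {
    scoring <- run_stage("scoring", function() {
      ref_bc <- qc$kept$barcode[qc$kept$group == "PNEUMONIA"]
      labels <- patterns$cell_labels
      labels <- labels[labels$barcode %in% ref_bc, , drop = FALSE]
      labels <- labels[labels$pattern %in% c("P1A", "P1B", "P2"), , drop = FALSE]
      refs <- build_references(qc$expr, labels,
                               genes_per_pair = config$scoring$genes_per_pair,
                               min_cells = config$scoring$min_ref_cells)
      query_bc <- qc$kept$barcode[
        qc$kept$group == "CONTROL" &
          qc$kept$compartment == config$scoring$query_compartment]
      query_bc <- intersect(query_bc, colnames(qc$expr$normalized))
      if (length(query_bc) == 0) {
        stop_validation("no control query cells in compartment ",
                        config$scoring$query_compartment)
      }
      qexpr <- qc$expr$normalized[, query_bc, drop = FALSE]
      preds <- fine_tune(qexpr, refs, margin = config$scoring$margin,
                         min_genes = config$scoring$min_eval_genes)
      write_tsv(preds, file.path(config$output_dir, "predictions.tsv"))
      write_tsv(summarize_predictions(preds),
                file.path(config$output_dir, "prediction_summary.tsv"))
      preds
    })
    report$stages$scoring <- list(
      n_queries = nrow(scoring),
      labels = as.list(table(scoring$final_label)))
  }

  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
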