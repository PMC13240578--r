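#' Configuration of a synthetic cohort
#'
#' Builds the full parameter set for [simulate_cohort()]. Defaults describe a
#' small pneumonia-like cohort: subject-scoped repertoires with clonal
#' expansion, pattern-structured compartment occupancy, and
#' compartment/pattern-specific phenotype programs (resident markers ITGAE /
#' CXCR6 / CXCR3, circulating markers CX3CR1 / FGFBP2 / KLRG1, cycling
#' marker MKI67, cytotoxic GZMB / GNLY) as overdispersed counts, plus QC
#' covariates.
#'
#' @param n_subjects Number of pneumonia-group subjects (default 5).
#' @param n_control_subjects Control-group subjects (default 0); their clones
#'   are drawn from `control_pattern_mix`.
#' @param clones_per_subject Clones per subject (default 200).
#' @param pattern_mix Probability vector over P1A, P1B, P2, OTHER
#'   (default 0.5 / 0.2 / 0.3 / 0).
#' @param control_pattern_mix Pattern mix for control subjects (default
#'   0 / 0.6 / 0.4 / 0: resting and circulating programs only).
#' @param clone_size_law `list(family = "geometric", p = ...)` or
#'   `list(family = "zipf", s = ..., max = ...)`; minimum size 1.
#' @param expansion_fraction Fraction of clones that are expanded, i.e.
#'   forced to size >= 2 (default 0.5); the rest are singletons.
#' @param compartment_allocation Per pattern, Dirichlet concentrations over
#'   its allowed compartments (P1A: lung+BALF; P1B: lung; P2: lung+PBMC;
#'   OTHER: all three).
#' @param enforce_occupancy If `TRUE` (default) every allowed compartment of
#'   an expanded clone receives at least one cell, so true occupancy is
#'   deterministic (probability 0/1) and the clone's configured pattern is
#'   its realised occupancy pattern.
#' @param cluster_mix Per pattern, probability vector over phenotype cluster
#'   labels for its cells.
#' @param programs Per pattern, named vector of log2 fold effects on marker
#'   genes.
#' @param n_background_genes Background genes with no pattern effect
#'   (default 100).
#' @param baseline_mean Median of the per-gene negative-binomial baseline
#'   means (default 5).
#' @param baseline_sdlog Log-scale spread of per-gene baseline means
#'   (default 1.2); baselines are log-normal across genes and shared across
#'   patterns, giving transcriptome-like rank structure.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2,
#'   default 0.3).
#' @param qc List of QC-covariate parameters: `mito_shape1`, `mito_shape2`
#'   (beta), `n_genes_meanlog`, `n_genes_sdlog` (log-normal),
#'   `fail_fraction` (fraction of deliberately low-quality cells).
#' @param receptor_type `"TCR"` or `"BCR"`.
#' @param isotype_mix For BCR mode, clone-level isotype class probabilities.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 5L,
                          n_control_subjects = 0L,
                          clones_per_subject = 200L,
                          pattern_mix = c(P1A = 0.5, P1B = 0.2, P2 = 0.3,
                                          OTHER = 0),
                          control_pattern_mix = c(P1A = 0, P1B = 0.6,
                                                  P2 = 0.4, OTHER = 0),
                          clone_size_law = list(family = "geometric", p = 0.4),
                          expansion_fraction = 0.5,
                          compartment_allocation = list(
                            P1A = c(LUNG = 2, BALF = 2),
                            P1B = c(LUNG = 1),
                            P2 = c(LUNG = 2, PBMC = 2),
                            OTHER = c(LUNG = 1, BALF = 1, PBMC = 1)),
                          enforce_occupancy = TRUE,
                          cluster_mix = list(
                            P1A = c(T8_rm = 0.7, Cycling = 0.3),
                            P1B = c(T8_rm = 1),
                            P2 = c(T8_eff = 0.6, T8_NK = 0.4),
                            OTHER = c(T8_em = 1)),
                          programs = list(
                            P1A = c(ITGAE = 2, CXCR6 = 2, CXCR3 = 2, GZMB = 2,
                                    GNLY = 2, MKI67 = 2),
                            P1B = c(ITGAE = 2, CXCR6 = 2),
                            P2 = c(CX3CR1 = 2, FGFBP2 = 2, KLRG1 = 2),
                            OTHER = c()),
                          n_background_genes = 100L,
                          baseline_mean = 5,
                          baseline_sdlog = 1.2,
                          nb_dispersion = 0.3,
                          qc = list(mito_shape1 = 2, mito_shape2 = 38,
                                    n_genes_meanlog = log(2500),
                                    n_genes_sdlog = 0.35,
                                    fail_fraction = 0.02),
                          receptor_type = c("TCR", "BCR"),
                          isotype_mix = c(IGHA = 0.6, IGHG = 0.4)) {
  receptor_type <- match.arg(receptor_type)
  stopifnot(abs(sum(pattern_mix) - 1) < 1e-9,
            abs(sum(control_pattern_mix) - 1) < 1e-9)
  cfg <- as.list(environment())
  for (pat in names(cfg$compartment_allocation)) {
    alpha <- cfg$compartment_allocation[[pat]]
    if (length(alpha) == 0 || any(alpha <= 0)) {
      stop_validation("pattern ", pat, " must allow at least one compartment ",
                      "with positive concentration")
    }
  }
  structure(cfg, class = "cohort_config")
}

draw_clone_sizes <- function(n, law, expansion_fraction) {
  expanded <- runif(n) < expansion_fraction
  draw <- function(k) {
    if (law$family == "geometric") {
      1L + rgeom(k, law$p)
    } else if (law$family == "zipf") {
      kmax <- law$max %||% 1000L
      pr <- (1:kmax)^(-law$s)
      sample.int(kmax, k, replace = TRUE, prob = pr)
    } else stop_validation("unknown clone_size_law family: ", law$family)
  }
  sizes <- rep(1L, n)
  # expanded clones: size law conditioned on >= 2 (memoryless for geometric)
  if (any(expanded)) {
    k <- sum(expanded)
    s <- draw(k)
    while (any(s < 2)) s[s < 2] <- draw(sum(s < 2))
    sizes[expanded] <- s
  }
  list(sizes = sizes, expanded = expanded)
}

random_seq <- function(n, len, alphabet) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a cohort with known ground truth
#'
#' Generates a complete synthetic cohort -- receptor contigs, a gene-by-cell
#' count matrix, and cell metadata -- whose clonal structure, sharing
#' patterns, compartment allocations and expression programs are known, and
#' writes it in exactly the dialects the readers consume. The same seed
#' yields byte-identical files.
#'
#' Clone sizes follow the configured law; each clone is assigned a pattern
#' from the pattern mix; its cells are allocated to the pattern's allowed
#' compartments by a Dirichlet-multinomial draw (with every allowed
#' compartment guaranteed one cell when `enforce_occupancy` is set); marker
#' counts are negative-binomial with multiplicative `2^effect` mean shifts.
#' Each clone carries unique CDR3 sequences.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory, created if needed. Files written:
#'   `contigs.csv` (or `contigs_airr.tsv`), `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, `metadata.tsv`, `truth.json`.
#' @param seed Integer RNG seed.
#' @param dialect Contig dialect to emit.
#' @return Invisibly, a list with `paths`, `truth` (list of `clones` and
#'   `cells` data frames), `expr`, `cells`, `contigs`.
#' @export
simulate_cohort <- function(config = cohort_config(), dir, seed = 1L,
                            dialect = c("TENX_CSV", "AIRR_TSV")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  subjects <- c(
    if (config$n_subjects > 0) sprintf("P%02d", seq_len(config$n_subjects)),
    if (config$n_control_subjects > 0)
      sprintf("C%02d", seq_len(config$n_control_subjects)))
  group_of <- setNames(rep(c("PNEUMONIA", "CONTROL"),
                           c(config$n_subjects, config$n_control_subjects)),
                       subjects)

  pattern_names <- c("P1A", "P1B", "P2", "OTHER")
  clone_rows <- list()
  cell_rows <- list()
  for (subj in subjects) {
    mix <- if (group_of[[subj]] == "PNEUMONIA") config$pattern_mix else
      config$control_pattern_mix
    n_cl <- config$clones_per_subject
    sz <- draw_clone_sizes(n_cl, config$clone_size_law,
                           config$expansion_fraction)
    patterns <- sample(pattern_names, n_cl, replace = TRUE, prob = mix)
    for (ci in seq_len(n_cl)) {
      clone_id <- sprintf("%s_T_%04d", subj, ci)
      pat <- patterns[[ci]]
      size <- sz$sizes[[ci]]
      alpha <- config$compartment_allocation[[pat]]
      comps <- names(alpha)
      w <- rgamma(length(alpha), shape = alpha)
      w <- w / sum(w)
      counts <- as.integer(rmultinom(1, size, w))
      names(counts) <- comps
      if (config$enforce_occupancy && sz$expanded[[ci]] &&
          size >= length(comps)) {
        # guarantee one cell in every allowed compartment
        while (any(counts == 0)) {
          i0 <- which(counts == 0)[[1]]
          imax <- which.max(counts)
          counts[i0] <- counts[i0] + 1L
          counts[imax] <- counts[imax] - 1L
        }
      }
      comp_of_cell <- rep(comps, counts)
      cl_mix <- config$cluster_mix[[pat]]
      cluster_of_cell <- if (length(cl_mix) == 1) {
        rep(names(cl_mix), size)
      } else {
        sample(names(cl_mix), size, replace = TRUE, prob = cl_mix)
      }
      clone_rows[[length(clone_rows) + 1L]] <- data.frame(
        subject_id = subj, clone_id = clone_id, pattern = pat,
        expanded = sz$expanded[[ci]], size = size,
        n_lung = sum(comp_of_cell == "LUNG"),
        n_balf = sum(comp_of_cell == "BALF"),
        n_pbmc = sum(comp_of_cell == "PBMC"),
        stringsAsFactors = FALSE)
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        subject_id = subj, clone_id = clone_id, pattern = pat,
        compartment = comp_of_cell, cluster = cluster_of_cell,
        stringsAsFactors = FALSE)
    }
  }
  truth_clones <- do.call(rbind, clone_rows)
  truth_cells <- do.call(rbind, cell_rows)
  truth_cells$barcode <- sprintf("%s-BC%06d", truth_cells$subject_id,
                                 seq_len(nrow(truth_cells)))
  n_cells <- nrow(truth_cells)

  # ---- QC covariates --------------------------------------------------
  mito <- rbeta(n_cells, config$qc$mito_shape1, config$qc$mito_shape2)
  mito <- pmin(mito, 0.999)
  n_genes_cov <- as.integer(round(rlnorm(n_cells, config$qc$n_genes_meanlog,
                                         config$qc$n_genes_sdlog)))
  n_genes_cov <- pmax(n_genes_cov, 201L)
  qc_fail <- runif(n_cells) < config$qc$fail_fraction
  if (any(qc_fail)) {
    # deliberately low-quality: half fail on mito, half on gene count
    fail_mode <- runif(sum(qc_fail)) < 0.5
    mito[qc_fail][fail_mode] <- runif(sum(fail_mode), 0.12, 0.5)
    n_genes_cov[qc_fail][!fail_mode] <-
      as.integer(sample(50:180, sum(!fail_mode), replace = TRUE))
  }
  mito[!qc_fail] <- pmin(mito[!qc_fail], 0.0999)
  truth_cells$qc_fail <- qc_fail

  cells <- data.frame(
    barcode = truth_cells$barcode,
    subject_id = truth_cells$subject_id,
    compartment = truth_cells$compartment,
    group = unname(group_of[truth_cells$subject_id]),
    cluster = truth_cells$cluster,
    mito_fraction = round(mito, 6),
    n_genes = n_genes_cov,
    stringsAsFactors = FALSE)

  # ---- expression counts ----------------------------------------------
  marker_genes <- unique(unlist(lapply(config$programs, names)))
  genes <- c(marker_genes,
             sprintf("GENE%04d", seq_len(config$n_background_genes)))
  effects <- matrix(0, nrow = length(genes), ncol = 4,
                    dimnames = list(genes, pattern_names))
  for (pat in pattern_names) {
    pr <- config$programs[[pat]]
    if (length(pr) > 0) effects[names(pr), pat] <- pr
  }
  size_nb <- 1 / config$nb_dispersion
  # per-gene baseline means, log-normal across genes, shared across patterns
  gene_baseline <- rlnorm(length(genes), meanlog = log(config$baseline_mean),
                          sdlog = config$baseline_sdlog)
  names(gene_baseline) <- genes
  counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes, truth_cells$barcode))
  for (pat in pattern_names) {
    idx <- which(truth_cells$pattern == pat)
    if (length(idx) == 0) next
    mu <- gene_baseline * 2^effects[, pat]
    counts[, idx] <- matrix(
      rnbinom(length(genes) * length(idx), mu = mu, size = size_nb),
      nrow = length(genes))
  }
  expr <- new_expression_matrix(
    as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"))

  # ---- receptor contigs -----------------------------------------------
  n_clones <- nrow(truth_clones)
  nts <- c("A", "C", "G", "T")
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (config$receptor_type == "TCR") {
    chain1 <- "TRA"; chain2 <- "TRB"
    v1 <- sprintf("TRAV%d", sample(1:40, n_clones, replace = TRUE))
    j1 <- sprintf("TRAJ%d", sample(1:50, n_clones, replace = TRUE))
    v2 <- sprintf("TRBV%d", sample(1:30, n_clones, replace = TRUE))
    j2 <- sprintf("TRBJ%d-%d", sample(1:2, n_clones, replace = TRUE),
                  sample(1:7, n_clones, replace = TRUE))
    c1 <- rep("", n_clones); c2 <- rep("", n_clones)
  } else {
    chain1 <- "IGH"; chain2 <- "IGK"
    v1 <- sprintf("IGHV%d-%d", sample(1:7, n_clones, replace = TRUE),
                  sample(1:70, n_clones, replace = TRUE))
    j1 <- sprintf("IGHJ%d", sample(1:6, n_clones, replace = TRUE))
    v2 <- sprintf("IGKV%d-%d", sample(1:7, n_clones, replace = TRUE),
                  sample(1:40, n_clones, replace = TRUE))
    j2 <- sprintf("IGKJ%d", sample(1:5, n_clones, replace = TRUE))
    iso_class <- sample(names(config$isotype_mix), n_clones, replace = TRUE,
                        prob = config$isotype_mix)
    c1 <- paste0(iso_class, "1")  # e.g. IGHA1 / IGHG1
    c2 <- rep("IGKC", n_clones)
  }
  # unique CDR3 per clone and chain
  repeat {
    cdr3_nt1 <- random_seq(n_clones, 36, nts)
    cdr3_nt2 <- random_seq(n_clones, 39, nts)
    if (!anyDuplicated(c(cdr3_nt1, cdr3_nt2))) break
  }
  cdr3_aa1 <- random_seq(n_clones, 12, aas)
  cdr3_aa2 <- random_seq(n_clones, 13, aas)

  ci_of_cell <- match(paste(truth_cells$subject_id, truth_cells$clone_id),
                      paste(truth_clones$subject_id, truth_clones$clone_id))
  contigs <- data.frame(
    barcode = rep(truth_cells$barcode, each = 2),
    chain = rep(c(chain1, chain2), times = n_cells),
    v_gene = as.vector(rbind(v1[ci_of_cell], v2[ci_of_cell])),
    j_gene = as.vector(rbind(j1[ci_of_cell], j2[ci_of_cell])),
    cdr3_nt = as.vector(rbind(cdr3_nt1[ci_of_cell], cdr3_nt2[ci_of_cell])),
    cdr3_aa = as.vector(rbind(cdr3_aa1[ci_of_cell], cdr3_aa2[ci_of_cell])),
    productive = TRUE,
    umis = 1L + rpois(2L * n_cells, 3),
    c_gene = as.vector(rbind(c1[ci_of_cell], c2[ci_of_cell])),
    raw_clonotype_id = rep(truth_cells$clone_id, each = 2),
    stringsAsFactors = FALSE)

  # ---- write ----------------------------------------------------------
  contig_path <- file.path(dir, if (dialect == "TENX_CSV") "contigs.csv"
                           else "contigs_airr.tsv")
  write_contig_table(contigs, contig_path, dialect)
  write_expression_matrix(expr, dir)
  meta_path <- file.path(dir, "metadata.tsv")
  write.table(cells, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(clones = truth_clones, cells = truth_cells)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, dataframe = "columns", digits = NA)

  invisible(list(
    paths = list(contigs = contig_path, mtx = file.path(dir, "matrix.mtx"),
                 features = file.path(dir, "features.tsv"),
                 barcodes = file.path(dir, "barcodes.tsv"),
                 metadata = meta_path, truth = truth_path),
    dialect = dialect, truth = truth, expr = expr, cells = cells,
    contigs = contigs))
}

#' Read a truth file written by [simulate_cohort()]
#'
#' @param path `truth.json` path.
#' @return List with `clones` and `cells` data frames.
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(clones = as.data.frame(raw$clones, stringsAsFactors = FALSE),
       cells = as.data.frame(raw$cells, stringsAsFactors = FALSE))
}

#' Evaluate pipeline pattern calls against simulation truth
#'
#' Maps each truth clone to the pipeline clone its member cells were
#' assigned to (via barcodes), and compares predicted with true patterns
#' over the truth's expanded clones.
#'
#' @param clone_patterns Output of [classify_clones()].
#' @param assignments Clone assignments used to build the table.
#' @param truth Truth list from [simulate_cohort()] / [read_truth()].
#' @return List with `pattern_accuracy` (fraction of expanded truth clones
#'   whose predicted pattern equals the true one), `confusion` (true x
#'   predicted table) and `n_clones`.
#' @export
evaluate_against_truth <- function(clone_patterns, assignments, truth) {
  exp_clones <- truth$clones[truth$clones$expanded, , drop = FALSE]
  if (nrow(exp_clones) == 0) stop_validation("truth contains no expanded clones")
  # truth clone -> pipeline clone via member barcodes
  pipe_of_bc <- setNames(assignments$clone_id, assignments$barcode)
  pred_of <- setNames(clone_patterns$pattern, clone_patterns$clone_id)
  truth_key <- paste(truth$cells$subject_id, truth$cells$clone_id)
  pred <- vapply(seq_len(nrow(exp_clones)), function(i) {
    bcs <- truth$cells$barcode[truth_key == paste(exp_clones$subject_id[[i]],
                                                  exp_clones$clone_id[[i]])]
    pids <- unique(pipe_of_bc[bcs])
    pids <- pids[!is.na(pids)]
    if (length(pids) == 0) return("UNCLASSIFIED")
    if (length(pids) > 1) {
      stop_integrity("truth clone ", exp_clones$clone_id[[i]],
                     " maps to multiple pipeline clones (cohort mismatch?)")
    }
    lab <- pred_of[pids]
    if (is.na(lab)) "UNCLASSIFIED" else unname(lab)
  }, character(1))
  confusion <- table(truth = exp_clones$pattern,
                     predicted = factor(pred, levels = PATTERN_LEVELS))
  list(pattern_accuracy = mean(pred == exp_clones$pattern),
       confusion = confusion, n_clones = nrow(exp_clones))
}
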