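# Independent per-clone loop oracle for the migration/transition machinery:
# per subject, per clone, entropy of its category distribution weighted by
# the clone's share of stratum cells; subjects then combined weighted by
# stratum cell count.
oracle_index <- function(cells, category_col, categories, normalize) {
  subj_vals <- c()
  subj_n <- c()
  for (s in unique(cells$subject_id)) {
    sc <- cells[cells$subject_id == s, ]
    total <- nrow(sc)
    acc <- 0
    for (cl in unique(sc$clone_id)) {
      cc <- sc[sc$clone_id == cl, ]
      h <- 0
      for (cat in categories) {
        p <- sum(cc[[category_col]] == cat) / nrow(cc)
        if (p > 0) h <- h - p * log(p)
      }
      acc <- acc + (nrow(cc) / total) * h
    }
    if (normalize) acc <- acc / log(length(categories))
    subj_vals <- c(subj_vals, acc)
    subj_n <- c(subj_n, total)
  }
  sum(subj_vals * subj_n) / sum(subj_n)
}

test_that("Shannon entropy matches closed forms and validates input", {
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  expect_equal(shannon_entropy(rep(1 / 3, 3)), log(3))
  for (k in 2:6) expect_equal(shannon_entropy(rep(1 / k, k)), log(k))
  expect_error(shannon_entropy(c(-0.1, 1.1)), "nonnegative")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("expansion index spans its degenerate and hand-computed cases", {
  expect_equal(expansion_index(rep(1, 10)), 0)   # 10 singletons
  expect_equal(expansion_index(10), 1)           # monoclonal
  expect_equal(expansion_index(1), 0)            # single singleton
  # sizes (9, 1): 1 - H(0.9, 0.1) / ln 2
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  expect_equal(expansion_index(c(9, 1)), 1 - h / log(2))
  expect_equal(expansion_index(c(9, 1)), 0.5310, tolerance = 1e-4)
  expect_error(expansion_index(integer(0)), "empty")
})

test_that("migration and transition hit their trivial closed forms", {
  # every clone confined to one compartment -> 0
  cells <- make_cells(sprintf("BC%d", 1:6),
                      compartment = rep(c("LUNG", "BALF"), each = 3))
  asg <- data.frame(barcode = cells$barcode, subject_id = "S1",
                    clone_id = rep(c("S1:a", "S1:b"), each = 3),
                    receptor_type = "TCR", isotype = NA_character_,
                    stringsAsFactors = FALSE)
  tab <- build_clone_table(asg, cells)
  expect_equal(migration_index(tab)$value, 0)

  # single clone split 5/5 between LUNG and BALF, pairwise normalized -> 1
  cells2 <- make_cells(sprintf("BC%d", 1:10),
                       compartment = rep(c("LUNG", "BALF"), 5))
  asg2 <- data.frame(barcode = cells2$barcode, subject_id = "S1",
                     clone_id = "S1:solo", receptor_type = "TCR",
                     isotype = NA_character_, stringsAsFactors = FALSE)
  tab2 <- build_clone_table(asg2, cells2)
  mig <- migration_index(tab2, compartments = c("LUNG", "BALF"))
  expect_equal(mig$value, 1, tolerance = 1e-12)

  # clones never spanning two clusters -> transition 0
  expect_equal(transition_index(tab)$value, 0)
  # one clone split equally between two clusters -> normalized pairwise 1
  cells3 <- make_cells(sprintf("BC%d", 1:8),
                       cluster = rep(c("T8_rm", "Cycling"), 4))
  asg3 <- data.frame(barcode = cells3$barcode, subject_id = "S1",
                     clone_id = "S1:solo", receptor_type = "TCR",
                     isotype = NA_character_, stringsAsFactors = FALSE)
  tab3 <- build_clone_table(asg3, cells3)
  expect_equal(transition_index(tab3, clusters = c("T8_rm", "Cycling"))$value,
               1, tolerance = 1e-12)
})

test_that("indices equal the independent loop oracle on random tables", {
  set.seed(55)
  for (rep in 1:20) {
    tab <- random_clone_table(sample(5:20, 1), n_subjects = sample(1:3, 1))
    # migration, all compartments, per cluster
    for (cl in unique(tab$cells$cluster)) {
      sub <- tab$cells[tab$cells$cluster == cl, ]
      got <- migration_index(tab, clusters = cl)$value
      expect_equal(got, oracle_index(sub, "compartment",
                                     c("LUNG", "BALF", "PBMC"), TRUE),
                   tolerance = 1e-12)
    }
    # pairwise migration
    sub <- tab$cells[tab$cells$compartment %in% c("LUNG", "BALF") &
                       tab$cells$cluster == tab$cells$cluster[1], ]
    if (nrow(sub) > 0) {
      got <- migration_index(tab, clusters = tab$cells$cluster[1],
                             compartments = c("LUNG", "BALF"))$value
      expect_equal(got, oracle_index(sub, "compartment", c("LUNG", "BALF"),
                                     TRUE), tolerance = 1e-12)
    }
    # transition over all clusters
    cats <- sort(unique(tab$cells$cluster))
    got <- transition_index(tab)$value
    expect_equal(got, oracle_index(tab$cells, "cluster", cats, TRUE),
                 tolerance = 1e-12)
    # expansion per cluster vs direct formula
    cl1 <- sort(unique(tab$cells$cluster))[1]
    sizes_by_subj <- lapply(split(tab$cells[tab$cells$cluster == cl1, ],
                                  tab$cells$subject_id[tab$cells$cluster == cl1]),
                            function(sc) as.integer(table(sc$clone_id)))
    vals <- vapply(sizes_by_subj, expansion_index, numeric(1))
    ns <- vapply(sizes_by_subj, sum, numeric(1))
    expect_equal(expansion_index_by_cluster(tab, clusters = cl1)$value,
                 sum(vals * ns) / sum(ns), tolerance = 1e-12)
  }
})

test_that("pairwise migration is consistent under compartment restriction", {
  set.seed(66)
  tab <- random_clone_table(25, n_subjects = 2)
  full <- migration_index(tab, compartments = c("LUNG", "BALF"))
  pruned_cells <- tab$cells[tab$cells$compartment != "PBMC", ]
  asg <- data.frame(barcode = pruned_cells$barcode,
                    subject_id = pruned_cells$subject_id,
                    clone_id = pruned_cells$clone_id,
                    receptor_type = "TCR", isotype = NA_character_,
                    stringsAsFactors = FALSE)
  meta <- make_cells(pruned_cells$barcode, subject_id = pruned_cells$subject_id,
                     compartment = pruned_cells$compartment,
                     cluster = pruned_cells$cluster)
  pruned <- migration_index(build_clone_table(asg, meta),
                            compartments = c("LUNG", "BALF"))
  expect_equal(full$value, pruned$value, tolerance = 1e-12)
})

test_that("indices are invariant to clone relabelling and count scaling", {
  set.seed(77)
  tab <- random_clone_table(12)
  base_mig <- migration_index(tab)$value
  base_exp <- expansion_index_by_cluster(tab)$value

  # relabel clone ids
  relab <- tab
  map <- setNames(sprintf("S1:z%02d", seq_along(unique(tab$cells$clone_id))),
                  unique(tab$cells$clone_id))
  relab$cells$clone_id <- unname(map[tab$cells$clone_id])
  relab$clones$clone_id <- unname(map[tab$clones$clone_id])
  expect_equal(migration_index(relab)$value, base_mig, tolerance = 1e-12)

  # triple every cell (uniform integer scaling of all clone counts)
  cells3 <- tab$cells[rep(seq_len(nrow(tab$cells)), each = 3), ]
  cells3$barcode <- sprintf("%s_r%d", cells3$barcode, 1:3)
  asg3 <- data.frame(barcode = cells3$barcode, subject_id = cells3$subject_id,
                     clone_id = cells3$clone_id, receptor_type = "TCR",
                     isotype = NA_character_, stringsAsFactors = FALSE)
  meta3 <- make_cells(cells3$barcode, subject_id = cells3$subject_id,
                      compartment = cells3$compartment,
                      cluster = cells3$cluster)
  tab3 <- build_clone_table(asg3, meta3)
  expect_equal(migration_index(tab3)$value, base_mig, tolerance = 1e-12)
  expect_equal(expansion_index_by_cluster(tab3)$value, base_exp,
               tolerance = 1e-12)
})

test_that("per-subject weighted aggregation equals pooled computation", {
  # clone namespaces are subject-scoped, so the weighted mean of per-subject
  # values must equal a single pooled pass over all cells
  set.seed(88)
  tab <- random_clone_table(15, n_subjects = 3)
  agg <- migration_index(tab)
  pooled_cells <- tab$cells
  pooled_cells$subject_id <- "pooledsubject"  # legitimate only because clone
  asg <- data.frame(barcode = pooled_cells$barcode,      # ids stay distinct
                    subject_id = "pooledsubject",
                    clone_id = pooled_cells$clone_id, receptor_type = "TCR",
                    isotype = NA_character_, stringsAsFactors = FALSE)
  meta <- make_cells(pooled_cells$barcode, subject_id = "pooledsubject",
                     compartment = pooled_cells$compartment,
                     cluster = pooled_cells$cluster)
  pooled <- migration_index(build_clone_table(asg, meta))
  expect_equal(agg$value, pooled$value, tolerance = 1e-12)
})

test_that("a 50/50 lung-BALF cohort yields unit migration by construction", {
  # clones allocated exactly half lung, half BALF
  n <- 20
  cells <- make_cells(sprintf("BC%03d", 1:(4 * n)),
                      compartment = rep(c("LUNG", "BALF"), 2 * n))
  asg <- data.frame(barcode = cells$barcode, subject_id = "S1",
                    clone_id = rep(sprintf("S1:c%02d", 1:n), each = 4),
                    receptor_type = "TCR", isotype = NA_character_,
                    stringsAsFactors = FALSE)
  tab <- build_clone_table(asg, cells)
  mig <- migration_index(tab, compartments = c("LUNG", "BALF"))
  expect_equal(mig$value, 1, tolerance = 1e-12)
})
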