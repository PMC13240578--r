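test_that("10x contig CSV parses productive flags and rejects bad headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "barcode,is_cell,chain,v_gene,j_gene,cdr3,cdr3_nt,productive,umis,c_gene,raw_clonotype_id",
    "BC1,True,TRB,TRBV7,TRBJ2-1,CASSF,TGTGCCAGCAGT,True,4,,clonotype1",
    "BC1,True,TRA,TRAV1,TRAJ33,CAVR,TGTGCTGTGAGA,true,2,,clonotype1",
    "BC2,True,TRB,TRBV9,TRBJ1-2,CASRF,TGTGCCAGTCGT,None,1,,clonotype2"), path)
  recs <- read_contig_table(path, "TENX_CSV")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$productive, c(TRUE, TRUE, FALSE))
  expect_equal(recs$cdr3_aa[1], "CASSF")   # 10x 'cdr3' column is amino acid
  expect_equal(recs$umis, c(4L, 2L, 1L))

  # header only -> format error
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("barcode,chain,v_gene,j_gene,cdr3,cdr3_nt,productive,umis,c_gene,raw_clonotype_id",
             path2)
  expect_error(read_contig_table(path2, "TENX_CSV"), "no data rows")

  # missing mandatory column named in the error
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("barcode,chain,v_gene,j_gene,cdr3,productive,umis,c_gene,raw_clonotype_id",
               "BC1,TRB,TRBV7,TRBJ2-1,CASSF,True,4,,clonotype1"), path3)
  expect_error(read_contig_table(path3, "TENX_CSV"), "cdr3_nt")
})

test_that("AIRR TSV round-trips through write+read identically", {
  contigs <- make_contigs(
    barcode = c("BC1", "BC1", "BC2", "BC3", "BC3"),
    chain = c("TRB", "TRA", "TRB", "IGH", "IGK"),
    v_gene = c("TRBV7", "TRAV2", "TRBV9", "IGHV1-2", "IGKV3-11"),
    cdr3_nt = c("TGTAAA", "TGTCCC", "TGTGGG", "TGTTTT", "TGTACG"),
    cdr3_aa = c("CK", "CP", "CG", "CF", "CT"),
    productive = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    umis = c(5L, 3L, 1L, 7L, 2L),
    c_gene = c("", "", "", "IGHA1", "IGKC"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contig_table(contigs, path, "AIRR_TSV")
  back <- read_contig_table(path, "AIRR_TSV")
  for (col in c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt", "cdr3_aa",
                "productive", "umis", "c_gene")) {
    expect_equal(back[[col]], contigs[[col]], info = col)
  }
})

test_that("clonotype collapse builds subject-scoped keys from productive chains", {
  cells <- make_cells(c("BC1", "BC2", "BC3", "BC4"),
                      subject_id = c("S1", "S1", "S2", "S1"))
  contigs <- rbind(
    make_contigs("BC1", chain = c("TRB", "TRA"),
                 v_gene = c("TRBV7", "TRAV1"), cdr3_nt = c("TGTAAA", "TGTCCC")),
    make_contigs("BC2", chain = c("TRA", "TRB"),  # same chains, other order
                 v_gene = c("TRAV1", "TRBV7"), cdr3_nt = c("TGTCCC", "TGTAAA")),
    make_contigs("BC3", chain = c("TRB", "TRA"),  # same chains, other subject
                 v_gene = c("TRBV7", "TRAV1"), cdr3_nt = c("TGTAAA", "TGTCCC")),
    make_contigs("BC4", productive = FALSE))      # no productive chain
  asg <- collapse_to_clonotypes(contigs, cells)
  expect_setequal(asg$barcode, c("BC1", "BC2", "BC3"))
  expect_equal(asg$clone_id[asg$barcode == "BC1"],
               asg$clone_id[asg$barcode == "BC2"])
  expect_false(asg$clone_id[asg$barcode == "BC3"] ==
                 asg$clone_id[asg$barcode == "BC1"])
  expect_true(startsWith(asg$clone_id[asg$barcode == "BC3"], "S2:"))
})

test_that("collapse is invariant to row order and drops unknown barcodes", {
  cells <- make_cells(c("BC1", "BC2"))
  contigs <- rbind(
    make_contigs("BC1", chain = c("TRB", "TRA"), cdr3_nt = c("TGTAAA", "TGTCCC")),
    make_contigs("BC2", chain = "TRB", cdr3_nt = "TGTGGG"),
    make_contigs("BCX", chain = "TRB", cdr3_nt = "TGTTTT"))
  expect_message(a1 <- collapse_to_clonotypes(contigs, cells), "dropped")
  a2 <- suppressMessages(
    collapse_to_clonotypes(contigs[rev(seq_len(nrow(contigs))), ], cells))
  expect_equal(a1[order(a1$barcode), ], a2[order(a2$barcode), ],
               ignore_attr = TRUE)
  expect_false("BCX" %in% a1$barcode)
})

test_that("more than two productive chains of one locus keep the top-2 by UMIs", {
  cells <- make_cells("BC1")
  contigs <- make_contigs("BC1", chain = "TRB",
                          cdr3_nt = c("TGTAAA", "TGTCCC", "TGTGGG"),
                          umis = c(9L, 7L, 1L))
  asg <- collapse_to_clonotypes(contigs, cells)
  expect_true(grepl("TGTAAA", asg$clone_id))
  expect_true(grepl("TGTCCC", asg$clone_id))
  expect_false(grepl("TGTGGG", asg$clone_id))
})

test_that("a barcode mapped to two subjects is an integrity error", {
  cells <- rbind(make_cells("BC1", subject_id = "S1"),
                 make_cells("BC1", subject_id = "S2"))
  contigs <- make_contigs("BC1")
  expect_error(collapse_to_clonotypes(contigs, cells), "more than one subject")
})

test_that("AA_VJ and RAW_ID policies change the key as declared", {
  cells <- make_cells(c("BC1", "BC2"))
  # same amino acid CDR3, different nucleotide CDR3
  contigs <- rbind(
    make_contigs("BC1", cdr3_nt = "TGTAAAGCA", cdr3_aa = "CKA",
                 raw_clonotype_id = "ct1"),
    make_contigs("BC2", cdr3_nt = "TGCAAAGCC", cdr3_aa = "CKA",
                 raw_clonotype_id = "ct2"))
  nt <- collapse_to_clonotypes(contigs, cells, policy = "NT_VJ")
  aa <- collapse_to_clonotypes(contigs, cells, policy = "AA_VJ")
  raw <- collapse_to_clonotypes(contigs, cells, policy = "RAW_ID")
  expect_length(unique(nt$clone_id), 2)
  expect_length(unique(aa$clone_id), 1)
  expect_equal(sort(raw$clone_id), c("S1:ct1", "S1:ct2"))
})

test_that("BCR isotype comes from the highest-UMI heavy chain", {
  cells <- make_cells(c("BC1", "BC2"))
  contigs <- rbind(
    make_contigs("BC1", chain = c("IGH", "IGK"),
                 cdr3_nt = c("TGTAAA", "TGTCCC"),
                 c_gene = c("IGHA1", "IGKC")),
    make_contigs("BC2", chain = "IGK", cdr3_nt = "TGTGGG", c_gene = "IGKC"))
  asg <- collapse_to_clonotypes(contigs, cells)
  expect_equal(asg$receptor_type, c("BCR", "BCR"))
  expect_equal(asg$isotype[asg$barcode == "BC1"], "IGHA1")
  expect_true(is.na(asg$isotype[asg$barcode == "BC2"]))
})

test_that("no clone id ever spans two subjects on random fixtures", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 40
    cells <- make_cells(sprintf("BC%03d", 1:n),
                        subject_id = sample(c("S1", "S2", "S3"), n, TRUE))
    # deliberately reuse a small CDR3 pool so chains recur across subjects
    contigs <- make_contigs(cells$barcode,
                            cdr3_nt = sample(c("TGTAAA", "TGTCCC", "TGTGGG"),
                                             n, TRUE))
    asg <- collapse_to_clonotypes(contigs, cells)
    spans <- tapply(asg$subject_id, asg$clone_id,
                    function(s) length(unique(s)))
    expect_true(all(spans == 1))
  }
})

test_that("expression matrix reads MTX + sidecars and round-trips", {
  set.seed(5)
  m <- matrix(rpois(20, 2), nrow = 5)
  expr <- make_expr(m, normalize = FALSE)
  dir <- withr::local_tempdir()
  write_expression_matrix(expr, dir)
  back <- read_expression_matrix(file.path(dir, "matrix.mtx"),
                                 file.path(dir, "features.tsv"),
                                 file.path(dir, "barcodes.tsv"))
  expect_equal(as.matrix(back$counts), as.matrix(expr$counts))
  expect_equal(dim(back$counts), c(5L, 4L))
})

test_that("sidecar dimension mismatches and duplicate symbols are handled", {
  m <- matrix(1:20, nrow = 5)
  expr <- make_expr(m, normalize = FALSE)
  dir <- withr::local_tempdir()
  write_expression_matrix(expr, dir)
  # 6 features vs 5 matrix rows
  writeLines(sprintf("G%02d", 1:6), file.path(dir, "features.tsv"))
  expect_error(read_expression_matrix(file.path(dir, "matrix.mtx"),
                                      file.path(dir, "features.tsv"),
                                      file.path(dir, "barcodes.tsv")),
               "feature sidecar")
  # duplicated symbols get deterministic suffixes in file order
  writeLines(c("ACTB", "ACTB", "CD8A", "ACTB", "CD8A"),
             file.path(dir, "features.tsv"))
  back <- read_expression_matrix(file.path(dir, "matrix.mtx"),
                                 file.path(dir, "features.tsv"),
                                 file.path(dir, "barcodes.tsv"))
  expect_equal(rownames(back$counts),
               c("ACTB", "ACTB.1", "CD8A", "ACTB.2", "CD8A.1"))
})

test_that("synthetic cohort files round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(cohort_config(n_subjects = 1, clones_per_subject = 20),
                         dir, seed = 4)
  contigs <- read_contig_table(sim$paths$contigs, "TENX_CSV")
  expect_equal(nrow(contigs), nrow(sim$contigs))
  expect_equal(contigs$cdr3_nt, sim$contigs$cdr3_nt)
  expr <- read_expression_matrix(sim$paths$mtx, sim$paths$features,
                                 sim$paths$barcodes)
  expect_equal(as.matrix(expr$counts), as.matrix(sim$expr$counts))
  cells <- read_cell_metadata(sim$paths$metadata)
  expect_equal(cells$barcode, sim$cells$barcode)

  # AIRR dialect round-trips too
  dir2 <- withr::local_tempdir()
  sim2 <- simulate_cohort(cohort_config(n_subjects = 1, clones_per_subject = 10),
                          dir2, seed = 4, dialect = "AIRR_TSV")
  back <- read_contig_table(sim2$paths$contigs, "AIRR_TSV")
  expect_equal(back$cdr3_nt, sim2$contigs$cdr3_nt)
  expect_equal(back$productive, sim2$contigs$productive)
})
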