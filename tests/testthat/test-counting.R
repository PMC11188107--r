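make_refs <- function() {
  list(whitelist = barcode_whitelist(c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG")),
       tags = tag_reference(c("CD4", "CD8"),
                            c("ACGTACGTACGTACGT", "TGCATGCATGCATGCA")))
}

test_that("assign_reads resolves exact reads and tallies failures", {
  refs <- make_refs()
  layoutless <- data.frame(
    read_id = c("r1", "r2", "r3"),
    cell_window = c("AAAAAAAA",          # exact whitelist hit
                    "AATTTTAA",          # 2+ mismatches from everything
                    "CCCCCCCC"),
    umi_window = c("ACAC", "ACAC", "GTGT"),
    tag_window = c("ACGTACGTACGTACGT", "ACGTACGTACGTACGT",
                   "AAAAAAAACCCCCCCC"),  # unmatched tag
    stringsAsFactors = FALSE)
  asg <- assign_reads(layoutless, refs$whitelist, refs$tags)
  expect_identical(nrow(asg$molecules), 1L)
  expect_identical(asg$molecules$cell_index, 1L)
  expect_identical(asg$molecules$tag_index, 1L)
  expect_identical(asg$molecules$umi, "ACAC")
  expect_identical(asg$tallies[["n_cell_unmatched"]], 1L)
  expect_identical(asg$tallies[["n_tag_unmatched"]], 1L)
})

test_that("cell-side fate takes precedence for doubly failing reads", {
  refs <- make_refs()
  rec <- data.frame(read_id = "r1", cell_window = "TTTTTTTT",
                    umi_window = "ACAC", tag_window = "AAAACCCCAAAACCCC",
                    stringsAsFactors = FALSE)
  asg <- assign_reads(rec, refs$whitelist, refs$tags)
  expect_identical(asg$tallies[["n_cell_unmatched"]], 1L)
  expect_identical(asg$tallies[["n_tag_unmatched"]], 0L)
})

test_that("build_matrix tallies molecules and keeps full label sets", {
  refs <- make_refs()
  mol <- molecule_assignments(c(1, 1, 2), c(1, 1, 2), c("AAAA", "CCCC", "GGGG"))
  m <- build_matrix(mol, refs$whitelist, refs$tags)
  expect_identical(dim(m), c(2L, 3L))          # all tags x all whitelist cells
  expect_equal(m["CD4", "AAAAAAAA"], 2)
  expect_equal(m["CD8", "CCCCCCCC"], 1)
  expect_equal(sum(m), 3)

  empty <- build_matrix(mol[0, ], refs$whitelist, refs$tags)
  expect_identical(dim(empty), c(2L, 3L))
  expect_equal(sum(empty), 0)

  dropped <- build_matrix(mol, refs$whitelist, refs$tags, drop_zero_cells = TRUE)
  expect_identical(colnames(dropped), c("AAAAAAAA", "CCCCCCCC"))

  set.seed(41)
  for (i in 1:5) {                             # tally oracle
    mol <- rand_molecules(100, n_cells = 3, n_tags = 2)
    m <- build_matrix(mol, refs$whitelist, refs$tags)
    tab <- table(factor(mol$tag_index, 1:2), factor(mol$cell_index, 1:3))
    expect_equal(unname(as.matrix(m)), unname(unclass(tab)[, ]))
  }
})

sim_run <- function(cfg, td, out = NULL, ...) {
  ds <- generate_dataset(cfg, td)
  res <- run_pipeline(run_config(ds$paths$cell_fastq, ds$paths$tag_fastq,
                                 ds$paths$whitelist, ds$paths$tags,
                                 out_dir = out, ...))
  list(ds = ds, res = res)
}

test_that("zero-error, zero-duplication runs reproduce the truth matrix", {
  td <- withr::local_tempdir()
  r <- sim_run(sim_config(n_cells = 40, n_tags = 6, mean_molecules = 3,
                          seed = 42), td)
  expect_identical(as.matrix(r$res$matrix), as.matrix(r$ds$truth_matrix))
  expect_equal(r$res$report$n_counted, sum(r$ds$truth_matrix))
  expect_identical(r$res$report$n_cell_unmatched +
                     r$res$report$n_tag_unmatched, 0L)
})

test_that("exact dedup removes exactly the injected duplicates", {
  td <- withr::local_tempdir()
  r <- sim_run(sim_config(n_cells = 40, n_tags = 6, mean_molecules = 3,
                          duplication_rate = 0.3, seed = 43), td)
  expect_identical(r$res$report$n_umi_duplicates_removed,
                   sum(r$ds$provenance$is_duplicate))
  expect_identical(as.matrix(r$res$matrix), as.matrix(r$ds$truth_matrix))
})

test_that("the pipeline is chunk-invariant and byte-deterministic", {
  td <- withr::local_tempdir()
  ds <- generate_dataset(sim_config(n_cells = 30, n_tags = 5,
                                    mean_molecules = 2, duplication_rate = 0.2,
                                    substitution_error_rate = 0.01, seed = 44),
                         file.path(td, "sim"))
  outs <- file.path(td, c("o1", "o2", "o3"))
  for (i in 1:3) {
    chunk <- c(100000L, 1L, 100000L)[i]
    run_pipeline(run_config(ds$paths$cell_fastq, ds$paths$tag_fastq,
                            ds$paths$whitelist, ds$paths$tags,
                            out_dir = outs[i],
                            match = match_policy(chunk_size = chunk)))
  }
  for (f in c("matrix.mtx.gz", "features.tsv.gz", "barcodes.tsv.gz",
              "run_report.txt")) {
    b1 <- readBin(file.path(outs[1], f), "raw", 1e6)
    expect_identical(readBin(file.path(outs[2], f), "raw", 1e6), b1)
    expect_identical(readBin(file.path(outs[3], f), "raw", 1e6), b1)
  }
})

test_that("read fates always sum to the total, even on messy runs", {
  td <- withr::local_tempdir()
  # conservation is asserted inside run_report(); build reports from runs
  # with malformed reads, heavy errors and heavy duplication
  cfgs <- list(
    sim_config(n_cells = 25, n_tags = 4, mean_molecules = 2, seed = 45,
               malformed_rate = 0.05),
    sim_config(n_cells = 25, n_tags = 4, mean_molecules = 2, seed = 46,
               substitution_error_rate = 0.10, duplication_rate = 0.5,
               malformed_rate = 0.02)
  )
  for (k in seq_along(cfgs)) {
    r <- sim_run(cfgs[[k]], file.path(td, paste0("s", k)))
    rep <- r$res$report
    expect_identical(rep$n_malformed + rep$n_cell_unmatched +
                       rep$n_cell_ambiguous + rep$n_tag_unmatched +
                       rep$n_tag_ambiguous + rep$n_umi_duplicates_removed +
                       rep$n_counted,
                     rep$n_reads_total)
    expect_identical(rep$n_reads_total, nrow(r$ds$provenance))
    expect_identical(rep$n_malformed, sum(r$ds$provenance$is_malformed))
  }
  expect_error(run_report(n_reads_total = 5, n_counted = 4), "conservation")
})

test_that("reads with at most one error per window are always recovered", {
  td <- withr::local_tempdir()
  r <- sim_run(sim_config(n_cells = 50, n_tags = 8, mean_molecules = 3,
                          substitution_error_rate = 0.01, seed = 47), td)
  prov <- r$ds$provenance
  # tag-read errors can fall in the oligo or the UMI window; <=1 error in
  # the whole tag read implies <=1 in the oligo window
  clean <- prov$n_errors_cell_read <= 1 & prov$n_errors_tag_read <= 1
  assigned <- r$res$report$n_counted + r$res$report$n_umi_duplicates_removed
  expect_gte(assigned, sum(clean))

  # overall recovery tracks the analytic expectation for the error model:
  # a read survives iff both 16 nt windows carry <= 1 substitution
  p_win <- function(L, e) (1 - e)^L + L * e * (1 - e)^(L - 1)
  p <- p_win(16, 0.01)^2 * p_win(12, 0) # UMI errors do not drop reads
  n <- nrow(prov)
  expect_lt(abs(assigned / n - p), 3 * sqrt(p * (1 - p) / n) + 0.01)
})

test_that("permuting input read order leaves the count matrix unchanged", {
  td <- withr::local_tempdir()
  ds <- generate_dataset(sim_config(n_cells = 20, n_tags = 4,
                                    mean_molecules = 2, duplication_rate = 0.3,
                                    seed = 48), file.path(td, "sim"))
  pairs <- read_fastq_pairs(ds$paths$cell_fastq, ds$paths$tag_fastq, ds$layout)
  set.seed(48)
  perm <- sample.int(nrow(pairs$records))
  shuf <- pairs$records[perm, ]
  wl <- read_whitelist(ds$paths$whitelist)
  tr <- read_tag_reference(ds$paths$tags)
  count_of <- function(rec) {
    asg <- assign_reads(rec, wl, tr)
    build_matrix(dedup_exact(asg$molecules)$kept, wl, tr)
  }
  expect_identical(as.matrix(count_of(pairs$records)), as.matrix(count_of(shuf)))
})
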