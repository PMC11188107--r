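#' Construct a run report of read fates
#'
#' Every read pair is assigned exactly one fate. The conservation invariant
#' — fates summing to the total — is asserted at construction, so a report
#' can never silently lose reads. For reads failing both the cell and the
#' tag match, the cell-side fate takes precedence.
#'
#' @param n_reads_total,n_malformed,n_cell_unmatched,n_cell_ambiguous,n_tag_unmatched,n_tag_ambiguous,n_umi_duplicates_removed,n_counted
#'   Non-negative integer tallies.
#' @return A `run_report` object (named integer list).
#' @export
run_report <- function(n_reads_total = 0L, n_malformed = 0L,
                       n_cell_unmatched = 0L, n_cell_ambiguous = 0L,
                       n_tag_unmatched = 0L, n_tag_ambiguous = 0L,
                       n_umi_duplicates_removed = 0L, n_counted = 0L) {
  r <- lapply(list(
    n_reads_total = n_reads_total, n_malformed = n_malformed,
    n_cell_unmatched = n_cell_unmatched, n_cell_ambiguous = n_cell_ambiguous,
    n_tag_unmatched = n_tag_unmatched, n_tag_ambiguous = n_tag_ambiguous,
    n_umi_duplicates_removed = n_umi_duplicates_removed,
    n_counted = n_counted), as.integer)
  if (any(vapply(r, function(v) is.na(v) || v < 0L, logical(1))))
    stop("run report tallies must be non-negative integers")
  fates <- sum(unlist(r[-1]))
  if (fates != r$n_reads_total)
    stop(sprintf(
      "read-fate conservation violated: fates sum to %d but %d reads were seen",
      fates, r$n_reads_total))
  structure(r, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Run report (read fates):\n")
  for (nm in names(x))
    cat(sprintf("  %-26s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Write a run report as a machine-readable key:value file
#' @param report A [run_report()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  writeLines(sprintf("%s\t%d", names(report), unlist(report)), path)
  invisible(path)
}

#' Read back a run report file written by [write_run_report()]
#' @param path Path to the key:value file.
#' @return A [run_report()].
#' @export
read_run_report <- function(path) {
  kv <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  do.call(run_report, as.list(stats::setNames(kv[[2]], kv[[1]])))
}

#' Assign reads to cells and tags
#'
#' Matches each record's cell window against the whitelist under the Hamming
#' rule and its tag window against the reference oligos under the normalized
#' edit-ratio rule (cutoffs and chunking from one [match_policy()]). Only
#' reads uniquely assigned on both sides become molecules; every other read
#' is tallied, with the cell-side fate taking precedence when both sides
#' fail.
#'
#' @param records The `records` data.frame from [read_fastq_pairs()].
#' @param whitelist A [barcode_whitelist()].
#' @param tags A [tag_reference()].
#' @param policy A [match_policy()].
#' @return List with `molecules` (a [molecule_assignments()] table) and
#'   `tallies` (named integer vector of the four failure fates).
#' @export
assign_reads <- function(records, whitelist, tags, policy = match_policy()) {
  cell_res <- match_batch(records$cell_window, unclass(whitelist),
                          modifyList(policy, list(metric = "hamming")))
  tag_res <- match_batch(records$tag_window, tags$sequences,
                         modifyList(policy, list(metric = "edit_ratio")))
  cell_ok <- cell_res$status == "assigned"
  tag_ok <- tag_res$status == "assigned"
  both <- cell_ok & tag_ok
  tallies <- c(
    n_cell_unmatched = sum(cell_res$status == "unmatched"),
    n_cell_ambiguous = sum(cell_res$status == "ambiguous"),
    n_tag_unmatched = sum(cell_ok & tag_res$status == "unmatched"),
    n_tag_ambiguous = sum(cell_ok & tag_res$status == "ambiguous")
  )
  molecules <- molecule_assignments(
    cell_index = cell_res$reference_index[both],
    tag_index = tag_res$reference_index[both],
    umi = records$umi_window[both],
    order = which(both)
  )
  list(molecules = molecules, tallies = tallies)
}

#' Build the sparse cell-by-tag count matrix
#'
#' Counts deduplicated molecules per (cell, tag) pair. The matrix keeps the
#' full label sets — all whitelist barcodes and all reference tags — even
#' when a row or column is all zero, so its dimensions are always
#' `length(tags) x length(whitelist)` (features as rows, the CellRanger
#' orientation). Set `drop_zero_cells = TRUE` to keep only barcodes with at
#' least one count.
#'
#' @param molecules A deduplicated [molecule_assignments()] table.
#' @param whitelist A [barcode_whitelist()].
#' @param tags A [tag_reference()].
#' @param drop_zero_cells Drop all-zero barcode columns.
#' @return A `dgCMatrix`, tags as rows, cell barcodes as columns.
#' @export
build_matrix <- function(molecules, whitelist, tags, drop_zero_cells = FALSE) {
  m <- Matrix::sparseMatrix(
    i = molecules$tag_index, j = molecules$cell_index,
    x = rep(1L, nrow(molecules)),
    dims = c(length(tags$names), length(whitelist)),
    dimnames = list(tags$names, as.character(unclass(whitelist)))
  )
  if (drop_zero_cells) m <- m[, Matrix::colSums(m) > 0, drop = FALSE]
  methods::as(m, "CsparseMatrix")
}

#' Assemble a full pipeline configuration
#'
#' Collects and validates everything one counting run needs. The
#' configuration is serialised verbatim (JSON) into the output directory for
#' provenance; together with the input files it reproduces the run
#' bit-for-bit, since the pipeline contains no randomness.
#'
#' @param cell_fastq,tag_fastq Character vectors of paired FASTQ paths
#'   (lane order = list order).
#' @param whitelist Path to the cell-barcode whitelist.
#' @param tags Path to the tag-oligo reference table.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param layout A [read_layout()].
#' @param match A [match_policy()].
#' @param dedup A [dedup_policy()].
#' @param rc_barcodes Reverse-complement cell-barcode windows before
#'   whitelist matching (strand-convention mismatch between ATAC cell calls
#'   and manufacturer whitelists).
#' @param strip_suffix Strip a trailing `-<digits>` from whitelist entries.
#' @param drop_zero_cells Drop all-zero barcode columns from the output.
#' @param verbose Log per-stage tallies to the console.
#' @return A `run_config` object.
#' @export
run_config <- function(cell_fastq, tag_fastq, whitelist, tags,
                       out_dir = NULL, layout = read_layout(),
                       match = match_policy(), dedup = dedup_policy(),
                       rc_barcodes = FALSE, strip_suffix = TRUE,
                       drop_zero_cells = FALSE, verbose = FALSE) {
  stopifnot(inherits(layout, "read_layout"), inherits(match, "match_policy"),
            inherits(dedup, "dedup_policy"))
  cfg <- list(cell_fastq = as.character(cell_fastq),
              tag_fastq = as.character(tag_fastq),
              whitelist = as.character(whitelist), tags = as.character(tags),
              out_dir = out_dir, layout = layout, match = match,
              dedup = dedup, rc_barcodes = isTRUE(rc_barcodes),
              strip_suffix = isTRUE(strip_suffix),
              drop_zero_cells = isTRUE(drop_zero_cells),
              verbose = isTRUE(verbose))
  if (length(cfg$cell_fastq) != length(cfg$tag_fastq))
    stop("cell and tag FASTQ lists must have equal length")
  if (length(cfg$cell_fastq) == 0L) stop("no FASTQ inputs configured")
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full counting pipeline
#'
#' Reads the paired FASTQ inputs, matches cell barcodes and tag oligos,
#' filters ambiguous and unmatched reads, deduplicates UMIs, builds the
#' sparse count matrix and (when `out_dir` is set) writes the MatrixMarket
#' triplet, the run report (`run_report.txt`) and a JSON config snapshot
#' (`run_config.json`). Deterministic: identical inputs and configuration
#' yield byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `matrix` (dgCMatrix, tags x cells),
#'   `report` (a [run_report()]), and `molecules` (the deduplicated
#'   assignment table).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))

  whitelist <- stage("references", {
    wl <- read_whitelist(config$whitelist, strip_suffix = config$strip_suffix)
    if (length(unique(nchar(wl))) == 1L &&
        nchar(wl[1]) != config$layout$cell_bc_length)
      stop(sprintf("whitelist barcodes are %d nt but layout expects %d",
                   nchar(wl[1]), config$layout$cell_bc_length))
    wl
  })
  tags <- stage("references", read_tag_reference(config$tags))
  say("references: %d whitelist barcodes, %d tags",
      length(whitelist), length(tags$names))

  pairs <- stage("fastq", read_fastq_pairs(config$cell_fastq,
                                           config$tag_fastq, config$layout))
  records <- pairs$records
  if (config$rc_barcodes) records$cell_window <- revcomp(records$cell_window)
  say("fastq: %d read pairs (%d malformed skipped)",
      nrow(records) + pairs$n_malformed, pairs$n_malformed)

  asg <- stage("matching",
               assign_reads(records, whitelist, tags, config$match))
  say("matching: %d reads assigned to both references; dropped %s",
      nrow(asg$molecules),
      paste(names(asg$tallies), asg$tallies, sep = "=", collapse = ", "))

  dd <- stage("dedup", {
    if (config$dedup$mode == "exact") dedup_exact(asg$molecules, config$dedup)
    else dedup_close(asg$molecules, config$dedup)
  })
  say("dedup (%s): %d UMI duplicates removed", config$dedup$mode, dd$removed)

  mat <- stage("matrix", build_matrix(dd$kept, whitelist, tags,
                                      config$drop_zero_cells))
  report <- run_report(
    n_reads_total = nrow(records) + pairs$n_malformed,
    n_malformed = pairs$n_malformed,
    n_cell_unmatched = asg$tallies[["n_cell_unmatched"]],
    n_cell_ambiguous = asg$tallies[["n_cell_ambiguous"]],
    n_tag_unmatched = asg$tallies[["n_tag_unmatched"]],
    n_tag_ambiguous = asg$tallies[["n_tag_ambiguous"]],
    n_umi_duplicates_removed = dd$removed,
    n_counted = nrow(dd$kept)
  )
  say("counted %d molecules into a %d x %d matrix",
      report$n_counted, nrow(mat), ncol(mat))

  if (!is.null(config$out_dir)) stage("output", {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_count_matrix(mat, config$out_dir)
    write_run_report(report, file.path(config$out_dir, "run_report.txt"))
    snapshot <- unclass(config)
    snapshot$layout <- unclass(snapshot$layout)
    snapshot$match <- unclass(snapshot$match)
    snapshot$dedup <- unclass(snapshot$dedup)
    jsonlite::write_json(snapshot, file.path(config$out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  })
  invisible(list(matrix = mat, report = report, molecules = dd$kept))
}
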