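#' Read paired FASTQ files and extract barcode, UMI and tag windows
#'
#' Reads one or more lanes of paired FASTQ files (plain or gzipped) and
#' extracts the three informative windows from each read pair according to a
#' [read_layout()]. Lanes are concatenated in list order. Sequences are
#' uppercased and any non-ACGT character is normalised to `N` (which can
#' never match a reference base downstream). Base qualities are ignored.
#'
#' A pair is counted as malformed and skipped when either read is too short
#' to contain its required windows. Record counts must agree within each
#' cell/tag file pair, and paired records must carry the same read identifier
#' (first whitespace-delimited token, trailing `/1`/`/2` stripped).
#'
#' @param cell_fastq_paths,tag_fastq_paths Equal-length character vectors of
#'   FASTQ paths; element `i` of each forms lane `i`.
#' @param layout A [read_layout()].
#' @return A list of class `read_pairs` with elements `records` (data.frame
#'   with columns `read_id`, `cell_window`, `umi_window`, `tag_window`, one
#'   row per well-formed pair, in lane order) and `n_malformed`.
#' @export
read_fastq_pairs <- function(cell_fastq_paths, tag_fastq_paths,
                             layout = read_layout()) {
  cell_fastq_paths <- as.character(cell_fastq_paths)
  tag_fastq_paths <- as.character(tag_fastq_paths)
  if (length(cell_fastq_paths) != length(tag_fastq_paths))
    stop("cell and tag FASTQ path lists must have equal length")
  if (length(cell_fastq_paths) == 0L) stop("no FASTQ files given")
  stopifnot(inherits(layout, "read_layout"))

  mins <- layout_min_lengths(layout)
  pieces <- vector("list", length(cell_fastq_paths))
  n_malformed <- 0L
  for (i in seq_along(cell_fastq_paths)) {
    cells <- read_fastq_one(cell_fastq_paths[i])
    tags <- read_fastq_one(tag_fastq_paths[i])
    if (length(cells$seq) != length(tags$seq))
      stop(sprintf(
        "record count mismatch between paired FASTQ files '%s' (%d) and '%s' (%d)",
        cell_fastq_paths[i], length(cells$seq),
        tag_fastq_paths[i], length(tags$seq)))
    if (length(cells$seq) == 0L) next
    if (!identical(cells$id, tags$id)) {
      bad <- which(cells$id != tags$id)[1]
      stop(sprintf(
        "read identifier mismatch at record %d of pair '%s' / '%s': '%s' vs '%s'",
        bad, cell_fastq_paths[i], tag_fastq_paths[i],
        cells$id[bad], tags$id[bad]))
    }
    ok <- nchar(cells$seq) >= mins["cell"] & nchar(tags$seq) >= mins["tag"]
    n_malformed <- n_malformed + sum(!ok)
    cseq <- cells$seq[ok]
    tseq <- tags$seq[ok]
    umi_from <- if (layout$umi_source == "cell") cseq else tseq
    pieces[[i]] <- data.frame(
      read_id = cells$id[ok],
      cell_window = clean_window(substr(cseq, layout$cell_bc_offset + 1L,
                                        layout$cell_bc_offset + layout$cell_bc_length)),
      umi_window = clean_window(substr(umi_from, layout$umi_offset + 1L,
                                       layout$umi_offset + layout$umi_length)),
      tag_window = clean_window(substr(tseq, layout$tag_offset + 1L,
                                       layout$tag_offset + layout$tag_length)),
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, pieces)
  if (is.null(records))
    records <- data.frame(read_id = character(), cell_window = character(),
                          umi_window = character(), tag_window = character(),
                          stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(list(records = records, n_malformed = n_malformed),
            class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("read_pairs: %d well-formed records, %d malformed\n",
              nrow(x$records), x$n_malformed))
  invisible(x)
}

# One FASTQ file -> list(id, seq). Biostrings does the parsing (handles gzip
# and raises on malformed 4-line structure); ids keep the first header token
# with any trailing /1 or /2 stripped.
read_fastq_one <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTQ file not found: '%s'", path))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop(sprintf("failed to parse FASTQ '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  ids <- sub("/[12]$", "", sub("\\s.*$", "", names(set)))
  list(id = ids, seq = toupper(as.character(set)))
}

clean_window <- function(x) gsub("[^ACGT]", "N", toupper(x), perl = TRUE)

#' Read a tag-oligo reference table
#'
#' Parses a two-column delimited text file (comma or tab, autodetected)
#' mapping marker names to their conjugated oligo sequences. A header row is
#' detected by a non-ACGT second field and skipped.
#'
#' @param path Path to the reference file (plain or gzipped).
#' @return A `tag_reference` object: list with `names` (unique marker names)
#'   and `sequences` (unique uppercase oligos of uniform length), order
#'   preserved.
#' @export
read_tag_reference <- function(path) {
  lines <- readLines(gzfile(path), warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty tag reference file: '%s'", path))
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop(sprintf("tag reference '%s': every row needs name%ssequence", path, sep))
  nm <- trimws(vapply(fields, `[[`, "", 1L))
  sq <- toupper(trimws(vapply(fields, `[[`, "", 2L)))
  if (!grepl("^[ACGT]+$", sq[1])) {           # header row
    nm <- nm[-1]; sq <- sq[-1]
  }
  tag_reference(nm, sq)
}

#' Construct and validate a tag reference
#'
#' @param names Marker names, unique.
#' @param sequences Oligo sequences, unique, uniform length, ACGT only.
#' @return A `tag_reference` object.
#' @export
tag_reference <- function(names, sequences) {
  names <- as.character(names); sequences <- toupper(as.character(sequences))
  if (length(names) == 0L) stop("tag reference is empty")
  if (length(names) != length(sequences))
    stop("tag reference names and sequences differ in length")
  bad <- sequences[!grepl("^[ACGT]+$", sequences)]
  if (length(bad))
    stop("tag reference sequences contain non-ACGT characters: ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (anyDuplicated(names))
    stop("duplicate tag names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  if (anyDuplicated(sequences))
    stop("duplicate tag sequences: ",
         paste(unique(sequences[duplicated(sequences)]), collapse = ", "))
  if (length(unique(nchar(sequences))) != 1L)
    stop("tag reference sequences must all have the same length")
  structure(list(names = names, sequences = sequences),
            class = "tag_reference")
}

#' @export
print.tag_reference <- function(x, ...) {
  cat(sprintf("tag_reference: %d markers, %d nt oligos\n",
              length(x$names), nchar(x$sequences[1])))
  invisible(x)
}

#' Read a cell-barcode whitelist
#'
#' One barcode per line, plain or gzipped. Whitelists exported by cell
#' callers often carry a GEM-well suffix such as `-1`; `strip_suffix = TRUE`
#' removes a trailing `-<digits>`.
#'
#' @param path Path to the whitelist file.
#' @param strip_suffix Strip a trailing `-<digits>` suffix (default `TRUE`).
#' @param reverse_complement Reverse-complement the barcodes after reading
#'   (default `FALSE`). ATAC-derived barcode lists use the opposite strand
#'   convention from some manufacturer whitelists.
#' @return Character vector of unique uppercase barcodes of uniform length,
#'   order preserved, with class `barcode_whitelist`.
#' @export
read_whitelist <- function(path, strip_suffix = TRUE,
                           reverse_complement = FALSE) {
  lines <- readLines(gzfile(path), warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("empty whitelist file: '%s'", path))
  if (strip_suffix) lines <- sub("-[0-9]+$", "", lines)
  bc <- toupper(lines)
  if (reverse_complement) bc <- revcomp(bc)
  barcode_whitelist(bc)
}

#' Construct and validate a barcode whitelist
#' @param sequences Barcode sequences: unique, uniform length, ACGT only.
#' @return The validated barcodes with class `barcode_whitelist`.
#' @export
barcode_whitelist <- function(sequences) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("whitelist is empty")
  if (anyDuplicated(sequences))
    stop("duplicate whitelist barcodes (after suffix stripping): ",
         paste(utils::head(unique(sequences[duplicated(sequences)]), 5),
               collapse = ", "))
  if (length(unique(nchar(sequences))) != 1L)
    stop("whitelist barcodes must all have the same length")
  if (!all(grepl("^[ACGT]+$", sequences)))
    stop("whitelist barcodes contain non-ACGT characters")
  structure(sequences, class = "barcode_whitelist")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a count matrix as a CellRanger-style MatrixMarket triplet
#'
#' Writes `matrix.mtx.gz` (MatrixMarket `coordinate integer general`,
#' 1-based indices, features as rows and cell barcodes as columns),
#' `features.tsv.gz` (id, name, `"Antibody Capture"`) and `barcodes.tsv.gz`
#' into `out_dir`. Output bytes are deterministic (gzip mtime is zero), so
#' identical matrices produce identical files.
#'
#' @param matrix A features-by-cells sparse or dense matrix with complete
#'   dimnames, e.g. from [build_matrix()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the three file paths.
#' @export
write_count_matrix <- function(matrix, out_dir) {
  m <- methods::as(matrix, "TsparseMatrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix must have feature and barcode dimnames")
  if (any(m@x != round(m@x)) || any(m@x < 0))
    stop("count matrix entries must be non-negative integers")
  keep <- m@x != 0
  i <- m@i[keep] + 1L; j <- m@j[keep] + 1L; x <- as.integer(m@x[keep])
  o <- order(j, i)                      # column-major, the conventional order
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop(sprintf("output directory not writable: '%s'", out_dir))
  paths <- file.path(out_dir,
                     c("matrix.mtx.gz", "features.tsv.gz", "barcodes.tsv.gz"))
  gz_writelines(c(
    "%%MatrixMarket matrix coordinate integer general",
    "%",
    paste(nrow(m), ncol(m), length(i)),
    if (length(i)) paste(i[o], j[o], x[o])
  ), paths[1])
  gz_writelines(paste(rownames(m), rownames(m), "Antibody Capture",
                      sep = "\t"), paths[2])
  gz_writelines(colnames(m), paths[3])
  invisible(paths)
}

#' Read back a MatrixMarket triplet written by [write_count_matrix()]
#'
#' Parsing is delegated to [Matrix::readMM()]; labels are re-attached from
#' the features and barcodes files.
#'
#' @param dir Directory holding `matrix.mtx[.gz]`, `features.tsv[.gz]`,
#'   `barcodes.tsv[.gz]`.
#' @return A `dgCMatrix`, features as rows, barcodes as columns.
#' @export
read_count_matrix <- function(dir) {
  find1 <- function(base) {
    for (p in file.path(dir, c(paste0(base, ".gz"), base)))
      if (file.exists(p)) return(p)
    stop(sprintf("missing '%s[.gz]' in '%s'", base, dir))
  }
  m <- Matrix::readMM(find1("matrix.mtx"))
  feats <- read.delim(gzfile(find1("features.tsv")), header = FALSE,
                      stringsAsFactors = FALSE)
  bcs <- readLines(gzfile(find1("barcodes.tsv")))
  dimnames(m) <- list(feats[[1]], bcs)
  methods::as(m, "CsparseMatrix")
}

# deterministic gzip text writer (mtime field is 0 in R's gzfile output)
gz_writelines <- function(lines, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
}
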