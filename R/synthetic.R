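#' Configuration for the synthetic read generator
#'
#' Describes a simulated ADT experiment: how many cells and tags, window
#' lengths, the expected number of molecules per (cell, tag) pair, and the
#' nuisance processes the pipeline must survive — PCR duplication (a
#' molecule's read re-emitted with probability `duplication_rate`),
#' per-base substitution errors, and optionally junk read pairs too short
#' for the configured windows. References are generated with pairwise
#' Hamming distance >= 3 so a single sequencing error can never make a read
#' ambiguous by construction.
#'
#' @param n_cells,n_tags Number of whitelist barcodes / reference tags.
#' @param barcode_length,umi_length,tag_oligo_length Window lengths (bases).
#' @param mean_molecules Poisson mean of unique molecules per (cell, tag).
#' @param duplication_rate Probability a molecule emits one extra
#'   (PCR-duplicate) read.
#' @param substitution_error_rate Per-base substitution probability applied
#'   independently to every emitted read.
#' @param malformed_rate Expected share of extra junk read pairs (truncated
#'   below the window length) relative to the informative reads.
#' @param seed Integer RNG seed; everything downstream is deterministic in
#'   it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_cells = 200L, n_tags = 20L, barcode_length = 16L,
                       umi_length = 12L, tag_oligo_length = 16L,
                       mean_molecules = 5, duplication_rate = 0,
                       substitution_error_rate = 0, malformed_rate = 0,
                       seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_tags = as.integer(n_tags),
              barcode_length = as.integer(barcode_length),
              umi_length = as.integer(umi_length),
              tag_oligo_length = as.integer(tag_oligo_length),
              mean_molecules = as.numeric(mean_molecules),
              duplication_rate = as.numeric(duplication_rate),
              substitution_error_rate = as.numeric(substitution_error_rate),
              malformed_rate = as.numeric(malformed_rate),
              seed = as.integer(seed))
  rates <- c(cfg$duplication_rate, cfg$substitution_error_rate,
             cfg$malformed_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$n_cells < 1L || cfg$n_tags < 1L) stop("need at least 1 cell and 1 tag")
  if (min(cfg$barcode_length, cfg$umi_length, cfg$tag_oligo_length) < 4L)
    stop("window lengths must be >= 4")
  if (cfg$mean_molecules <= 0) stop("mean_molecules must be positive")
  structure(cfg, class = "sim_config")
}

random_seqs <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = len)
  do.call(paste0, split(m, row(m)))
}

#' Generate whitelist and tag references for a simulation
#'
#' Uniform-random sequences accepted greedily until the requested counts are
#' reached, rejecting any candidate within Hamming distance 2 of an accepted
#' sequence (pairwise distance >= 3 guarantees single-error reads stay
#' unambiguous). Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `whitelist` (a [barcode_whitelist()]) and `tags`
#'   (a [tag_reference()], markers named `TAG001`, ...).
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  list(
    whitelist = barcode_whitelist(
      spaced_seqs(config$n_cells, config$barcode_length)),
    tags = tag_reference(
      sprintf("TAG%03d", seq_len(config$n_tags)),
      spaced_seqs(config$n_tags, config$tag_oligo_length))
  )
}

spaced_seqs <- function(n, len, min_dist = 3L, max_tries = 200L) {
  if (n > 4^len)
    stop(sprintf("cannot draw %d distinct %d-mers (alphabet exhausted)", n, len))
  acc <- character(0)
  tries <- 0L
  while (length(acc) < n) {
    cand <- random_seqs(1L, len)
    ok <- length(acc) == 0L ||
      all(cpp_hamming(rep(cand, length(acc)), acc) >= min_dist)
    if (ok) {
      acc <- c(acc, cand)
      tries <- 0L
    } else if ((tries <- tries + 1L) > max_tries * n) {
      stop(sprintf(
        "could not place %d sequences at pairwise Hamming >= %d with length %d; use longer sequences",
        n, min_dist, len))
    }
  }
  acc
}

# draw n UMIs unique within one cell
unique_umis <- function(n, len) {
  u <- random_seqs(n, len)
  while (any(d <- duplicated(u))) u[d] <- random_seqs(sum(d), len)
  u
}

# substitute bases independently at `rate`; a substituted base always
# changes (drawn from the three other bases). Returns mutated sequences and
# the per-sequence substitution count.
mutate_seqs <- function(seqs, rate) {
  n <- length(seqs)
  if (n == 0L || rate <= 0)
    return(list(seq = seqs, n_mut = integer(n)))
  len <- nchar(seqs[1])
  v <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  mask <- runif(length(v)) < rate
  if (any(mask)) {
    idx <- match(v[mask], DNA_BASES)
    shift <- sample.int(3L, sum(mask), replace = TRUE)
    v[mask] <- DNA_BASES[(idx - 1L + shift) %% 4L + 1L]
  }
  m <- matrix(v, nrow = len)
  list(seq = do.call(paste0, split(m, row(m))),
       n_mut = as.integer(colSums(matrix(mask, nrow = len))))
}

#' Generate a ground-truthed synthetic FASTQ dataset
#'
#' Simulates one ADT sequencing run under `config` and writes everything
#' the pipeline consumes: gzipped paired FASTQ (cell read = the barcode; tag
#' read = tag oligo followed by the UMI, matching the default
#' [read_layout()]), the whitelist, the tag reference table, and the truth
#' count matrix as a MatrixMarket triplet under `truth/`. Per-read
#' provenance (true cell, tag, UMI, duplicate flag, injected error counts)
#' is returned and written as `provenance.tsv`.
#'
#' Molecule counts per (cell, tag) are Poisson; each molecule's read is
#' re-emitted once as a PCR duplicate with probability
#' `config$duplication_rate` (the duplicate follows its original
#' immediately, so the original is always the first occurrence); junk pairs
#' with a truncated tag read are appended at `malformed_rate`. Byte-level
#' deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Directory to write into (created if needed).
#' @return Invisibly, a list with `paths` (cell_fastq, tag_fastq, whitelist,
#'   tags, truth_dir, provenance), `truth_matrix` (dgCMatrix, tags x cells),
#'   `provenance` (data.frame), `whitelist`, `tags`, `layout`, `config`,
#'   and error-injection totals `n_emitted_bases` / `n_mutated_bases`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  refs <- generate_references(config)   # seeds the RNG; sampling continues
  wl <- refs$whitelist
  tags <- refs$tags
  layout <- read_layout(cell_bc_length = config$barcode_length,
                        umi_length = config$umi_length,
                        tag_length = config$tag_oligo_length)

  counts <- rpois(config$n_cells * config$n_tags, config$mean_molecules)
  cell_of <- rep(rep(seq_len(config$n_cells), each = config$n_tags), counts)
  tag_of <- rep(rep(seq_len(config$n_tags), times = config$n_cells), counts)
  n_mol <- length(cell_of)
  if (n_mol == 0L) stop("simulation produced zero molecules; raise mean_molecules")

  umi <- character(n_mol)
  for (cell in unique(cell_of)) {
    idx <- which(cell_of == cell)
    umi[idx] <- unique_umis(length(idx), config$umi_length)
  }

  extra <- rbinom(n_mol, 1L, config$duplication_rate)
  emit <- rep(seq_len(n_mol), 1L + extra)   # duplicate directly follows original
  is_dup <- duplicated(emit)
  n_reads <- length(emit)

  cell_reads <- mutate_seqs(wl[cell_of[emit]], config$substitution_error_rate)
  tag_reads <- mutate_seqs(paste0(tags$sequences[tag_of[emit]], umi[emit]),
                           config$substitution_error_rate)

  prov <- data.frame(
    read_id = sprintf("read%08d", seq_len(n_reads)),
    cell_index = cell_of[emit], tag_index = tag_of[emit], umi = umi[emit],
    is_duplicate = is_dup, is_malformed = FALSE,
    n_errors_cell_read = cell_reads$n_mut,
    n_errors_tag_read = tag_reads$n_mut,
    stringsAsFactors = FALSE
  )
  cell_seq <- cell_reads$seq
  tag_seq <- tag_reads$seq

  n_junk <- rbinom(1L, n_reads, config$malformed_rate)
  if (n_junk > 0L) {
    junk_len <- max(1L, config$tag_oligo_length %/% 2L)  # too short for any tag window
    prov_junk <- data.frame(
      read_id = sprintf("junk%08d", seq_len(n_junk)),
      cell_index = NA_integer_, tag_index = NA_integer_, umi = NA_character_,
      is_duplicate = FALSE, is_malformed = TRUE,
      n_errors_cell_read = 0L, n_errors_tag_read = 0L,
      stringsAsFactors = FALSE
    )
    cell_seq <- c(cell_seq, random_seqs(n_junk, config$barcode_length))
    tag_seq <- c(tag_seq, random_seqs(n_junk, junk_len))
    prov <- rbind(prov, prov_junk)
  }

  truth <- Matrix::sparseMatrix(
    i = tag_of, j = cell_of, x = rep(1L, n_mol),
    dims = c(config$n_tags, config$n_cells),
    dimnames = list(tags$names, as.character(unclass(wl))))
  truth <- methods::as(truth, "CsparseMatrix")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    cell_fastq = file.path(out_dir, "cell_R1.fastq.gz"),
    tag_fastq = file.path(out_dir, "tag_R2.fastq.gz"),
    whitelist = file.path(out_dir, "whitelist.tsv"),
    tags = file.path(out_dir, "tags.csv"),
    truth_dir = file.path(out_dir, "truth"),
    provenance = file.path(out_dir, "provenance.tsv")
  )
  write_fastq(prov$read_id, cell_seq, paths$cell_fastq)
  write_fastq(prov$read_id, tag_seq, paths$tag_fastq)
  writeLines(as.character(unclass(wl)), paths$whitelist)
  writeLines(c("name,sequence", paste(tags$names, tags$sequences, sep = ",")),
             paths$tags)
  write_count_matrix(truth, paths$truth_dir)
  utils::write.table(prov, paths$provenance, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(
    paths = paths, truth_matrix = truth, provenance = prov,
    whitelist = wl, tags = tags, layout = layout, config = config,
    n_emitted_bases = n_reads *
      (config$barcode_length + config$tag_oligo_length + config$umi_length),
    n_mutated_bases = sum(prov$n_errors_cell_read + prov$n_errors_tag_read)
  ))
}

# minimal FASTQ writer (constant qualities; the pipeline ignores them);
# gzipped deterministically via gzfile (mtime 0)
write_fastq <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  gz_writelines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
}
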