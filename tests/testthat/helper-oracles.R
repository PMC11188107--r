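# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: Hamming by character-wise comparison,
# Levenshtein by utils::adist or a literal two-loop DP, matching by
# exhaustive all-pairs application of the pass rule, dedup by quadratic
# scans.

rdna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), "")
}

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb | ca == "N" | cb == "N")
}

# textbook full-matrix Levenshtein DP (unit costs)
oracle_levenshtein_dp <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  D <- matrix(0L, na + 1, nb + 1)
  D[, 1] <- 0:na
  D[1, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    D[i + 1, j + 1] <- min(D[i, j] + (ca[i] != cb[j]),
                           D[i, j + 1] + 1L,
                           D[i + 1, j] + 1L)
  }
  D[na + 1, nb + 1]
}

# exhaustive all-pairs matcher applying the pass rule directly
oracle_match <- function(queries, reference, metric, cutoff) {
  t(vapply(queries, function(q) {
    pass <- vapply(reference, function(r) {
      if (metric == "hamming") {
        nchar(q) == nchar(r) && oracle_hamming(q, r) <= cutoff
      } else {
        m <- max(nchar(q), nchar(r))
        sim <- if (m == 0) 1 else 1 - utils::adist(q, r)[1, 1] / m
        sim >= cutoff
      }
    }, logical(1))
    np <- sum(pass)
    c(n_passing = np,
      ref_index = if (np == 1L) which(pass) else NA_integer_)
  }, c(n_passing = 0L, ref_index = 0L)))
}

oracle_dedup_exact <- function(mol, include_tag = FALSE) {
  key <- paste(mol$cell_index,
               if (include_tag) mol$tag_index else "", mol$umi)
  seen <- character(0)
  keep <- logical(nrow(mol))
  for (i in seq_len(nrow(mol))) {
    if (!key[i] %in% seen) {
      keep[i] <- TRUE
      seen <- c(seen, key[i])
    }
  }
  keep
}

oracle_dedup_close <- function(mol, radius, include_tag = FALSE) {
  grp <- paste(mol$cell_index, if (include_tag) mol$tag_index else "")
  keep <- logical(nrow(mol))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    kept <- integer(0)
    for (i in idx) {
      near <- any(vapply(kept, function(k)
        oracle_hamming(mol$umi[i], mol$umi[k]) <= radius, logical(1)))
      if (!near) {
        keep[i] <- TRUE
        kept <- c(kept, i)
      }
    }
  }
  keep
}

rand_molecules <- function(n, n_cells = 10, n_tags = 4, n_umis = 8,
                           umi_len = 4) {
  pool <- rdna(n_umis, umi_len)
  molecule_assignments(
    cell_index = sample.int(n_cells, n, replace = TRUE),
    tag_index = sample.int(n_tags, n, replace = TRUE),
    umi = sample(pool, n, replace = TRUE)
  )
}

# bypasses the constructor's max_mismatch >= 1 check, for the degenerate
# radius-0 equivalence test
close_policy_radius <- function(radius, include_tag = FALSE) {
  structure(list(mode = "close", max_mismatch = as.integer(radius),
                 key_includes_tag = include_tag), class = "dedup_policy")
}

write_tmp_fastq <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  path
}
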