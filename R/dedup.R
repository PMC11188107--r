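#' Build a molecule-assignment table
#'
#' A molecule assignment records one read resolved to a whitelist cell, a
#' reference tag and its UMI, in original read order. Only reads with both
#' the cell and the tag side uniquely assigned become molecules.
#'
#' @param cell_index 1-based whitelist indices.
#' @param tag_index 1-based tag-reference indices.
#' @param umi UMI sequences.
#' @param order Original read indices; must be strictly increasing. Default
#'   `seq_along(cell_index)`.
#' @return A data.frame with columns `order`, `cell_index`, `tag_index`,
#'   `umi`.
#' @export
molecule_assignments <- function(cell_index, tag_index, umi,
                                 order = seq_along(cell_index)) {
  m <- data.frame(order = as.integer(order),
                  cell_index = as.integer(cell_index),
                  tag_index = as.integer(tag_index),
                  umi = toupper(as.character(umi)),
                  stringsAsFactors = FALSE)
  if (nrow(m) > 1L && any(diff(m$order) <= 0L))
    stop("molecule 'order' must be strictly increasing")
  m
}

#' UMI deduplication policy
#'
#' `"exact"` mode (the default) removes reads whose dedup key — the
#' cell index plus the literal UMI sequence — has already been seen.
#' `"close"` mode additionally collapses UMIs within a Hamming radius of an
#' already-kept UMI, absorbing single sequencing errors in the UMI at extra
#' cost. The key excludes the tag by default; `key_includes_tag = TRUE`
#' switches to the conventional feature-barcoding key (cell, tag, UMI).
#'
#' @param mode `"exact"` or `"close"`.
#' @param max_mismatch Hamming radius for close mode; must be >= 1.
#' @param key_includes_tag Include the tag index in the dedup key.
#' @return A `dedup_policy` object.
#' @export
dedup_policy <- function(mode = c("exact", "close"), max_mismatch = 1L,
                         key_includes_tag = FALSE) {
  mode <- match.arg(mode)
  max_mismatch <- as.integer(max_mismatch)
  if (mode == "close" && (is.na(max_mismatch) || max_mismatch < 1L))
    stop("max_mismatch must be >= 1 in close mode")
  structure(list(mode = mode, max_mismatch = max_mismatch,
                 key_includes_tag = isTRUE(key_includes_tag)),
            class = "dedup_policy")
}

#' @export
print.dedup_policy <- function(x, ...) {
  cat(sprintf("dedup_policy: mode=%s, max_mismatch=%d, key_includes_tag=%s\n",
              x$mode, x$max_mismatch, x$key_includes_tag))
  invisible(x)
}

dedup_key <- function(molecules, policy, with_umi = TRUE) {
  parts <- list(molecules$cell_index)
  if (policy$key_includes_tag) parts <- c(parts, list(molecules$tag_index))
  if (with_umi) parts <- c(parts, list(molecules$umi))
  do.call(paste, c(parts, sep = "\r"))
}

#' Remove exactly duplicated molecules
#'
#' Within each dedup key group only the first-occurring molecule (by input
#' order) is kept; later occurrences are PCR duplicates and are removed.
#'
#' @param molecules A [molecule_assignments()] table, ordered by read index.
#' @param policy A [dedup_policy()].
#' @return List with `kept` (the surviving rows, original order preserved)
#'   and `removed` (count of dropped duplicates).
#' @export
dedup_exact <- function(molecules, policy = dedup_policy()) {
  stopifnot(inherits(policy, "dedup_policy"))
  keep <- !duplicated(dedup_key(molecules, policy))
  list(kept = molecules[keep, , drop = FALSE],
       removed = sum(!keep))
}

#' Remove near-duplicate molecules by UMI Hamming distance
#'
#' Greedy keep-first collapse: within each cell (and tag, when the key
#' includes it), molecules are scanned in read order and removed when their
#' UMI lies within Hamming distance `policy$max_mismatch` of the UMI of any
#' already-kept molecule in the group. With radius 0 this degenerates to
#' [dedup_exact()]. All UMIs within a group must have equal length.
#'
#' @inheritParams dedup_exact
#' @return List with `kept` and `removed`, as [dedup_exact()].
#' @export
dedup_close <- function(molecules, policy = dedup_policy(mode = "close")) {
  stopifnot(inherits(policy, "dedup_policy"))
  reps <- close_representatives(molecules, policy, policy$max_mismatch)
  keep <- reps == seq_len(nrow(molecules))
  list(kept = molecules[keep, , drop = FALSE], removed = sum(!keep))
}

# Row index (into molecules) of each molecule's kept representative under
# greedy keep-first close collapse at the given radius.
close_representatives <- function(molecules, policy, radius) {
  n <- nrow(molecules)
  reps <- integer(n)
  groups <- split(seq_len(n), dedup_key(molecules, policy, with_umi = FALSE))
  for (idx in groups) {
    local_rep <- cpp_dedup_close_group(molecules$umi[idx], as.integer(radius))
    reps[idx] <- idx[local_rep]
  }
  reps
}

#' Profile UMI duplication levels
#'
#' For each dedup key (cell + UMI, plus tag if the policy includes it) seen
#' `c` times, the duplicate fraction is `(c - 1) / c`: the share of that
#' key's reads that exact deduplication would remove. Returns the per-key
#' fractions, a histogram over `[0, 1]`, and the overall share of keys with
#' zero duplicates.
#'
#' @param molecules A [molecule_assignments()] table (nonempty).
#' @param policy A [dedup_policy()] (only `key_includes_tag` is used).
#' @param breaks Histogram bin edges over `[0, 1]`.
#' @return A `duplication_profile` object: list with `fractions` (per key,
#'   in first-appearance order), `counts` (per key read totals),
#'   `histogram` (data.frame `bin_low`, `bin_high`, `n_keys`), and
#'   `zero_duplicate_share`.
#' @export
duplication_profile <- function(molecules, policy = dedup_policy(),
                                breaks = seq(0, 1, by = 0.05)) {
  if (nrow(molecules) == 0L) stop("no molecules to profile")
  key <- dedup_key(molecules, policy)
  counts <- table(factor(key, levels = unique(key)))
  cnt <- as.integer(counts)
  frac <- (cnt - 1) / cnt
  h <- graphics::hist(frac, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  structure(list(
    fractions = frac,
    counts = cnt,
    histogram = data.frame(bin_low = utils::head(h$breaks, -1),
                           bin_high = utils::tail(h$breaks, -1),
                           n_keys = h$counts),
    zero_duplicate_share = mean(cnt == 1L)
  ), class = "duplication_profile")
}

#' @export
print.duplication_profile <- function(x, ...) {
  cat(sprintf(
    "duplication_profile: %d keys, %.1f%% with zero duplicates, max fraction %.3f\n",
    length(x$fractions), 100 * x$zero_duplicate_share, max(x$fractions)))
  invisible(x)
}

#' Per-group normalized difference between exact and close deduplication
#'
#' Close-mode collapse merges molecules onto kept representatives; for each
#' resulting group with `total` reads, the normalized difference is
#' `(duplicates_close - duplicates_exact) / total`, where `duplicates_close`
#' is `total - 1` (everything but the representative) and
#' `duplicates_exact` counts reads sharing a literal UMI within the group.
#' The difference is never negative: close mode removes at least what exact
#' mode removes.
#'
#' @param molecules A [molecule_assignments()] table.
#' @param policy A [dedup_policy()]; `max_mismatch` sets the close radius.
#' @return data.frame with one row per close-mode kept representative:
#'   `cell_index`, `tag_index` (NA unless the key includes it), `umi` (the
#'   representative's), `total`, `duplicates_exact`, `duplicates_close`,
#'   `normalized_difference`.
#' @export
exact_vs_close_difference <- function(molecules,
                                      policy = dedup_policy(mode = "close")) {
  stopifnot(inherits(policy, "dedup_policy"))
  n <- nrow(molecules)
  if (n == 0L) stop("no molecules")
  reps <- close_representatives(molecules, policy, policy$max_mismatch)
  grp <- split(seq_len(n), reps)
  rep_idx <- as.integer(names(grp))
  total <- lengths(grp)
  dup_exact <- vapply(grp, function(idx) {
    length(idx) - length(unique(dedup_key(molecules[idx, , drop = FALSE], policy)))
  }, integer(1))
  dup_close <- total - 1L
  out <- data.frame(
    cell_index = molecules$cell_index[rep_idx],
    tag_index = if (policy$key_includes_tag)
      molecules$tag_index[rep_idx] else NA_integer_,
    umi = molecules$umi[rep_idx],
    total = as.integer(total),
    duplicates_exact = dup_exact,
    duplicates_close = as.integer(dup_close),
    normalized_difference = (dup_close - dup_exact) / total,
    stringsAsFactors = FALSE
  )
  out <- out[order(rep_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write duplication statistics as TSV
#'
#' Exports either a [duplication_profile()] (per-key counts and fractions)
#' or an [exact_vs_close_difference()] table for external plotting.
#'
#' @param x A `duplication_profile` or the data.frame from
#'   [exact_vs_close_difference()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_dedup_stats <- function(x, path) {
  if (inherits(x, "duplication_profile"))
    x <- data.frame(total_count = x$counts, duplicate_fraction = x$fractions)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
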