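#' Hamming distance between equal-length DNA sequences
#'
#' Vectorised over pairs. An `N` never matches any base, including another
#' `N`, so it always contributes a mismatch. Unequal lengths are an error:
#' the Hamming distance is undefined there (the batch matcher reports such
#' queries as unmatched instead, see [match_batch()]).
#'
#' @param a,b Character vectors of equal-length DNA sequences (recycled to a
#'   common length like arithmetic operators).
#' @return Integer vector of mismatch counts.
#' @examples
#' hamming_distance("ACGT", "ACGA")
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  cpp_hamming(rep_len(toupper(as.character(a)), n),
              rep_len(toupper(as.character(b)), n))
}

#' Normalized edit-distance similarity ratio
#'
#' Computes `1 - L(a, b) / max(nchar(a), nchar(b))` where `L` is the
#' unit-cost Levenshtein distance (substitutions, insertions and deletions
#' each cost 1). One substitution in a 16-mer scores 0.9375, just above the
#' default tag-matching cutoff of 0.93 ("0.93, or 1 mismatch" for 16 bp
#' oligos). An empty sequence against a nonempty one scores 0; two empty
#' sequences score 1. `N` bases never match and always cost an edit.
#'
#' @param a,b Character vectors of DNA sequences (recycled).
#' @return Numeric vector of similarities in `[0, 1]`.
#' @examples
#' edit_ratio("ACGTACGTACGTACGT", "ACGAACGTACGTACGT")  # 0.9375
#' @export
edit_ratio <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(toupper(as.character(a)), n)
  b <- rep_len(toupper(as.character(b)), n)
  mx <- pmax(nchar(a), nchar(b))
  d <- cpp_levenshtein(a, b)
  ifelse(mx == 0L, 1, 1 - d / mx)
}

#' Matching policy: metric, cutoffs and chunk size
#'
#' Cell barcodes are matched by Hamming distance (pass when distance is at
#' most `hamming_cutoff`); tag oligos by the normalized edit ratio (pass
#' when similarity is at least `ratio_cutoff`). Defaults are the recommended
#' cutoffs: 1 mismatch for barcodes and 0.93 for oligos — one substitution
#' in a 16 bp oligo (0.9375) passes, two do not. Queries are processed in
#' chunks of `chunk_size`; results are identical for any chunk size.
#'
#' @param metric `"hamming"` or `"edit_ratio"`; which pass rule
#'   [match_batch()] applies.
#' @param hamming_cutoff Maximum mismatches for the Hamming metric.
#' @param ratio_cutoff Minimum similarity in `(0, 1]` for the ratio metric.
#' @param chunk_size Queries per processing batch.
#' @return A `match_policy` object.
#' @export
match_policy <- function(metric = c("hamming", "edit_ratio"),
                         hamming_cutoff = 1L, ratio_cutoff = 0.93,
                         chunk_size = 100000L) {
  metric <- match.arg(metric)
  hamming_cutoff <- as.integer(hamming_cutoff)
  chunk_size <- as.integer(chunk_size)
  if (is.na(hamming_cutoff) || hamming_cutoff < 0L)
    stop("hamming_cutoff must be >= 0")
  if (!is.numeric(ratio_cutoff) || ratio_cutoff <= 0 || ratio_cutoff > 1)
    stop("ratio_cutoff must be in (0, 1]")
  if (is.na(chunk_size) || chunk_size < 1L)
    stop("chunk_size must be >= 1")
  structure(list(metric = metric, hamming_cutoff = hamming_cutoff,
                 ratio_cutoff = ratio_cutoff, chunk_size = chunk_size),
            class = "match_policy")
}

#' @export
print.match_policy <- function(x, ...) {
  cat(sprintf(
    "match_policy: metric=%s, hamming_cutoff=%d, ratio_cutoff=%g, chunk_size=%d\n",
    x$metric, x$hamming_cutoff, x$ratio_cutoff, x$chunk_size))
  invisible(x)
}

#' Match a batch of query sequences against a reference list
#'
#' Every query is compared against every reference under the policy's pass
#' rule. A query with exactly one passing reference is `assigned` to it; two
#' or more passing references make it `ambiguous` (dropped downstream — no
#' best-hit rescue, even when one reference is strictly closer); none make
#' it `unmatched`. Under the Hamming metric a query whose length differs
#' from a reference cannot pass that reference, so malformed-length queries
#' come back unmatched rather than raising.
#'
#' Queries are processed in chunks of `policy$chunk_size`; the result is
#' identical for every chunk size and in query order.
#'
#' @param queries Character vector of DNA sequences.
#' @param reference Nonempty character vector of reference sequences.
#' @param policy A [match_policy()]; `policy$metric` selects the rule.
#' @return A data.frame with one row per query: `query_index`, `status`
#'   (`"assigned"`, `"ambiguous"` or `"unmatched"`), `reference_index`
#'   (1-based, `NA` unless assigned) and `n_passing`.
#' @export
match_batch <- function(queries, reference, policy = match_policy()) {
  stopifnot(inherits(policy, "match_policy"))
  reference <- toupper(as.character(reference))
  if (length(reference) == 0L) stop("reference must be nonempty")
  queries <- toupper(as.character(queries))
  n <- length(queries)
  metric_code <- if (policy$metric == "hamming") 0L else 1L
  cutoff <- if (policy$metric == "hamming") policy$hamming_cutoff else policy$ratio_cutoff

  n_passing <- integer(n)
  ref_index <- rep(NA_integer_, n)
  starts <- seq.int(1L, max(n, 1L), by = policy$chunk_size)
  if (n > 0L) for (s in starts) {
    e <- min(s + policy$chunk_size - 1L, n)
    res <- cpp_match_chunk(queries[s:e], reference, metric_code, cutoff)
    n_passing[s:e] <- res$n_passing
    ref_index[s:e] <- res$ref_index
  }
  status <- rep("unmatched", n)
  status[n_passing == 1L] <- "assigned"
  status[n_passing >= 2L] <- "ambiguous"
  data.frame(query_index = seq_len(n), status = status,
             reference_index = ref_index, n_passing = n_passing,
             stringsAsFactors = FALSE)
}
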