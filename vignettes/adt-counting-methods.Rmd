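---
title: "Counting antibody-derived tags: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting antibody-derived tags: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtcount)
```

## The procedure

ASAP-seq and CITE-seq quantify cell-surface proteins through
antibody-conjugated oligos. Each sequenced molecule is observed as a read
pair: one read carries the cell barcode (and, in some layouts, the UMI),
the other carries the tag oligo and usually the UMI. `adtcount` converts
these pairs into a molecule count matrix in four deterministic steps:
window extraction, reference matching, ambiguity filtering, and UMI
deduplication. There is no randomness anywhere in the counting path, so a
run is reproducible bit for bit from its inputs and its configuration
snapshot (`run_config.json`).

### Window extraction

`read_layout()` describes where each element sits (0-based offsets). The
defaults — 16 bp barcode at the start of the cell read, 16 bp oligo at the
start of the tag read, 12 bp UMI immediately following the oligo — mirror
common 10x feature-barcoding designs, but sequencing vendors do not
standardise which physical read carries which element, so every offset,
length and the UMI's source read are configurable rather than guessed.
Reads too short for any required window are dropped as *malformed* and
tallied. Base qualities are read and ignored: no quality-based filtering
is part of the procedure. Any non-ACGT character is normalised to `N`, and
an `N` never matches any reference base (including another `N`) — a
conservative, deterministic treatment that simply spends one of the
allowed mismatches.

### Matching and its two metrics

Cell barcodes are compared to the whitelist with **Hamming distance**
(equal lengths by construction; the batch matcher reports a
length-mismatched query as unmatched rather than raising, so one malformed
record cannot abort a run). Tag oligos are compared with the **normalized
edit-distance similarity**

$$ r(a, b) = 1 - \frac{L(a,b)}{\max(|a|, |b|)} $$

where $L$ is the unit-cost Levenshtein distance. The normalization by the
longer length is a design choice: the ratio's defining calibration is that
one substitution in a 16 bp oligo must sit just above the default cutoff,
and $1 - 1/16 = 0.9375 \ge 0.93$ holds under this definition (as it does
for 15-mers, $0.9\overline{3}$). An insertion/deletion-only normalization
would satisfy the same single-substitution calibration; full Levenshtein
was chosen because it is the standard meaning of "edit distance" and
additionally tolerates one indel in an otherwise exact oligo.

Defaults: Hamming cutoff **1** mismatch, ratio cutoff **0.93**. Allowing
more than one barcode mismatch is known to yield only marginal additional
recovery while increasing misassignment risk, hence 1 is both the default
and the recommendation; both cutoffs are user-tunable per run
(`--cell-mismatch`, `--tag-ratio`).

Queries are processed in chunks (default **100,000**) purely as a
memory/parallelism granularity knob; the per-query result is independent
of chunking, and the test suite asserts bitwise identical output for chunk
sizes 1, 7 and 1000.

### Ambiguity filtering

A read whose window passes the cutoff for **two or more** references is
dropped as ambiguous — even when one reference is strictly closer. No
best-hit rescue is attempted: with references this short, a one-mismatch
"winner" among several passing candidates is weak evidence, and the
drop-on-multimatch rule keeps the procedure order-free and deterministic.
Counts of ambiguous cells and ambiguous tags are reported separately at
the end of each run.

### UMI deduplication

Only reads assigned on *both* sides enter deduplication (a dedup key needs
an assigned cell), which therefore runs after matching and before matrix
construction. The key is the cell index plus the literal UMI; the tag
index is **excluded by default** — deduplication acts on "cellID + UMI" —
and `key_includes_tag = TRUE` switches to the conventional
feature-barcoding key for users who prefer it. Two modes:

* `exact` (default): drop reads whose key was already seen. Fastest, and
  empirically near-indistinguishable from near-match collapse on real
  data, where ~95% of UMIs show no difference between the two.
* `close`: greedy keep-first collapse — scanning in read order, a
  molecule is removed when its UMI is within Hamming distance
  `max_mismatch` (default 1) of an already-kept molecule's UMI in the same
  group. Greedy keep-first (rather than directional networks or connected
  components) is the simplest deterministic rule that extends exact-mode
  semantics; read order is the sole tie-break. Radius 0 provably
  degenerates to `exact` (tested).

Hamming, not the edit ratio, is used over UMIs because UMIs are
fixed-length windows; the radius is configurable.

Two diagnostic statistics support tuning this choice:
`duplication_profile()` reports, per key seen $c$ times, the duplicate
fraction $(c-1)/c$ plus the share of keys with zero duplicates;
`exact_vs_close_difference()` reports, per close-collapse group with
$t$ total reads, $(\mathrm{dup}_{close} - \mathrm{dup}_{exact})/t$, which
is provably non-negative.

### Read-fate accounting

Every input read ends in exactly one bucket: malformed, cell-unmatched,
cell-ambiguous, tag-unmatched, tag-ambiguous, UMI-duplicate, or counted.
For reads failing both matches the **cell-side fate wins** — an arbitrary
but fixed precedence that makes reports deterministic. The conservation
identity (buckets sum to total reads) is asserted inside the `run_report()`
constructor itself, so a run that loses track of a read cannot complete.

### Output format

The matrix is written as the CellRanger-dialect MatrixMarket triplet —
`matrix.mtx.gz` (`coordinate integer general`, 1-based, **features as
rows, barcodes as columns**), `features.tsv.gz` (id, name, literal type
`Antibody Capture`), `barcodes.tsv.gz` — because that is the de facto
exchange format every downstream tool already reads. The matrix keeps the
full whitelist and tag panel as labels, including all-zero rows/columns,
so its dimensions are always (number of tags) × (whitelist size);
`drop_zero_cells` subsets on request. Gzip members are written with a zero
mtime, so repeated identical runs produce byte-identical files — the
self-consistency the format tests assert.

## The synthetic-data generator

`generate_dataset()` emits the world the pipeline is specified against:

* **References**: uniform-random sequences accepted only at pairwise
  Hamming distance ≥ 3, so a single substitution can never render a read
  ambiguous *by construction*. This is a property of the simulation, not
  of real panels (real whitelists are merely "error-robust").
* **Molecule counts**: Poisson per (cell, tag) with configurable mean
  (default 5). Real ADT counts are overdispersed and cell-size dependent;
  the counting pipeline is count-model-agnostic, so the simplest
  calibrated model suffices and negative-binomial emulation is
  deliberately out of scope.
* **UMIs**: drawn unique within each cell, making exact-dedup ground
  truth unambiguous. Real UMI collisions exist but would only blur the
  truth labels, not exercise different code.
* **Duplication**: each molecule re-emits its read once with probability
  `duplication_rate`, the duplicate immediately following its original, so
  the expected duplicate share of reads is $d/(1+d)$ and keep-first always
  keeps the true original.
* **Errors**: independent per-base substitutions at
  `substitution_error_rate`; a substituted base always changes. Indels
  and quality-score structure are not simulated (the matching regime for
  barcodes is Hamming; an indel-robustness stress test would exercise the
  ratio metric only).
* **Malformed reads**: optional junk read pairs with a truncated tag
  read, to exercise the malformed tally.

Everything is deterministic under `seed`, to the byte, including the
gzipped FASTQ.

A green truth-recovery test therefore establishes that extraction,
matching, filtering, dedup and formatting compose correctly under the
stated noise model — it does **not** establish robustness to indels,
ambient antibody background, barcode swapping, or realistic per-cycle
error profiles, none of which the generator emulates.

## Numerical and edge-case choices

* `edit_ratio` on two empty strings is defined as 1 (identical); empty vs
  nonempty is 0. Neither occurs with validated references.
* Matching cutoffs are compared with `<=` / `>=` exactly; similarities are
  ratios of small integers, so no floating-point guard is needed at the
  default cutoff (0.9375 vs 0.93 differs in the second decimal).
* Reference validation is strict (unique names, unique sequences, uniform
  length, ACGT only) and fails loudly listing offenders, because a silent
  bad panel corrupts every downstream count.
* Whitelist barcodes may carry a `-1`-style suffix (stripped by default)
  and may need reverse-complementing (`rc_barcodes`) when cell calls come
  from ATAC processing with the opposite strand convention; both were made
  explicit flags since the upstream convention cannot be detected from the
  data itself.

## A note on one stated property

For the default simulator settings with a 1% per-base error rate, the
fraction of molecules whose read survives both matches has the closed form
$p = [q(16)]^2$ with $q(L) = (1-e)^L + L e (1-e)^{L-1}$, i.e. $p \approx
0.978$: about 2.2% of reads draw two or more substitutions in one of the
two 16 nt windows and are correctly rejected by the default cutoffs. A
blanket "≥ 99% recovered at 1% error" expectation is therefore not
attainable under this error model — the suite instead asserts the analytic
value (within Monte-Carlo tolerance) plus the sharp guarantee that *every*
read with at most one error per window is recovered, which is what the
minimum-distance-3 references make provable.

## Known limitations

* No cell calling: the whitelist is taken as given (manufacturer list or
  upstream ATAC/GEX cell identification).
* No UMI error *correction*: close-mode dedup removes near-duplicate
  reads; it never reassigns them.
* No sliding-window search for shifted oligos; a constant offset error in
  library design must be expressed through the layout, not discovered.
* Whole-file FASTQ ingestion per lane (no streaming); comfortably fine for
  ADT libraries, which are orders of magnitude smaller than transcriptome
  data, but not intended for genome-scale inputs.
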