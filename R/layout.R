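#' Describe where the barcode, UMI and tag windows sit within a read pair
#'
#' A read layout pins down which bases of the two reads carry the three
#' informative elements. Offsets are 0-based (the number of bases preceding
#' the window), so a window occupies positions `offset + 1` to
#' `offset + length` in 1-based string coordinates. Reads too short for any
#' required window are dropped as malformed by [read_fastq_pairs()].
#'
#' Defaults mirror the common 10x feature-barcoding arrangement: a 16 bp cell
#' barcode at the start of the cell-ID read, the tag oligo at the start of
#' the tag read, and a 12 bp UMI immediately after the tag oligo on the tag
#' read. Every position is overridable because library designs differ and
#' vendors do not standardise which physical read carries which element.
#'
#' @param cell_bc_offset 0-based offset of the cell barcode in the cell read.
#' @param cell_bc_length Cell barcode length in bases.
#' @param umi_source Which read carries the UMI: `"tag"` or `"cell"`.
#' @param umi_offset 0-based offset of the UMI within its read. Default:
#'   immediately after the tag window (`tag_offset + tag_length`).
#' @param umi_length UMI length in bases.
#' @param tag_offset 0-based offset of the tag oligo in the tag read.
#' @param tag_length Tag oligo length in bases; must equal the reference
#'   oligo length used for matching.
#' @return A `read_layout` object (a validated named list).
#' @examples
#' read_layout()
#' read_layout(umi_source = "cell", umi_offset = 16, umi_length = 10)
#' @export
read_layout <- function(cell_bc_offset = 0L, cell_bc_length = 16L,
                        umi_source = c("tag", "cell"), umi_offset = NULL,
                        umi_length = 12L, tag_offset = 0L, tag_length = 16L) {
  umi_source <- match.arg(umi_source)
  umi_offset <- as.integer(umi_offset %||% (tag_offset + tag_length))
  layout <- list(
    cell_bc_offset = as.integer(cell_bc_offset),
    cell_bc_length = as.integer(cell_bc_length),
    umi_source = umi_source,
    umi_offset = umi_offset,
    umi_length = as.integer(umi_length),
    tag_offset = as.integer(tag_offset),
    tag_length = as.integer(tag_length)
  )
  offs <- c(layout$cell_bc_offset, layout$umi_offset, layout$tag_offset)
  lens <- c(layout$cell_bc_length, layout$umi_length, layout$tag_length)
  if (any(is.na(offs)) || any(offs < 0L))
    stop("read layout offsets must be non-negative integers")
  if (any(is.na(lens)) || any(lens < 1L))
    stop("read layout window lengths must be >= 1")
  structure(layout, class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  cat("Read layout (offsets 0-based):\n")
  cat(sprintf("  cell barcode: cell read [%d, %d)\n",
              x$cell_bc_offset, x$cell_bc_offset + x$cell_bc_length))
  cat(sprintf("  tag oligo:    tag read  [%d, %d)\n",
              x$tag_offset, x$tag_offset + x$tag_length))
  cat(sprintf("  UMI:          %s read [%d, %d)\n",
              x$umi_source, x$umi_offset, x$umi_offset + x$umi_length))
  invisible(x)
}

# window end positions required on each physical read
layout_min_lengths <- function(layout) {
  cell_min <- layout$cell_bc_offset + layout$cell_bc_length
  tag_min <- layout$tag_offset + layout$tag_length
  umi_min <- layout$umi_offset + layout$umi_length
  if (layout$umi_source == "cell") {
    cell_min <- max(cell_min, umi_min)
  } else {
    tag_min <- max(tag_min, umi_min)
  }
  c(cell = cell_min, tag = tag_min)
}
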