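# Repeat masking: flag variants falling in RepeatMasker-style BED intervals.

#' Flag variants inside repeat-masked regions
#'
#' Marks `in_repeat = TRUE` for every variant whose 1-based position falls
#' inside any interval of a BED3 mask (0-based half-open, the RepeatMasker
#' output convention); downstream co-segregation classification skips
#' flagged variants.  A BED interval `[99, 100)` therefore covers exactly
#' the 1-based position 100.  The operation is idempotent and independent
#' of BED interval order.
#'
#' @param x a `coseg_variants` object from [load_variants()].
#' @param mask path to a BED file, a `GRanges`, or a data frame with
#'   columns `chrom`, `start`, `end` (0-based half-open).
#' @return `x` with `table$in_repeat` updated (flags are recomputed, not
#'   OR-ed, so re-masking with a different BED replaces the flags).
#' @export
apply_repeat_mask <- function(x, mask) {
  stopifnot(inherits(x, "coseg_variants"))
  gr <- mask_to_granges(mask)
  tbl <- x$table
  if (length(gr) == 0L || nrow(tbl) == 0L) {
    x$table$in_repeat <- rep(FALSE, nrow(tbl))
    return(x)
  }
  extra <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                   unique(tbl$scaffold))
  if (length(extra))
    warning("mask scaffold(s) absent from variants: ",
            paste(extra, collapse = ", "))
  vr <- GenomicRanges::GRanges(tbl$scaffold,
                               IRanges::IRanges(tbl$pos, width = 1))
  hits <- GenomicRanges::countOverlaps(vr, gr, ignore.strand = TRUE)
  x$table$in_repeat <- hits > 0L
  x
}

mask_to_granges <- function(mask) {
  if (inherits(mask, "GRanges")) return(mask)
  if (is.data.frame(mask)) {
    if (nrow(mask) == 0L) return(GenomicRanges::GRanges())
    # columns: chrom, start, end in BED convention (0-based half-open)
    return(GenomicRanges::GRanges(
      as.character(mask[[1]]),
      IRanges::IRanges(start = as.numeric(mask[[2]]) + 1,
                       end = as.numeric(mask[[3]]))))
  }
  if (is.character(mask) && length(mask) == 1L) {
    if (file.size(mask) == 0L) return(GenomicRanges::GRanges())
    # rtracklayer converts BED 0-based half-open to 1-based closed
    return(rtracklayer::import(mask, format = "BED"))
  }
  stop("mask must be a BED path, a GRanges, or a chrom/start/end data frame")
}
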