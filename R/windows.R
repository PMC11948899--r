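# Sliding-window co-segregation proportions along scaffolds.

#' Sliding-window co-segregation proportion scan
#'
#' Tiles every scaffold with windows of `window_size` bp advancing by
#' `step` bp (defaults 1 Mb / 100 kb), anchored at scaffold coordinate 0,
#' and computes per window the proportion of co-segregating variants.  A
#' variant is counted in every window containing it.  Terminal partial
#' windows are kept and flagged.  Repeat-masked variants are excluded from
#' both numerator and denominator.
#'
#' The numerator is always the number of variants co-segregating across all
#' libraries (`combined`).  The denominator depends on `denominator_mode`:
#' `"all_variants"` counts every non-masked variant in the window;
#' `"parental_coseg"` counts only variants whose pattern holds in the
#' parental libraries (`coseg_parental`), so the proportion measures how
#' often a parentally consistent variant is confirmed by the offspring
#' pools.
#'
#' @param verdicts output of [combine_families()] (or any data frame with
#'   columns `scaffold`, `pos`, `in_repeat`, `combined`, `coseg_parental`).
#' @param window_size window width in bp (default 1e6).
#' @param step window offset in bp (default 1e5); `window_size >= step > 0`.
#' @param denominator_mode `"all_variants"` (default) or `"parental_coseg"`.
#' @param scaffold_lengths optional named numeric vector of scaffold
#'   lengths in bp; defaults to the largest variant position per scaffold.
#' @return data frame with columns `scaffold`, `start` (0-based inclusive),
#'   `end` (exclusive), `n_coseg`, `n_denom`, `proportion` (0 when
#'   undefined), `defined` (`n_denom > 0`), `partial`.
#' @export
scan_windows <- function(verdicts, window_size = 1e6, step = 1e5,
                         denominator_mode = c("all_variants",
                                              "parental_coseg"),
                         scaffold_lengths = NULL) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(window_size >= step, step > 0)
  v <- verdicts[!verdicts$in_repeat, , drop = FALSE]
  if (nrow(v) && is.unsorted(order(v$scaffold, v$pos))) {
    # callers may hand over unsorted tables; order is restored quietly
    v <- v[order(v$scaffold, v$pos), ]
  }
  scaffolds <- if (!is.null(scaffold_lengths)) names(scaffold_lengths)
               else unique(v$scaffold)
  out <- vector("list", length(scaffolds))
  for (i in seq_along(scaffolds)) {
    sc <- scaffolds[i]
    len <- if (!is.null(scaffold_lengths)) scaffold_lengths[[sc]]
           else max(v$pos[v$scaffold == sc], 0)
    if (len <= 0) next
    starts <- seq(0, max(0, len - 1), by = step)
    ends <- pmin(starts + window_size, len)
    vi <- v[v$scaffold == sc, , drop = FALSE]
    win <- IRanges::IRanges(start = starts + 1, end = ends)  # 1-based closed
    posr <- IRanges::IRanges(start = vi$pos, width = 1)
    num <- IRanges::countOverlaps(win, posr[which(vi$combined)])
    denom <- switch(denominator_mode,
      all_variants = IRanges::countOverlaps(win, posr),
      parental_coseg = IRanges::countOverlaps(win,
                                              posr[which(vi$coseg_parental)]))
    out[[i]] <- data.frame(
      scaffold = sc, start = starts, end = ends,
      n_coseg = num, n_denom = denom,
      proportion = ifelse(denom > 0, num / denom, 0),
      defined = denom > 0,
      partial = (ends - starts) < window_size,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), n_coseg = integer(),
                      n_denom = integer(), proportion = numeric(),
                      defined = logical(), partial = logical())
  rownames(out) <- NULL
  out
}

#' Write per-window statistics as TSV
#' @param stats output of [scan_windows()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(stats, path) write_tsv_plain(stats, path)
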