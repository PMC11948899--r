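# Simulated reads tiling an insertion junction, with SAM output and
# per-read truth labels for the junction-spanning definition.

#' Simulate reads tiling an insertion junction
#'
#' Places reads with uniform alignment starts along a junction-bearing
#' reference, draws soft-clip lengths at each read end from a simple clip
#' model, and labels each read with the per-base truth: does its aligned
#' span cover a junction boundary with at least 10 bases on each side?
#' The truth label is independent of the start-window detection rule, so
#' detector-vs-truth comparisons expose exactly the reads on which the two
#' definitions differ.
#'
#' @param junction a [junction_model()].
#' @param read_length read length in bp (> 20).
#' @param n_reads number of reads (0 gives an empty, valid SAM).
#' @param ref_length reference length (default `downstream + 500`).
#' @param clip_model list with `prob` (probability that a given read end
#'   is clipped) and `lengths` (clip lengths sampled uniformly); use
#'   `prob = 0` for clean reads or `lengths = 6` (say) to force failing
#'   clips.
#' @param seed RNG seed.
#' @param sam_path optional SAM output path (minimal `@HD`/`@SQ` header).
#' @return data frame `read_id`, `start`, `cigar`, `read_length`,
#'   `clip_left`, `clip_right`, `spans_upstream`, `spans_downstream`,
#'   `spans_any` with attribute `sam_path`.
#' @export
simulate_junction_reads <- function(junction, read_length = 100,
                                    n_reads = 1000, ref_length = NULL,
                                    clip_model = list(prob = 0.2,
                                                      lengths = 1:8),
                                    seed = 1, sam_path = NULL) {
  stopifnot(inherits(junction, "junction_model"), read_length > 20)
  ref_length <- ref_length %||% (junction$downstream + 500)
  set.seed(seed)
  if (n_reads > 0) {
    clip <- function()
      ifelse(stats::runif(n_reads) < clip_model$prob,
             sample(rep(clip_model$lengths, 2), n_reads, replace = TRUE), 0L)
    clip_l <- clip(); clip_r <- clip()
    m <- read_length - clip_l - clip_r
    stopifnot(all(m >= 1))
    start <- floor(stats::runif(n_reads, 1, ref_length - m + 1 + 1))
    start <- pmin(start, ref_length - m + 1)
    end <- start + m - 1
    cigar <- paste0(ifelse(clip_l > 0, paste0(clip_l, "S"), ""),
                    m, "M",
                    ifelse(clip_r > 0, paste0(clip_r, "S"), ""))
    spans <- function(J) start <= J - 9 & end >= J + 10
    reads <- data.frame(
      read_id = sprintf("read_%06d", seq_len(n_reads)),
      start = start, cigar = cigar, read_length = read_length,
      clip_left = clip_l, clip_right = clip_r,
      spans_upstream = spans(junction$upstream),
      spans_downstream = spans(junction$downstream),
      stringsAsFactors = FALSE)
    reads$spans_any <- reads$spans_upstream | reads$spans_downstream
  } else {
    reads <- data.frame(read_id = character(), start = integer(),
                        cigar = character(), read_length = integer(),
                        clip_left = integer(), clip_right = integer(),
                        spans_upstream = logical(),
                        spans_downstream = logical(), spans_any = logical(),
                        stringsAsFactors = FALSE)
  }
  if (!is.null(sam_path)) {
    write_sim_sam(sam_path, reads, junction$reference_id, ref_length)
    attr(reads, "sam_path") <- sam_path
  }
  reads
}

write_sim_sam <- function(path, reads, ref_id, ref_length) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_id, as.integer(ref_length))),
             con)
  if (nrow(reads)) {
    seqs <- vapply(reads$read_length, function(n)
      paste(sample(DNA_BASES, n, replace = TRUE), collapse = ""),
      character(1))
    writeLines(paste(reads$read_id, 0L, ref_id, reads$start, 60L,
                     reads$cigar, "*", 0L, 0L, seqs, "*", sep = "\t"),
               con)
  }
  invisible(path)
}
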