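# Detection of reads spanning an insertion junction from alignment start
# positions and CIGAR soft clips, against a junction-bearing reference.

#' Describe an insertion junction on a reference sequence
#'
#' The junction-bearing reference is the host sequence with the insert
#' included: the insert occupies positions `(upstream, downstream]`, i.e.
#' `upstream` is the 1-based position of the last host base before the
#' insert and `downstream` the 1-based position of the last insert base.
#'
#' @param reference_id name of the junction-bearing reference sequence.
#' @param upstream 1-based position of the last base before the insert.
#' @param downstream 1-based position of the last base of the insert.
#' @return a `junction_model` with derived `insert_length`.
#' @examples
#' jm <- junction_model("clcn2_stripe", 605, 1002)
#' jm$insert_length  # 397
#' @export
junction_model <- function(reference_id, upstream, downstream) {
  upstream <- as.numeric(upstream); downstream <- as.numeric(downstream)
  stopifnot(downstream > upstream, upstream >= 1)
  structure(list(reference_id = reference_id, upstream = upstream,
                 downstream = downstream,
                 insert_length = downstream - upstream),
            class = "junction_model")
}

#' Read minimal alignment records from a SAM file
#'
#' Loads read id, 1-based leftmost aligned position and CIGAR from a SAM
#' (text) file via Rsamtools, returning the minimal record table consumed
#' by [detect_junction_reads()].  Unmapped records are dropped.
#'
#' @param sam path to a SAM file with a valid header.
#' @return data frame `read_id`, `start`, `cigar`, `read_length` (query
#'   length implied by the CIGAR).
#' @export
read_sam_alignments <- function(sam) {
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(what = c("qname", "pos", "cigar"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(res$pos)
  data.frame(read_id = res$qname[keep], start = res$pos[keep],
             cigar = res$cigar[keep],
             read_length = GenomicAlignments::cigarWidthAlongQuerySpace(
               res$cigar[keep], after.soft.clipping = FALSE),
             stringsAsFactors = FALSE)
}

#' Detect reads spanning an insertion junction
#'
#' Implements the start-window/soft-clip filter for insertion-spanning
#' reads: for each junction boundary `J` (the insert start boundary
#' `upstream` or end boundary `downstream`), a read is retained iff its
#' alignment start lies in `[J + start_window[1], J + start_window[2]]`
#' (default `[J - 80, J - 10]`) *and* every soft- or hard-clipped region is
#' strictly shorter than `max_softclip` bases (default 5) at both read
#' ends.  For ~100 bp reads the start window guarantees at least 10 aligned
#' bases on each side of the junction.  Overhangs are computed from the
#' reference-consuming CIGAR operations; a retained read whose aligned span
#' nonetheless ends on or before the junction (possible only for short or
#' heavily deleted alignments) is dropped, since it spans nothing.
#'
#' @param reads data frame with columns `read_id`, `start` (1-based
#'   leftmost aligned position), `cigar` -- e.g. from
#'   [read_sam_alignments()] or [simulate_junction_reads()].
#' @param junction a [junction_model()].
#' @param start_window numeric length-2, offsets of the allowed alignment
#'   start relative to the junction (default `c(-80, -10)`).
#' @param max_softclip clips must be `< max_softclip` bases (strict;
#'   default 5).  Hard clips count as clips.
#' @return data frame of junction hits: `read_id`, `junction`
#'   (`"upstream"`/`"downstream"`), `start`, `end`, `left_overhang`,
#'   `right_overhang`, `max_clip`.
#' @export
detect_junction_reads <- function(reads, junction,
                                  start_window = c(-80, -10),
                                  max_softclip = 5) {
  stopifnot(inherits(junction, "junction_model"),
            length(start_window) == 2, start_window[1] <= start_window[2])
  if (nrow(reads) == 0L)
    return(data.frame(read_id = character(), junction = character(),
                      start = numeric(), end = numeric(),
                      left_overhang = numeric(), right_overhang = numeric(),
                      max_clip = numeric(), stringsAsFactors = FALSE))
  ops <- GenomicAlignments::explodeCigarOps(reads$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(reads$cigar)
  max_clip <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    if (!all(o %in% c("M", "I", "D", "S", "H", "=", "X", "N")))
      stop("unsupported CIGAR op in '", reads$cigar[i], "'")
    # clips are only legal at the ends (H outermost, then S)
    clip_idx <- which(o %in% c("S", "H"))
    core_idx <- which(!(o %in% c("S", "H")))
    if (length(core_idx) == 0L)
      stop("CIGAR '", reads$cigar[i], "' has no aligned bases")
    if (any(clip_idx > min(core_idx) & clip_idx < max(core_idx)))
      stop("internal clip op in CIGAR '", reads$cigar[i], "'")
    if (length(clip_idx)) max(l[clip_idx]) else 0
  }, numeric(1))
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  start <- reads$start
  end <- start + ref_w - 1
  clip_ok <- max_clip < max_softclip

  hit_one <- function(J, label) {
    sel <- which(clip_ok &
                   start >= J + start_window[1] &
                   start <= J + start_window[2] &
                   end > J)  # must actually reach past the junction
    data.frame(read_id = reads$read_id[sel],
               junction = rep(label, length(sel)),
               start = start[sel], end = end[sel],
               left_overhang = J - start[sel] + 1,
               right_overhang = end[sel] - J,
               max_clip = max_clip[sel], stringsAsFactors = FALSE)
  }
  out <- rbind(hit_one(junction$upstream, "upstream"),
               hit_one(junction$downstream, "downstream"))
  rownames(out) <- NULL
  out
}

#' Write junction hits as TSV
#' @param hits output of [detect_junction_reads()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_junction_hits <- function(hits, path) write_tsv_plain(hits, path)
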