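# Counting near-identical retroelement copies in a genome by a local
# seed-and-extend search under aligned-length and identity thresholds.

#' Define a retroelement copy-scan query
#'
#' @param element_seq the element sequence (character or `DNAString`).
#' @param min_match_len minimum aligned length in bp for a hit to count as
#'   a copy (default 5000).
#' @param min_identity minimum identity, matches over alignment columns
#'   (gaps count against identity; default 0.95).
#' @return an `element_query` object.
#' @export
element_query <- function(element_seq, min_match_len = 5000,
                          min_identity = 0.95) {
  seq <- toupper(as.character(element_seq))
  stopifnot(min_identity > 0, min_identity <= 1)
  if (min_match_len > nchar(seq))
    stop("min_match_len (", min_match_len,
         ") exceeds the element length (", nchar(seq), ")")
  structure(list(element_seq = seq, min_match_len = min_match_len,
                 min_identity = min_identity), class = "element_query")
}

#' Count near-identical element copies in a genome
#'
#' Seed-and-extend homology search: exact `seed_k`-mers sampled every
#' `seed_stride` bases along the query are anchored in the genome
#' (`matchPDict`), anchors on nearby diagonals are chained, and every
#' chained candidate locus with at least two anchors is verified by a
#' gapped local alignment of the element against the candidate region.  A verified hit counts as a copy when its aligned length (in
#' alignment columns) reaches `min_match_len` and its identity
#' (matches / alignment columns) reaches `min_identity`.  Both strands are
#' searched and overlapping accepted hits at the same locus collapse to a
#' single copy.  Alignment scoring is conventional (match +2, mismatch -3,
#' gap open 5, gap extend 2); the copy criterion is the length/identity
#' threshold pair, not any particular aligner's score.
#'
#' @param genome a `DNAStringSet`, a named character vector of sequences,
#'   or a FASTA path.
#' @param query an [element_query()].
#' @param seed_k exact seed length (default 31, sensitive at 5%
#'   divergence).
#' @param seed_stride spacing of sampled seeds along the query (default
#'   16).
#' @param band maximal diagonal drift within one anchor chain (default
#'   64 bp, generous for substitution-dominated divergence).
#' @param max_anchor_gap maximal genomic gap between chained anchors
#'   (default 2000 bp).
#' @param pad bases of genomic context added around a chained candidate
#'   before alignment (default 200).
#' @return list with `n_copies` (integer) and `loci`, a data frame
#'   (`seqname`, `start`, `end`, `strand`, `identity`, `aligned_len`) of
#'   collapsed copies; plus `hits`, the uncollapsed accepted alignments.
#' @export
scan_element_copies <- function(genome, query, seed_k = 31, seed_stride = 16,
                                band = 64, max_anchor_gap = 2000, pad = 200) {
  stopifnot(inherits(query, "element_query"))
  subj <- genome_to_dnastringset(genome)
  q <- Biostrings::DNAString(query$element_seq)
  qlen <- length(q)
  stopifnot(seed_k <= qlen)
  queries <- list(`+` = q, `-` = Biostrings::reverseComplement(q))

  hits <- list()
  for (si in seq_along(subj)) {
    sname <- names(subj)[si] %||% as.character(si)
    s <- subj[[si]]
    for (strand in names(queries)) {
      qs <- queries[[strand]]
      anch <- seed_anchors(qs, s, seed_k, seed_stride)
      if (nrow(anch) < 2L) next
      min_qspan <- min(query$min_match_len / 4, qlen / 4)
      regions <- chain_anchors(anch, qlen, seed_k, band, max_anchor_gap,
                               pad, length(s), min_qspan)
      for (r in seq_len(nrow(regions))) {
        a <- align_candidate(qs, s, regions$start[r], regions$end[r])
        if (a$aligned_len >= query$min_match_len &&
            a$identity >= query$min_identity) {
          hits[[length(hits) + 1L]] <- data.frame(
            seqname = sname, start = a$start, end = a$end, strand = strand,
            identity = a$identity, aligned_len = a$aligned_len,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(seqname = character(), start = integer(), end = integer(),
               strand = character(), identity = numeric(),
               aligned_len = integer(), stringsAsFactors = FALSE)
  loci <- collapse_hits(hits)
  list(n_copies = nrow(loci), loci = loci, hits = hits)
}

genome_to_dnastringset <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome)) {
    nm <- names(genome) %||% paste0("seq", seq_along(genome))
    return(Biostrings::DNAStringSet(stats::setNames(toupper(genome), nm)))
  }
  stop("genome must be a DNAStringSet, character sequences, or a FASTA path")
}

# Exact k-mer anchors (query position, subject position) for one strand.
seed_anchors <- function(q, s, k, stride) {
  qpos <- seq(1L, length(q) - k + 1L, by = stride)
  seeds <- Biostrings::DNAStringSet(
    lapply(qpos, function(p) Biostrings::subseq(q, p, p + k - 1L)))
  pd <- Biostrings::PDict(seeds)
  m <- Biostrings::matchPDict(pd, s)
  starts <- BiocGenerics::start(m)
  n_per <- S4Vectors::elementNROWS(m)
  data.frame(qpos = rep.int(qpos, n_per),
             spos = unlist(starts, use.names = FALSE))
}

# Group anchors into candidate genomic regions: anchors on nearby
# diagonals (within `band`) and without large genomic gaps form one chain.
# Chains whose anchors cover less than `min_qspan` of the query are
# dropped: they arise from short internal repeats (e.g. the element's own
# terminal repeats cross-matching between copies) and would otherwise
# bridge neighbouring loci into one candidate region.
chain_anchors <- function(anch, qlen, k, band, max_gap, pad, slen,
                          min_qspan = 0) {
  anch$diag <- anch$spos - anch$qpos
  anch <- anch[order(anch$diag, anch$spos), ]
  diag_grp <- cumsum(c(1L, diff(anch$diag) > band))
  cl <- integer(nrow(anch)); cur <- 0L
  for (g in unique(diag_grp)) {
    idx <- which(diag_grp == g)
    idx <- idx[order(anch$spos[idx])]
    sub_grp <- cumsum(c(1L, diff(anch$spos[idx]) > max_gap))
    cl[idx] <- cur + sub_grp
    cur <- cur + max(sub_grp)
  }
  keep <- as.integer(names(which(table(cl) >= 2L)))  # two-hit requirement
  regs <- lapply(keep, function(g) {
    a <- anch[cl == g, ]
    if (diff(range(a$qpos)) + k < min_qspan) return(NULL)
    data.frame(start = max(1L, min(a$spos - a$qpos + 1L) - pad),
               end = min(slen, max(a$spos + k - 1L + (qlen - a$qpos)) + pad))
  })
  regs <- Filter(Negate(is.null), regs)
  if (!length(regs))
    return(data.frame(start = integer(), end = integer()))
  regs <- do.call(rbind, regs)
  # merge overlapping candidate regions to avoid duplicate alignments
  ir <- IRanges::reduce(IRanges::IRanges(regs$start, regs$end))
  data.frame(start = BiocGenerics::start(ir), end = BiocGenerics::end(ir))
}

# Gapped local alignment of the query against one candidate region: true
# copies score across their whole homologous span, flanking background and
# truncated-away query parts stay unaligned.
align_candidate <- function(q, s, rstart, rend) {
  region <- Biostrings::subseq(s, rstart, rend)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(q, region, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  nmat <- Biostrings::nmatch(aln)
  nmis <- Biostrings::nmismatch(aln)
  ins <- sum(S4Vectors::width(unlist(Biostrings::insertion(aln))))
  del <- sum(S4Vectors::width(unlist(Biostrings::deletion(aln))))
  cols <- nmat + nmis + ins + del
  sr <- aln@subject@range
  list(start = rstart + BiocGenerics::start(sr) - 1L,
       end = rstart + BiocGenerics::end(sr) - 1L,
       identity = if (cols > 0) nmat / cols else 0,
       aligned_len = cols)
}

collapse_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  out <- list()
  for (sn in unique(hits$seqname)) {
    h <- hits[hits$seqname == sn, , drop = FALSE]
    ir <- IRanges::IRanges(h$start, h$end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    for (g in unique(grp)) {
      hh <- h[grp == g, , drop = FALSE]
      best <- hh[which.max(hh$identity * hh$aligned_len), , drop = FALSE]
      best$start <- min(hh$start); best$end <- max(hh$end)
      out[[length(out) + 1L]] <- best
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$seqname, out$start), ]
}

#' Write element-scan loci as a GFF3-style feature table
#' @param scan output of [scan_element_copies()].
#' @param path output path.
#' @param source feature source label.
#' @return `path`, invisibly.
#' @export
write_element_gff <- function(scan, path, source = "cosegscan") {
  loci <- scan$loci
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(loci)) {
    lines <- sprintf("%s\t%s\tdispersed_repeat\t%d\t%d\t.\t%s\t.\tID=copy%d;identity=%.4f;aligned_len=%d",
                     loci$seqname, source, loci$start, loci$end, loci$strand,
                     seq_len(nrow(loci)), loci$identity, loci$aligned_len)
    writeLines(lines, con)
  }
  invisible(path)
}
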