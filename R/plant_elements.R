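# Genomes with planted, diverged retroelement copies and recorded truth.

#' Plant diverged element copies in a random genome
#'
#' Builds a uniform-composition random background sequence and replaces
#' non-overlapping segments with copies of the element, each independently
#' mutated by per-base substitutions at the stated divergence (no indels,
#' keeping identity accounting exact for the truth labels), optionally
#' truncated to a prefix, and placed on a random strand.
#'
#' @param genome_len background length in bp; must exceed
#'   `n_copies * length(element_seq)`.
#' @param element_seq the element (character or `DNAString`).
#' @param n_copies number of copies to plant (0 gives a plain random
#'   genome with empty truth).
#' @param divergence per-base substitution probability applied to each
#'   planted copy.
#' @param truncate_to optional vector of copy lengths (prefix truncation);
#'   `NA` entries keep the full element.  Recycled over copies.
#' @param seed RNG seed.
#' @param fasta_path optional FASTA output path (60-column).
#' @param seqname name of the emitted sequence.
#' @return list with `genome` (a `DNAStringSet`) and `truth`, a data frame
#'   `start`, `end`, `strand`, `length`, `divergence` of planted loci.
#' @export
plant_element_copies <- function(genome_len, element_seq, n_copies,
                                 divergence = 0.02, truncate_to = NULL,
                                 seed = 1, fasta_path = NULL,
                                 seqname = "synthetic_genome") {
  el <- toupper(as.character(element_seq))
  el_len <- nchar(el)
  stopifnot(genome_len > n_copies * el_len, n_copies >= 0,
            divergence >= 0, divergence < 1)
  set.seed(seed)
  bg <- sample(DNA_BASES, genome_len, replace = TRUE)

  lens <- if (n_copies > 0) {
    tl <- rep_len(truncate_to %||% NA_real_, n_copies)
    ifelse(is.na(tl), el_len, pmin(tl, el_len))
  } else integer(0)

  # place copies left to right in randomly sized gaps, guaranteeing
  # non-overlap; error if the lengths cannot fit
  starts <- integer(n_copies)
  if (n_copies > 0) {
    slack <- genome_len - sum(lens)
    if (slack <= n_copies)
      stop("copies cannot be placed without overlap")
    cuts <- sort(sample.int(slack - 1L, n_copies))
    gaps <- diff(c(0L, cuts))
    pos <- 0L
    for (i in seq_len(n_copies)) {
      pos <- pos + gaps[i]
      starts[i] <- pos + 1L
      pos <- pos + lens[i]
    }
  }

  truth <- data.frame(start = integer(), end = integer(),
                      strand = character(), length = integer(),
                      divergence = numeric(), stringsAsFactors = FALSE)
  for (i in seq_len(n_copies)) {
    copy <- strsplit(substr(el, 1, lens[i]), "")[[1]]
    mut <- which(stats::runif(lens[i]) < divergence)
    for (p in mut)
      copy[p] <- sample(setdiff(DNA_BASES, copy[p]), 1L)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-")
      copy <- rev(chartr("ACGT", "TGCA", copy))
    bg[starts[i]:(starts[i] + lens[i] - 1L)] <- copy
    truth <- rbind(truth, data.frame(
      start = starts[i], end = starts[i] + lens[i] - 1L, strand = strand,
      length = lens[i], divergence = length(mut) / lens[i],
      stringsAsFactors = FALSE))
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(bg, collapse = ""), seqname))
  if (!is.null(fasta_path))
    Biostrings::writeXStringSet(genome, fasta_path, width = 60)
  list(genome = genome, truth = truth)
}
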