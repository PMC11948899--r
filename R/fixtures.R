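# Synthetic reference fixtures.
#
# The study's supplementary sequences (wild-type and insertion-bearing
# CLCN2 transcripts, the Copia-like element, the element copy inserted in
# OCA2) are not redistributable here, so the package ships *synthetic
# stand-ins* built deterministically in code to satisfy every published
# constraint on those sequences: a 2643 bp CDS translating to an 880 aa
# protein; a 397 bp insert placed after CDS position 605 whose transcript
# encodes 4 novel residues followed by a premature stop, truncating the
# protein to 205 aa; a 5832 bp LTR-bounded element from which the insert's
# three fragments are excised; and a second element copy differing from
# the first by exactly one substitution.  All downstream worked examples
# run on these stand-ins; none of the sequences is biological.

FIXTURE_SEED <- 733001L
FIXTURE_FILES <- c(
  wt_cds = "synthetic_clcn2_wt_cds.fa",
  stripe_insert = "synthetic_stripe_insert.fa",
  stripe_transcript = "synthetic_stripe_transcript.fa",
  element_clcn2 = "synthetic_copia_clcn2.fa",
  element_oca2 = "synthetic_copia_oca2.fa")

# Element coordinates of the three fragments spliced into the transcript
# insert (120 + 150 + 127 = 397 bp), and of the single substitution
# distinguishing the second element copy.
FIXTURE_FRAGMENTS <- list(c(1001, 1120), c(2501, 2650), c(4001, 4127))
FIXTURE_OCA2_SUBST_POS <- 5000L

#' Build the synthetic reference fixtures
#'
#' Deterministically constructs the synthetic stand-in sequences used by
#' the worked examples (see the package source for the constraints they
#' satisfy).  The same sequences are shipped as FASTA under
#' `inst/extdata/`; [fixture_path()] locates them and a test asserts the
#' shipped files match this builder.
#'
#' @return named list of character sequences: `wt_cds` (2643 bp),
#'   `stripe_insert` (397 bp), `stripe_transcript` (3040 bp),
#'   `element_clcn2` (5832 bp), `element_oca2` (5832 bp), plus
#'   `insert_after` (605) and `junction` (the [junction_model()] of the
#'   insertion-bearing transcript, boundaries 605 and 1002).
#' @export
reference_fixtures <- function() {
  with_local_seed(FIXTURE_SEED, build_fixtures())
}

build_fixtures <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  sense <- codons[gc_tab != "*"]
  aa_of <- function(codon) unname(gc_tab[codon])

  # wild-type CDS: ATG + 879 random sense codons + TAA = 2643 bp / 880 aa.
  # Codon 202 is fixed to GAA so that the insertion interrupting it can
  # always complete it to a sense codon encoding a different residue.
  wt_codons <- c("ATG", sample(sense, 879, replace = TRUE), "TAA")
  wt_codons[202] <- "GAA"
  wt_cds <- paste(wt_codons, collapse = "")
  stopifnot(nchar(wt_cds) == 2643)

  # element: two identical 300 bp terminal repeats around a random core
  ltr <- paste(sample(DNA_BASES, 300, replace = TRUE), collapse = "")
  core <- paste(sample(DNA_BASES, 5832 - 600, replace = TRUE), collapse = "")
  element <- paste0(ltr, core, ltr)
  stopifnot(nchar(element) == 5832)

  # The insert interrupts codon 202 after its second base (CDS position
  # 605).  Its first 13 bases are chosen so that codons 202-205 of the
  # mutant transcript are sense codons differing from the wild-type
  # residues, and codon 206 is a stop: 4 novel residues, 205 aa protein.
  insert_after <- 605L
  prefix2 <- substr(wt_cds, 604, 605)
  pick_base <- function() {
    for (b in DNA_BASES) {
      cod <- paste0(prefix2, b)
      if (gc_tab[cod] != "*" && aa_of(cod) != aa_of(wt_codons[202]))
        return(b)
    }
    stop("no completing base found")  # unreachable: <= 2 aa excluded of 20
  }
  pick_codon <- function(not_aa) {
    for (cod in sense) if (aa_of(cod) != not_aa) return(cod)
  }
  head13 <- paste0(pick_base(),
                   pick_codon(aa_of(wt_codons[203])),
                   pick_codon(aa_of(wt_codons[204])),
                   pick_codon(aa_of(wt_codons[205])),
                   "TAA")
  stopifnot(nchar(head13) == 13)
  # write the constrained bases into the element at the start of the first
  # spliced fragment, then excise the three fragments as the insert
  f1 <- FIXTURE_FRAGMENTS[[1]]
  substr(element, f1[1], f1[1] + 12) <- head13
  insert <- paste(vapply(FIXTURE_FRAGMENTS, function(fr)
    substr(element, fr[1], fr[2]), character(1)), collapse = "")
  stopifnot(nchar(insert) == 397)

  # second element copy: exactly one substitution, outside the fragments
  p <- FIXTURE_OCA2_SUBST_POS
  old <- substr(element, p, p)
  element_oca2 <- element
  substr(element_oca2, p, p) <- setdiff(DNA_BASES, old)[1]

  ti <- transcript_insertion(wt_cds, insert, insert_after)
  list(wt_cds = wt_cds,
       stripe_insert = insert,
       stripe_transcript = splice_insertion(ti),
       element_clcn2 = element,
       element_oca2 = element_oca2,
       insert_after = insert_after,
       junction = junction_model("stripe_transcript_synthetic",
                                 upstream = insert_after,
                                 downstream = insert_after + nchar(insert)))
}

#' Locate an installed synthetic fixture FASTA
#'
#' @param name one of `"wt_cds"`, `"stripe_insert"`,
#'   `"stripe_transcript"`, `"element_clcn2"`, `"element_oca2"`.
#' @return file path of the installed FASTA.
#' @export
fixture_path <- function(name) {
  name <- match.arg(name, names(FIXTURE_FILES))
  p <- system.file("extdata", FIXTURE_FILES[[name]], package = "cosegscan",
                   mustWork = TRUE)
  p
}

#' Load an installed synthetic fixture as a character sequence
#' @inheritParams fixture_path
#' @return character sequence.
#' @export
load_fixture <- function(name) {
  as.character(Biostrings::readDNAStringSet(fixture_path(name))[[1]])
}

#' Write the synthetic fixtures as FASTA files
#'
#' Regenerates the shipped `inst/extdata/` FASTA files from
#' [reference_fixtures()].
#'
#' @param dir output directory.
#' @return the written paths, invisibly.
#' @export
write_reference_fixtures <- function(dir) {
  fx <- reference_fixtures()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(FIXTURE_FILES)) {
    p <- file.path(dir, FIXTURE_FILES[[nm]])
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(fx[[nm]],
                                               sub("\\.fa$", "",
                                                   FIXTURE_FILES[[nm]]))),
      p, width = 60)
    paths <- c(paths, p)
  }
  invisible(paths)
}
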