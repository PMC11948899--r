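# Coding consequence of a transcript insertion: splice the insert into the
# CDS, translate, and report truncation by a premature stop codon.

#' Describe an insertion into a coding sequence
#'
#' @param wildtype_cds wild-type coding sequence (character or
#'   `DNAString`); must start with ATG, end with a stop codon, and have
#'   length divisible by 3.
#' @param insert_seq inserted sequence (may be empty).
#' @param insert_after 1-based CDS position after which the insert is
#'   placed (0 = before the first base); need not be codon-aligned.
#' @return a `transcript_insertion` object.
#' @export
transcript_insertion <- function(wildtype_cds, insert_seq, insert_after) {
  wt <- toupper(as.character(wildtype_cds))
  ins <- toupper(as.character(insert_seq))
  stopifnot(nchar(wt) %% 3 == 0, insert_after >= 0,
            insert_after <= nchar(wt))
  if (substr(wt, 1, 3) != "ATG")
    stop("wildtype_cds does not start with ATG")
  if (!substr(wt, nchar(wt) - 2, nchar(wt)) %in% STOP_CODONS)
    stop("wildtype_cds does not end with a stop codon")
  structure(list(wildtype_cds = wt, insert_seq = ins,
                 insert_after = as.integer(insert_after)),
            class = "transcript_insertion")
}

#' Splice an insert into a coding sequence
#'
#' Returns `wildtype_cds[1..insert_after] + insert_seq +
#' wildtype_cds[(insert_after+1)..end]`.  Which genomic fragments of a
#' retroelement splice together into the realised insert is an upstream
#' question; here the realised insert sequence is an input.
#'
#' @param ti a [transcript_insertion()].
#' @return the mutant CDS as a character string.
#' @export
splice_insertion <- function(ti) {
  stopifnot(inherits(ti, "transcript_insertion"))
  wt <- ti$wildtype_cds; a <- ti$insert_after
  paste0(substr(wt, 1, a), ti$insert_seq, substr(wt, a + 1, nchar(wt)))
}

translate_cds <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1, n)),
                                     if.fuzzy.codon = "X"))
}

#' Annotate the coding consequence of a transcript insertion
#'
#' Translates the spliced mutant CDS from position 1 in the wild-type frame
#' (standard nuclear codon table) up to the first in-frame stop codon and
#' compares it with the wild-type protein.  `novel_aa_after_junction`
#' counts the residues beyond the last junction-complete codon
#' (`floor(insert_after / 3)`) that differ from the wild-type residue at
#' the same position (positions beyond the wild-type protein count as
#' novel).  If no stop codon is reached the report is flagged `stop_loss`
#' and `truncated` is `FALSE`.
#'
#' @param ti a [transcript_insertion()].
#' @return a `consequence_report`: list with `mutant_cds`, `protein`,
#'   `protein_length` (aa before the first stop), `wt_protein_length`,
#'   `truncated`, `novel_aa_after_junction`, `stop_loss`.
#' @export
annotate_consequence <- function(ti) {
  stopifnot(inherits(ti, "transcript_insertion"))
  mutant <- splice_insertion(ti)
  aa_mut <- translate_cds(mutant)
  aa_wt <- translate_cds(ti$wildtype_cds)
  wt_len <- nchar(sub("\\*.*$", "", aa_wt))
  stop_at <- regexpr("*", aa_mut, fixed = TRUE)
  stop_loss <- stop_at < 0
  prot <- if (stop_loss) aa_mut else substr(aa_mut, 1, stop_at - 1)
  p_len <- nchar(prot)
  j <- ti$insert_after %/% 3L
  novel <- 0L
  if (p_len > j) {
    mut_tail <- strsplit(substr(prot, j + 1, p_len), "")[[1]]
    wt_tail <- strsplit(substr(aa_wt, j + 1, j + length(mut_tail)), "")[[1]]
    wt_tail <- c(wt_tail, rep("", length(mut_tail) - length(wt_tail)))
    novel <- sum(mut_tail != wt_tail | wt_tail == "*")
  }
  structure(list(mutant_cds = mutant, protein = prot,
                 protein_length = p_len, wt_protein_length = wt_len,
                 truncated = !stop_loss && p_len < wt_len,
                 novel_aa_after_junction = as.integer(novel),
                 stop_loss = stop_loss),
            class = "consequence_report")
}

#' @export
print.consequence_report <- function(x, ...) {
  cat(sprintf("consequence_report: %d aa (wild type %d aa); %s%s; %d novel residue(s) after the junction\n",
              x$protein_length, x$wt_protein_length,
              if (x$truncated) "truncated by premature stop" else "not truncated",
              if (x$stop_loss) " [stop-loss]" else "",
              x$novel_aa_after_junction))
  invisible(x)
}

#' Serialise a consequence report to JSON
#' @param x a `consequence_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_consequence_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
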