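# Loading multi-sample VCF genotypes into per-alt-allele genotype classes.

#' Classify a diploid GT string relative to one alternate allele
#'
#' Maps VCF `GT` strings to the four genotype classes used by the
#' co-segregation filter, relative to the alternate allele with (1-based)
#' index `alt_index` after multi-allelic splitting.  `0/0` is `hom_ref`,
#' `k/k` (the split alt) is `hom_alt`, any genotype containing a `.` is
#' `missing`, and everything else -- including genotypes carrying a
#' non-reference allele other than the split alt, such as `1/2` when
#' splitting alt 1 -- is `het`, preserving the hom-vs-het dichotomy of the
#' filter without discarding multi-allelic sites.  Phased separators (`|`)
#' are accepted and reduced to unphased classes.
#'
#' @param gt character vector of GT strings (e.g. `"0/1"`, `"1|0"`, `"./."`).
#' @param alt_index 1-based index of the alternate allele of the split.
#' @return character vector of classes in
#'   `c("hom_ref","het","hom_alt","missing")`.
#' @examples
#' classify_gt(c("0/0", "0/1", "1|0", "./.", "1/2"), alt_index = 1)
#' @export
classify_gt <- function(gt, alt_index = 1L) {
  u <- unique(gt)
  cls <- vapply(u, function(g) {
    if (is.na(g)) return("missing")
    a <- strsplit(g, "[/|]")[[1]]
    if (length(a) < 1L || length(a) > 2L ||
        !all(grepl("^(\\.|[0-9]+)$", a)))
      stop("malformed GT string: '", g, "'")
    if (length(a) == 1L) a <- c(a, a)  # haploid call, treated as homozygous
    if (any(a == ".")) return("missing")
    ai <- as.integer(a)
    if (all(ai == 0L)) "hom_ref"
    else if (all(ai == alt_index)) "hom_alt"
    else "het"
  }, character(1))
  unname(cls[match(gt, u)])
}

#' Load variants and genotype classes from a multi-sample VCF
#'
#' Reads a VCF (plain or gzipped), restricts to the samples of a
#' [cross_design()], splits multi-allelic records into one variant per
#' alternate allele, and classifies every sample genotype relative to each
#' split alt with [classify_gt()].  Samples present in the VCF but absent
#' from the design are ignored; a design sample missing from the VCF header
#' is a configuration error.
#'
#' @param vcf path to a VCF file, or a `vcfR::vcfR` object.
#' @param design a [cross_design()].
#' @param pass_only if `TRUE`, keep only records with `FILTER` equal to
#'   `PASS` (or `.`).  Off by default: the co-segregation filter itself is
#'   the screen.
#' @return an object of class `coseg_variants`: a list with
#'   \describe{
#'     \item{table}{data frame `scaffold`, `pos` (1-based), `ref`, `alt`,
#'       `alt_index`, `in_repeat` (all `FALSE` until
#'       [apply_repeat_mask()]).}
#'     \item{classes}{character matrix, one row per split variant, one
#'       column per design sample, values in
#'       `c("hom_ref","het","hom_alt","missing")`.}
#'     \item{samples}{design sample ids (column order of `classes`).}
#'   }
#' @export
load_variants <- function(vcf, design, pass_only = FALSE) {
  stopifnot(inherits(design, "cross_design"))
  v <- if (inherits(vcf, "vcfR")) vcf else vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- design$samples$sample_id
  if (nrow(fix) == 0L) {
    return(new_coseg_variants(
      data.frame(scaffold = character(), pos = integer(), ref = character(),
                 alt = character(), alt_index = integer(),
                 in_repeat = logical(), stringsAsFactors = FALSE),
      matrix(character(), 0, length(ids), dimnames = list(NULL, ids)), ids))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  absent <- setdiff(ids, colnames(gt))
  if (length(absent))
    stop("design sample(s) not in VCF header: ", paste(absent, collapse = ", "))
  gt <- gt[, ids, drop = FALSE]
  keep <- rep(TRUE, nrow(fix))
  if (pass_only) {
    filt <- fix[, "FILTER"]
    keep <- is.na(filt) | filt %in% c("PASS", ".")
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep.int(seq_len(nrow(fix)), n_alt)
  alt_index <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  tbl <- data.frame(
    scaffold = fix[rec, "CHROM"],
    pos = as.integer(fix[rec, "POS"]),
    ref = fix[rec, "REF"],
    alt = unlist(alts, use.names = FALSE),
    alt_index = alt_index,
    in_repeat = FALSE,
    stringsAsFactors = FALSE)
  cls <- matrix(NA_character_, nrow(tbl), length(ids),
                dimnames = list(NULL, ids))
  for (k in unique(alt_index)) {
    rows <- which(alt_index == k)
    sub <- gt[rec[rows], , drop = FALSE]
    cls[rows, ] <- classify_gt(as.vector(sub), alt_index = k)
  }
  new_coseg_variants(tbl, cls, ids)
}

new_coseg_variants <- function(table, classes, samples) {
  structure(list(table = table, classes = classes, samples = samples),
            class = "coseg_variants")
}

#' Number of (split) variants
#' @param x a `coseg_variants` object.
#' @return integer count.
#' @export
n_variants <- function(x) nrow(x$table)

#' @export
print.coseg_variants <- function(x, ...) {
  cat("coseg_variants:", n_variants(x), "split variants x",
      length(x$samples), "samples;",
      sum(x$table$in_repeat), "in repeat regions\n")
  invisible(x)
}
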