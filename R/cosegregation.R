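# The co-segregation filter: a variant co-segregates with the recessive
# trait when every affected-role sample shows the orientation-expected
# homozygous class and every carrier-role sample is heterozygous.

#' Classify co-segregation of variants within one family
#'
#' Applies the recessive-trait genotype filter to one family of a cross
#' design: a variant co-segregates iff every affected-role sample of the
#' family has the orientation-expected homozygous class (0/0 when the
#' reference carries the mutant allele) and every carrier-role sample is
#' heterozygous.  Under `missing_policy = "fail_variant"` any missing
#' genotype in a required sample makes the variant non-co-segregating;
#' under `"ignore_sample"` missing samples are dropped from the test (a
#' variant with no informative sample left is not co-segregating).
#'
#' @param x a `coseg_variants` object, or a character matrix of genotype
#'   classes with sample ids as column names.
#' @param design a [cross_design()].
#' @param family_id family to classify.
#' @param roles which design roles participate: `"all"` (default) or
#'   `"parents"` (parental libraries only, used for the alternative window
#'   denominator).
#' @return logical vector, one element per variant.
#' @export
classify_cosegregation <- function(x, design, family_id,
                                   roles = c("all", "parents")) {
  roles <- match.arg(roles)
  cls <- if (inherits(x, "coseg_variants")) x$classes else as.matrix(x)
  s <- design$samples[design$samples$family_id == family_id, , drop = FALSE]
  if (roles == "parents")
    s <- s[s$role %in% PARENT_ROLES, , drop = FALSE]
  if (nrow(s) == 0L)
    stop("no samples for family '", family_id, "'",
         if (roles == "parents") " with a parental role")
  exp_cls <- expected_class(s$role, design$orientation)
  sub <- cls[, s$sample_id, drop = FALSE]
  if (nrow(sub) == 0L) return(logical(0))
  ok <- sub == matrix(exp_cls, nrow(sub), ncol(sub), byrow = TRUE)
  miss <- sub == "missing"
  if (design$missing_policy == "ignore_sample") {
    ok[miss] <- TRUE
    res <- rowSums(!ok) == 0L & rowSums(!miss) > 0L
  } else {
    res <- rowSums(!ok) == 0L  # missing never matches an expected class
  }
  unname(res)
}

#' Per-family and combined co-segregation verdicts
#'
#' Runs [classify_cosegregation()] for every family of the design and takes
#' the combined verdict as the conjunction over families -- equivalently,
#' the expected genotype pattern holding across the union of all samples.
#' A shared parent sequenced as one library per family contributes once per
#' family.  Variants flagged `in_repeat` are skipped (all verdicts `NA`).
#' An additional `coseg_parental` column applies the same pattern to the
#' parental libraries only, across all families; it serves as the
#' alternative window-scan denominator.
#'
#' @param x a `coseg_variants` object.
#' @param design a [cross_design()].
#' @return data frame with columns `scaffold`, `pos`, `alt_index`,
#'   `in_repeat`, one logical `coseg_<family>` column per family,
#'   `combined`, and `coseg_parental`.
#' @export
combine_families <- function(x, design) {
  stopifnot(inherits(x, "coseg_variants"))
  fams <- design_families(design)
  out <- x$table[, c("scaffold", "pos", "alt_index", "in_repeat")]
  masked <- out$in_repeat
  for (fam in fams) {
    v <- classify_cosegregation(x, design, fam)
    v[masked] <- NA
    out[[paste0("coseg_", fam)]] <- v
  }
  fam_cols <- paste0("coseg_", fams)
  comb <- rep(TRUE, nrow(out))
  for (col in fam_cols) comb <- comb & out[[col]]
  out$combined <- comb
  par <- rep(TRUE, nrow(out))
  for (fam in fams)
    par <- par & classify_cosegregation(x, design, fam, roles = "parents")
  par[masked] <- NA
  out$coseg_parental <- par
  out
}

#' Write the per-variant co-segregation table
#'
#' TSV with one row per non-masked split variant: scaffold, position, alt
#' index, per-family flags and the combined flag.
#'
#' @param verdicts output of [combine_families()].
#' @param path output TSV path.
#' @param keep_masked include repeat-masked variants (verdicts `NA`)?
#' @return `path`, invisibly.
#' @export
write_coseg_table <- function(verdicts, path, keep_masked = FALSE) {
  v <- if (keep_masked) verdicts else verdicts[!verdicts$in_repeat, ]
  write_tsv_plain(v, path)
}
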