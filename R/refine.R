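# Interval refinement from Sanger-genotyped recombinant individuals.

#' Refine a candidate interval with genotyped recombinant individuals
#'
#' Offspring genotyped at predefined sites inside (or flanking) the
#' candidate interval constrain the causal locus: an affected individual is
#' expected homozygous (orientation-appropriate class) at every fully
#' linked site, a carrier heterozygous.  A site whose class contradicts the
#' individual's phenotype places a recombination breakpoint; the causal
#' locus must lie in the individual's *consistent segment*, the maximal run
#' of phenotype-consistent sites bounded (exclusively) by the nearest
#' inconsistent sites.  The refined interval is the original interval
#' intersected with every individual's consistent segment; individuals with
#' no inconsistent site do not constrain.  When inconsistent sites split an
#' individual's sites into several consistent runs, the run with the
#' largest overlap with the current interval is taken.
#'
#' @param interval an [call_interval()] result (or a list with `scaffold`,
#'   `start_bp`, `end_bp`).
#' @param sites data frame with columns `individual_id`, `phenotype`
#'   (`"affected"` or `"carrier"`), `position` (1-based bp), `genotype`
#'   (class names `hom_ref`/`het`/`hom_alt`/`missing`, or GT strings such
#'   as `"0/1"`).  Sites with missing genotypes are dropped.
#' @param orientation design orientation (see [cross_design()]).
#' @param verdicts optional [combine_families()] table to recount
#'   co-segregating variants and density inside the refined interval.
#' @return an `interval_call` with the refined coordinates and an added
#'   `recombinants` data frame (`individual_id`, `phenotype`,
#'   `is_recombinant`, `segment_lo`, `segment_hi`).  An empty intersection
#'   is an error naming the conflicting individuals.
#' @export
refine_with_recombinants <- function(interval, sites,
                                     orientation = "reference_carries_mutant",
                                     verdicts = NULL) {
  stopifnot(!isTRUE(interval$no_signal))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  req <- c("individual_id", "phenotype", "position", "genotype")
  if (!all(req %in% names(sites)))
    stop("sites needs columns: ", paste(req, collapse = ", "))
  gt <- sites$genotype
  looks_gt <- grepl("[/|]", gt)
  gt[looks_gt] <- classify_gt(gt[looks_gt])
  if (!all(gt %in% GENOTYPE_CLASSES))
    stop("unrecognised genotype value(s): ",
         paste(unique(sites$genotype[!gt %in% GENOTYPE_CLASSES]),
               collapse = ", "))
  sites$genotype <- gt
  sites <- sites[sites$genotype != "missing", , drop = FALSE]

  lo <- interval$start_bp; hi <- interval$end_bp
  inds <- unique(sites$individual_id)
  rec <- data.frame(individual_id = inds,
                    phenotype = NA_character_,
                    is_recombinant = FALSE,
                    segment_lo = -Inf, segment_hi = Inf,
                    stringsAsFactors = FALSE)
  for (i in seq_along(inds)) {
    s <- sites[sites$individual_id == inds[i], , drop = FALSE]
    s <- s[order(s$position), ]
    phen <- unique(s$phenotype)
    if (length(phen) != 1L || !phen %in% c("affected", "carrier"))
      stop("individual '", inds[i],
           "' must have a single phenotype 'affected' or 'carrier'")
    rec$phenotype[i] <- phen
    expc <- if (phen == "affected") {
      if (orientation == "reference_carries_mutant") "hom_ref" else "hom_alt"
    } else "het"
    consistent <- s$genotype == expc
    if (all(consistent)) next
    rec$is_recombinant[i] <- TRUE
    # candidate segments: open intervals between consecutive inconsistent
    # sites that contain at least one consistent site
    bad_pos <- s$position[!consistent]
    bounds_lo <- c(-Inf, bad_pos)
    bounds_hi <- c(bad_pos, Inf)
    seg_ok <- vapply(seq_along(bounds_lo), function(k) {
      any(consistent & s$position > bounds_lo[k] & s$position < bounds_hi[k])
    }, logical(1))
    if (!any(seg_ok))
      stop("individual '", inds[i],
           "' is inconsistent at every genotyped site; ",
           "check phenotyping or the candidate interval")
    # exclusive breakpoint bounds -> half-open bp coordinates:
    # a lower inconsistent site at 1-based p excludes base p => start = p;
    # an upper inconsistent site at p excludes base p => end = p - 1.
    seg_start <- ifelse(is.finite(bounds_lo), bounds_lo, -Inf)
    seg_end <- ifelse(is.finite(bounds_hi), bounds_hi - 1, Inf)
    overlap <- pmax(0, pmin(seg_end, hi) - pmax(seg_start, lo))
    pick <- which(seg_ok)[which.max(overlap[seg_ok])]
    rec$segment_lo[i] <- seg_start[pick]
    rec$segment_hi[i] <- seg_end[pick]
  }
  new_lo <- max(lo, rec$segment_lo)
  new_hi <- min(hi, rec$segment_hi)
  if (new_hi <= new_lo) {
    conf <- rec$individual_id[rec$is_recombinant]
    stop("recombinant constraints leave an empty interval; conflicting ",
         "individuals: ", paste(conf, collapse = ", "),
         " (phenotyping/genotyping error, or wrong candidate interval)")
  }
  out <- interval
  out$start_bp <- new_lo
  out$end_bp <- new_hi
  out$length_mb <- (new_hi - new_lo) / 1e6
  if (!is.null(verdicts)) {
    vv <- verdicts[!verdicts$in_repeat & verdicts$scaffold == out$scaffold &
                     verdicts$pos > new_lo & verdicts$pos <= new_hi, ,
                   drop = FALSE]
    out$n_coseg <- sum(vv$combined, na.rm = TRUE)
  }
  out$density_per_mb <- round_half_up(out$n_coseg / out$length_mb)
  out$recombinants <- rec
  out
}

#' Read recombinant genotyping sites from TSV
#'
#' Columns: `individual_id`, `phenotype`, `position`, `genotype`.
#'
#' @param path TSV path.
#' @return data frame suitable for [refine_with_recombinants()].
#' @export
read_recombinant_sites <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
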