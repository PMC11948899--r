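# End-to-end orchestration: variant loading through interval calling, and
# the insertion-evidence suite.  Reports are plain lists with a stable key
# order and no timestamps, so a rerun with the same inputs is
# byte-identical.

#' Run the full mapping pipeline
#'
#' Executes load -> repeat mask -> per-family and combined co-segregation
#' -> window scan -> interval call, and optionally interval refinement
#' from recombinant genotyping sites.  Writes the per-variant table, the
#' window statistics and the interval JSON when `out_dir` is given.
#'
#' @param vcf VCF path or `vcfR` object.
#' @param design a [cross_design()] or a design TSV path.
#' @param mask optional repeat mask (BED path, `GRanges` or data frame).
#' @param window_size,step window parameters in bp (defaults 1 Mb /
#'   100 kb).
#' @param denominator_mode see [scan_windows()].
#' @param threshold_fraction see [call_interval()].
#' @param recombinant_sites optional data frame or TSV path for
#'   [refine_with_recombinants()].
#' @param scaffold_lengths optional named lengths for window tiling.
#' @param pass_only see [load_variants()].
#' @param out_dir optional output directory.
#' @return a `run_report` list: `config` (the parameters), `counts`
#'   (variants loaded, masked, retained, co-segregating per family and
#'   combined), `interval`, and `refined` (when sites were given).
#' @export
run_mapping <- function(vcf, design, mask = NULL,
                        window_size = 1e6, step = 1e5,
                        denominator_mode = "all_variants",
                        threshold_fraction = 0.9,
                        recombinant_sites = NULL,
                        scaffold_lengths = NULL,
                        pass_only = FALSE,
                        out_dir = NULL) {
  if (is.character(design)) design <- read_cross_design(design)
  x <- load_variants(vcf, design, pass_only = pass_only)
  if (!is.null(mask)) x <- apply_repeat_mask(x, mask)
  verdicts <- combine_families(x, design)
  stats <- scan_windows(verdicts, window_size = window_size, step = step,
                        denominator_mode = denominator_mode,
                        scaffold_lengths = scaffold_lengths)
  interval <- call_interval(stats, verdicts,
                            threshold_fraction = threshold_fraction)
  fams <- design_families(design)
  counts <- c(list(loaded = nrow(verdicts),
                   masked = sum(verdicts$in_repeat),
                   retained = sum(!verdicts$in_repeat)),
              stats::setNames(
                lapply(fams, function(f)
                  sum(verdicts[[paste0("coseg_", f)]], na.rm = TRUE)),
                paste0("coseg_", fams)),
              list(combined = sum(verdicts$combined, na.rm = TRUE)))
  refined <- NULL
  if (!is.null(recombinant_sites) && !interval$no_signal) {
    if (is.character(recombinant_sites))
      recombinant_sites <- read_recombinant_sites(recombinant_sites)
    refined <- refine_with_recombinants(interval, recombinant_sites,
                                        orientation = design$orientation,
                                        verdicts = verdicts)
  }
  report <- list(
    tool = "cosegscan",
    version = as.character(utils::packageVersion("cosegscan")),
    config = list(window_size = window_size, step = step,
                  denominator_mode = denominator_mode,
                  threshold_fraction = threshold_fraction,
                  pass_only = pass_only,
                  orientation = design$orientation,
                  missing_policy = design$missing_policy),
    counts = counts,
    interval = unclass(interval),
    refined = if (!is.null(refined))
      unclass(refined)[setdiff(names(refined), "recombinants")])
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_coseg_table(verdicts, file.path(out_dir, "coseg_table.tsv"))
    write_window_stats(stats, file.path(out_dir, "window_stats.tsv"))
    write_interval_json(if (is.null(refined)) interval else refined,
                        file.path(out_dir, "interval.json"))
    write_report_json(report, file.path(out_dir, "run_report.json"))
  }
  attr(report, "verdicts") <- verdicts
  attr(report, "window_stats") <- stats
  attr(report, "interval_call") <- interval
  attr(report, "refined_call") <- refined
  report
}

#' Run the insertion-evidence suite
#'
#' Detects junction-spanning reads in a SAM file against a junction model
#' and, when transcript inputs are given, annotates the coding consequence
#' of the insertion.
#'
#' @param sam SAM path, or a read data frame (`read_id`, `start`,
#'   `cigar`).
#' @param junction a [junction_model()].
#' @param start_window,max_softclip see [detect_junction_reads()].
#' @param wt_cds,insert_seq,insert_after optional transcript-insertion
#'   inputs for [annotate_consequence()].
#' @param out_dir optional output directory.
#' @return a `run_report` list with `counts` (`reads`, `junction_hits`,
#'   per-junction counts) and `consequence` (or `NULL`).
#' @export
run_insertion_suite <- function(sam, junction,
                                start_window = c(-80, -10), max_softclip = 5,
                                wt_cds = NULL, insert_seq = NULL,
                                insert_after = NULL, out_dir = NULL) {
  reads <- if (is.character(sam)) read_sam_alignments(sam) else sam
  hits <- detect_junction_reads(reads, junction,
                                start_window = start_window,
                                max_softclip = max_softclip)
  consequence <- NULL
  if (!is.null(wt_cds)) {
    if (is.null(insert_seq) || is.null(insert_after))
      stop("consequence annotation needs wt_cds, insert_seq and insert_after")
    consequence <- annotate_consequence(
      transcript_insertion(wt_cds, insert_seq, insert_after))
  }
  report <- list(
    tool = "cosegscan",
    version = as.character(utils::packageVersion("cosegscan")),
    config = list(reference_id = junction$reference_id,
                  upstream = junction$upstream,
                  downstream = junction$downstream,
                  start_window = start_window,
                  max_softclip = max_softclip),
    counts = list(reads = nrow(reads),
                  junction_hits = nrow(hits),
                  upstream_hits = sum(hits$junction == "upstream"),
                  downstream_hits = sum(hits$junction == "downstream")),
    consequence = if (!is.null(consequence))
      unclass(consequence)[c("protein_length", "wt_protein_length",
                             "truncated", "novel_aa_after_junction",
                             "stop_loss")])
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_junction_hits(hits, file.path(out_dir, "junction_hits.tsv"))
    if (!is.null(consequence))
      write_consequence_json(consequence,
                             file.path(out_dir, "consequence.json"))
    write_report_json(report, file.path(out_dir, "run_report.json"))
  }
  attr(report, "hits") <- hits
  attr(report, "consequence_report") <- consequence
  report
}

write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("cosegscan run_report (v", x$version, ")\n", sep = "")
  utils::str(x$counts, no.list = TRUE)
  if (!is.null(x$interval)) {
    iv <- x$interval
    if (isTRUE(iv$no_signal)) cat("interval: no signal\n")
    else cat(sprintf("interval: %s:%.0f-%.0f (%d co-segregating, %g/Mb)\n",
                     iv$scaffold, iv$start_bp, iv$end_bp, iv$n_coseg,
                     iv$density_per_mb))
  }
  invisible(x)
}
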