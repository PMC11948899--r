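# Shared builders for tests: a minimal one-family design, hand-written VCF
# text (independent of the simulator's writer), and small oracles.

one_family_design <- function(missing_policy = "fail_variant",
                              orientation = "reference_carries_mutant") {
  cross_design(data.frame(
    sample_id = c("sire", "dam", "aff_pool", "carr_pool"),
    family_id = "fam1",
    role = c("carrier_parent", "affected_parent", "affected_pool",
             "carrier_pool"),
    stringsAsFactors = FALSE),
    orientation = orientation, missing_policy = missing_policy)
}

two_family_design <- function() {
  cross_design(data.frame(
    sample_id = c("f1_sire", "f1_dam", "f1_aff", "f1_carr",
                  "f2_sire", "f2_dam", "f2_aff", "f2_carr"),
    family_id = rep(c("fam1", "fam2"), each = 4),
    role = rep(c("carrier_parent", "affected_parent", "affected_pool",
                 "carrier_pool"), 2),
    stringsAsFactors = FALSE))
}

# Write a small VCF by hand (text lines), bypassing the package's writer.
write_test_vcf <- function(path, records, samples,
                           contigs = c(s1 = 1000000L)) {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             records)
  writeLines(lines, path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts, filter = "PASS") {
  paste(c(chrom, pos, ".", ref, alt, ".", filter, ".", "GT", gts),
        collapse = "\t")
}

# Independent genotype-class oracle: set logic over the allele pair.
oracle_gt_class <- function(a1, a2, alt_index) {
  if (is.na(a1) || is.na(a2)) return("missing")
  if (a1 == 0 && a2 == 0) return("hom_ref")
  if (a1 == alt_index && a2 == alt_index) return("hom_alt")
  "het"
}

# Marker keys of the pipeline's combined co-segregating set.
combined_keys <- function(verdicts) {
  sort(paste0(verdicts$scaffold, ":",
              verdicts$pos)[which(verdicts$combined)])
}

interval_contains <- function(iv, scaffold, pos) {
  !iv$no_signal && iv$scaffold == scaffold &&
    pos > iv$start_bp && pos <= iv$end_bp
}
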