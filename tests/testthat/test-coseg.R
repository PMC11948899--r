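# Genotype classification, VCF loading, repeat masking and the
# co-segregation filter.

test_that("GT strings map to genotype classes, including multi-allelic splits", {
  expect_equal(classify_gt(c("0/0", "0/1", "0/0", "1/0")),
               c("hom_ref", "het", "hom_ref", "het"))
  expect_equal(classify_gt("./."), "missing")
  expect_equal(classify_gt("0|1"), "het")

  # brute force over every diploid pair of alleles {0,1,2,.} against both
  # split alts, compared with an independently coded oracle
  alleles <- c("0", "1", "2", ".")
  for (a in alleles) for (b in alleles) for (k in 1:2) {
    gt <- paste0(a, "/", b)
    exp <- oracle_gt_class(suppressWarnings(as.integer(a)),
                           suppressWarnings(as.integer(b)), k)
    expect_equal(classify_gt(gt, k), exp, label = paste(gt, "alt", k))
  }
  expect_error(classify_gt("0/x"), "malformed")
})

test_that("load_variants splits multi-allelic records and validates samples", {
  d <- one_family_design()
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), c(
    vcf_record("s1", 100, "A", "T", c("0/0", "0/1", "0/0", "1/0")),
    vcf_record("s1", 200, "C", "A,T", c("1/2", "0/1", "0/0", "2/2")),
    vcf_record("s1", 300, "G", "T", c("0/0", "./.", "0/0", "0/1"),
               filter = "q10")),
    samples = c("sire", "dam", "aff_pool", "carr_pool"))

  x <- load_variants(vcf, d)
  expect_equal(n_variants(x), 4L)  # biallelic + two splits + filtered record
  expect_equal(x$table$alt_index[x$table$pos == 200], c(1L, 2L))
  # 1/2 is het for both splits; 2/2 is het for alt 1 and hom_alt for alt 2
  expect_equal(unname(x$classes[x$table$pos == 200, "sire"]), c("het", "het"))
  expect_equal(unname(x$classes[x$table$pos == 200, "carr_pool"]),
               c("het", "hom_alt"))
  expect_equal(unname(x$classes[x$table$pos == 300, "dam"]), "missing")

  expect_equal(n_variants(load_variants(vcf, d, pass_only = TRUE)), 3L)

  d_bad <- cross_design(data.frame(
    sample_id = c("sire", "nobody"), family_id = "fam1",
    role = c("carrier_parent", "affected_pool")))
  expect_error(load_variants(vcf, d_bad), "nobody")
})

test_that("repeat masking follows BED half-open coordinates and is idempotent", {
  d <- one_family_design()
  recs <- sapply(1:10, function(p)
    vcf_record("s1", p, "A", "T", c("0/1", "0/1", "0/1", "0/1")))
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), recs,
                        samples = c("sire", "dam", "aff_pool", "carr_pool"))
  x <- load_variants(vcf, d)

  # BED [0,5) covers 1-based positions 1..5: exactly 5 flagged
  bed <- data.frame(chrom = "s1", start = 0, end = 5)
  x1 <- apply_repeat_mask(x, bed)
  expect_equal(sum(x1$table$in_repeat), 5L)
  expect_equal(x1$table$pos[x1$table$in_repeat], 1:5)

  # [99,100) covers exactly position 100
  v100 <- load_variants(write_test_vcf(tempfile(fileext = ".vcf"),
    vcf_record("s1", 100, "A", "T", c("0/1", "0/1", "0/1", "0/1")),
    samples = c("sire", "dam", "aff_pool", "carr_pool")), d)
  expect_true(apply_repeat_mask(
    v100, data.frame(chrom = "s1", start = 99, end = 100))$table$in_repeat)
  expect_false(apply_repeat_mask(
    v100, data.frame(chrom = "s1", start = 100, end = 101))$table$in_repeat)

  # empty mask leaves everything unflagged
  expect_equal(sum(apply_repeat_mask(x, data.frame(chrom = character(),
    start = numeric(), end = numeric()))$table$in_repeat), 0L)

  # idempotent and order-independent
  bed2 <- data.frame(chrom = "s1", start = c(7, 0), end = c(9, 5))
  bed2r <- bed2[2:1, ]
  expect_identical(apply_repeat_mask(x, bed2)$table,
                   apply_repeat_mask(apply_repeat_mask(x, bed2), bed2)$table)
  expect_identical(apply_repeat_mask(x, bed2)$table,
                   apply_repeat_mask(x, bed2r)$table)

  # a real BED file via the standard importer, plus unknown-scaffold warning
  bedfile <- tempfile(fileext = ".bed")
  writeLines(c("s1\t0\t5", "sX\t0\t10"), bedfile)
  expect_warning(x2 <- apply_repeat_mask(x, bedfile), "sX")
  expect_equal(sum(x2$table$in_repeat), 5L)
})

test_that("the co-segregation filter enforces the expected genotype pattern", {
  d <- one_family_design()
  cls <- function(sire, dam, aff, carr)
    matrix(c(sire, dam, aff, carr), 1, 4,
           dimnames = list(NULL, c("sire", "dam", "aff_pool", "carr_pool")))

  # affected homozygous-reference, carriers heterozygous: co-segregating
  expect_true(classify_cosegregation(
    cls("het", "hom_ref", "hom_ref", "het"), d, "fam1"))
  # one wrong class breaks it
  expect_false(classify_cosegregation(
    cls("het", "hom_ref", "het", "het"), d, "fam1"))
  # missing under fail_variant: not co-segregating
  expect_false(classify_cosegregation(
    cls("het", "hom_ref", "missing", "het"), d, "fam1"))
  # missing under ignore_sample: remaining samples decide
  d_ig <- one_family_design(missing_policy = "ignore_sample")
  expect_true(classify_cosegregation(
    cls("het", "hom_ref", "missing", "het"), d_ig, "fam1"))
  expect_false(classify_cosegregation(
    cls("missing", "missing", "missing", "missing"), d_ig, "fam1"))
  # opposite orientation expects affected samples homozygous-alternate
  d_alt <- one_family_design(orientation = "reference_carries_wildtype")
  expect_true(classify_cosegregation(
    cls("het", "hom_alt", "hom_alt", "het"), d_alt, "fam1"))
  expect_false(classify_cosegregation(
    cls("het", "hom_ref", "hom_ref", "het"), d_alt, "fam1"))
})

test_that("combined verdicts are the conjunction over families", {
  d <- two_family_design()
  samples <- d$samples$sample_id
  good <- c("het", "hom_ref", "hom_ref", "het")
  make_x <- function(f1, f2) {
    cls <- matrix(c(f1, f2), 1, 8, dimnames = list(NULL, samples))
    new_coseg_variants(
      data.frame(scaffold = "s1", pos = 1L, ref = "A", alt = "T",
                 alt_index = 1L, in_repeat = FALSE), cls, samples)
  }
  bad <- c("het", "het", "hom_ref", "het")
  v_tt <- combine_families(make_x(good, good), d)
  v_tf <- combine_families(make_x(good, bad), d)
  expect_true(v_tt$combined)
  expect_false(v_tf$combined)
  expect_true(v_tf$coseg_fam1)
  expect_false(v_tf$coseg_fam2)

  # masked variants get NA verdicts
  x <- make_x(good, good)
  x$table$in_repeat <- TRUE
  expect_true(is.na(combine_families(x, d)$combined))
})

test_that("on simulated variants the combined set is the per-family intersection", {
  sim <- simulate_cross(sim_config(
    scaffold_lengths = c(s1 = 5e6), causal = list(scaffold = "s1", pos = 2e6),
    marker_density = 200, seed = 42))
  v <- combine_families(sim$variants, sim$design)
  expect_identical(which(v$combined),
                   intersect(which(v$coseg_fam1), which(v$coseg_fam2)))
  # monotonicity: the combined set never exceeds any single family's set
  expect_true(all(v$combined <= v$coseg_fam1))
  expect_true(all(v$combined <= v$coseg_fam2))
})
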