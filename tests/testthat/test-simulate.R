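# Cross simulator: reproducibility, Mendelian expectation, and agreement
# between the pipeline and truth recomputed from haplotype paintings.

test_that("identical seed and config give byte-identical outputs", {
  cfg <- sim_config(scaffold_lengths = c(s1 = 4e6),
                    causal = list(scaffold = "s1", pos = 2e6),
                    marker_density = 100, seed = 17)
  v1 <- tempfile(fileext = ".vcf"); v2 <- tempfile(fileext = ".vcf")
  s1 <- simulate_cross(cfg, v1)
  s2 <- simulate_cross(cfg, v2)
  expect_identical(readLines(v1), readLines(v2))
  expect_identical(s1$truth$coseg_markers, s2$truth$coseg_markers)
  expect_identical(s1$variants$classes, s2$variants$classes)
})

test_that("config validation catches impossible causal positions and rates", {
  expect_error(sim_config(causal = list(scaffold = "scaffold_1", pos = 9e9)),
               "beyond")
  expect_error(sim_config(causal = list(scaffold = "nope", pos = 1)))
  expect_error(sim_config(miscall_rate = 0.7))
})

test_that("a carrier x affected cross yields half affected offspring", {
  cfg <- sim_config(seed = 99)
  aff <- simulate_offspring_affected(cfg, 10000)
  bt <- stats::binom.test(sum(aff), length(aff), p = 0.5)
  expect_gt(bt$p.value, 0.01)
})

test_that("affected pool members are homozygous mutant after recombination", {
  sim <- simulate_cross(sim_config(seed = 11))
  for (fam in names(sim$truth$paintings)) {
    p <- sim$truth$paintings[[fam]]
    expect_true(all(p$affected$paternal_causal_hap == 1L))
    expect_true(all(p$carrier$paternal_causal_hap == 2L))
  }
})

test_that("pipeline combined set equals truth recomputed from paintings at zero miscall", {
  for (s in c(3, 14)) {
    cfg <- sim_config(miscall_rate = 0, seed = s)
    vcf <- tempfile(fileext = ".vcf")
    sim <- simulate_cross(cfg, vcf)

    # pipeline path: VCF on disk -> loader -> classifier -> conjunction
    x <- load_variants(vcf, sim$design)
    v <- combine_families(x, sim$design)
    got <- combined_keys(v)

    # oracle path: recompute every emitted class from parental haplotype
    # alleles and offspring paintings, then apply the expected pattern
    mk <- sim$truth$markers
    hap <- sim$truth$parental_haplotypes
    par_class <- function(h) c("hom_ref", "het", "hom_alt")[h$h1 + h$h2 + 1L]
    pool_class <- function(allele_mat) {
      f <- rowSums(allele_mat) / (2 * ncol(allele_mat))
      minor <- pmin(f, 1 - f)
      ifelse(minor < cfg$pool_hom_threshold,
             ifelse(f < 0.5, "hom_ref", "hom_alt"), "het")
    }
    ok <- rep(TRUE, nrow(mk))
    for (fam in names(sim$truth$paintings)) {
      p <- sim$truth$paintings[[fam]]
      ok <- ok &
        par_class(hap$father) == "het" &
        par_class(hap$mothers[[fam]]) == "hom_ref" &
        pool_class(p$affected$maternal_allele +
                     p$affected$paternal_allele) == "hom_ref" &
        pool_class(p$carrier$maternal_allele +
                     p$carrier$paternal_allele) == "het"
    }
    want <- sort(paste0(mk$scaffold, ":", mk$pos)[ok])
    expect_identical(got, want)
    expect_identical(got, sort(sim$truth$coseg_markers))
    # markers fully linked in every sampled offspring are always recovered
    expect_true(all(sim$truth$fully_linked %in% got))
    unlink(vcf)
  }
})

test_that("adding a family never grows the combined co-segregating set", {
  sim <- simulate_cross(sim_config(seed = 8))
  v <- combine_families(sim$variants, sim$design)
  both <- which(v$combined)
  fam1_only <- which(v$coseg_fam1)
  expect_true(all(both %in% fam1_only))
  # dropping to a one-family design reproduces the per-family set
  d1 <- cross_design(
    sim$design$samples[sim$design$samples$family_id == "fam1", ])
  v1 <- combine_families(sim$variants, d1)
  expect_identical(which(v1$combined), fam1_only)
})

test_that("without recombination every diagnostic marker co-segregates", {
  cfg <- sim_config(scaffold_lengths = c(s1 = 4e6, s2 = 4e6),
                    causal = list(scaffold = "s1", pos = 2e6),
                    marker_density = 100, recomb_rate = 0,
                    miscall_rate = 0, seed = 6)
  sim <- simulate_cross(cfg)
  mk <- sim$truth$markers
  diag_keys <- paste0(mk$scaffold, ":", mk$pos)[mk$diagnostic]
  expect_true(all(diag_keys %in% sim$truth$coseg_markers))
  # and the called interval covers most of the causal scaffold
  v <- combine_families(sim$variants, sim$design)
  st <- scan_windows(v, window_size = 1e6, step = 1e5,
                     scaffold_lengths = cfg$scaffold_lengths)
  iv <- call_interval(st, v)
  expect_equal(iv$scaffold, "s1")
  expect_gt((iv$end_bp - iv$start_bp) / 4e6, 0.9)
})
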