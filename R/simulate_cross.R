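# Simulation of two-family recessive crosses with pooled offspring, a known
# causal locus, and multi-sample VCF output with per-marker truth.

#' Configure a recessive-cross simulation
#'
#' The simulated design mirrors a mapping-by-sequencing study of a
#' recessive mono-locus trait: per family, a carrier parent (mutant/+) and
#' an affected parent (mutant/mutant) produce offspring sequenced as an
#' affected pool and a carrier pool; the carrier parent is shared between
#' the two families and sequenced once per family (two libraries).  Marker
#' genotype classes are oriented as if the reference genome carried the
#' mutant haplotype (affected samples homozygous-reference at linked
#' sites).  On the causal scaffold a fraction of markers are
#' *lineage-diagnostic* (reference allele on every mutant-lineage
#' haplotype, alternate on the carrier parent's wild-type haplotype);
#' remaining marker alleles are drawn independently per parental haplotype,
#' so background co-segregation arises only by chance.
#'
#' @param scaffold_lengths named vector of scaffold lengths in bp.
#' @param marker_density markers per Mb.
#' @param causal list `scaffold`, `pos`: the causal locus.
#' @param families named list; each element a list with `n_affected_pool`
#'   and `n_carrier_pool` (pooled offspring counts).
#' @param recomb_rate crossovers per Mb per meiosis.
#' @param miscall_rate per-sample, per-marker genotype miscall probability
#'   (a miscalled class is replaced by one of the other two concrete
#'   classes, uniformly).
#' @param pool_hom_threshold a pool is emitted homozygous when the
#'   minor-allele fraction among its haplotypes is below this threshold,
#'   heterozygous otherwise (a stand-in for a diploid caller genotyping a
#'   pooled library as one sample).
#' @param diagnostic_fraction fraction of causal-scaffold markers that are
#'   lineage-diagnostic.
#' @param seed RNG seed; identical seed and config give byte-identical
#'   outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(scaffold_lengths = c(scaffold_1 = 2e7,
                                            scaffold_2 = 2e7),
                       marker_density = 60,
                       causal = list(scaffold = "scaffold_1", pos = 11.5e6),
                       families = list(
                         fam1 = list(n_affected_pool = 10,
                                     n_carrier_pool = 14),
                         fam2 = list(n_affected_pool = 18,
                                     n_carrier_pool = 18)),
                       recomb_rate = 0.5,
                       miscall_rate = 0.005,
                       pool_hom_threshold = 0.10,
                       diagnostic_fraction = 0.7,
                       seed = 1) {
  stopifnot(length(scaffold_lengths) >= 1, !is.null(names(scaffold_lengths)),
            marker_density > 0,
            causal$scaffold %in% names(scaffold_lengths),
            miscall_rate >= 0, miscall_rate < 0.5,
            pool_hom_threshold > 0, pool_hom_threshold < 0.5,
            diagnostic_fraction >= 0, diagnostic_fraction <= 1,
            length(families) >= 1)
  if (causal$pos < 1 || causal$pos > scaffold_lengths[[causal$scaffold]])
    stop("causal position lies beyond its scaffold")
  for (f in families)
    stopifnot(f$n_affected_pool > 0, f$n_carrier_pool > 0)
  structure(list(scaffold_lengths = scaffold_lengths,
                 marker_density = marker_density, causal = causal,
                 families = families, recomb_rate = recomb_rate,
                 miscall_rate = miscall_rate,
                 pool_hom_threshold = pool_hom_threshold,
                 diagnostic_fraction = diagnostic_fraction,
                 seed = seed),
            class = "sim_config")
}

# One gamete from a parent: per scaffold, Poisson crossovers between the
# parent's two haplotypes, uniform breakpoints, random starting phase.
# Returns the haplotype index (1/2) at each marker and at the causal locus.
draw_gamete <- function(markers, cfg) {
  hap <- integer(nrow(markers))
  causal_hap <- NA_integer_
  for (sc in names(cfg$scaffold_lengths)) {
    len <- cfg$scaffold_lengths[[sc]]
    ncx <- stats::rpois(1, cfg$recomb_rate * len / 1e6)
    cx <- sort(stats::runif(ncx, 0, len))
    phase0 <- sample.int(2L, 1L)
    idx <- which(markers$scaffold == sc)
    seg <- findInterval(markers$pos[idx], cx)
    hap[idx] <- 1L + (phase0 - 1L + seg) %% 2L
    if (sc == cfg$causal$scaffold) {
      seg_c <- findInterval(cfg$causal$pos, cx)
      causal_hap <- 1L + (phase0 - 1L + seg_c) %% 2L
    }
  }
  list(hap = hap, causal_hap = causal_hap)
}

#' Simulate a pooled-offspring recessive cross
#'
#' Generates parental haplotypes carrying biallelic markers at the
#' configured density, produces offspring by Mendelian segregation with
#' Poisson-distributed crossovers, assigns offspring to the affected or
#' carrier pool by their genotype at the causal locus (homozygous mutant
#' after recombination = affected), emits pooled genotype classes under the
#' pool-call model, perturbs all emitted genotypes by the miscall rate, and
#' writes a multi-sample VCF matching the returned [cross_design()].
#' Markers at which no emitted genotype carries the alternate allele are
#' dropped (a variant caller would not report them).
#'
#' @param cfg a [sim_config()].
#' @param vcf_path optional path for the VCF v4.3 output.
#' @return list with
#'   \describe{
#'     \item{vcf}{the VCF path (or `NULL`).}
#'     \item{design}{the matching `cross_design`.}
#'     \item{variants}{the `coseg_variants` object as emitted (identical
#'       to re-loading the VCF).}
#'     \item{truth}{list: `causal`; `markers` (scaffold, pos, diagnostic);
#'       `coseg_markers` (character keys `scaffold:pos` expected to
#'       co-segregate in all families before miscall noise);
#'       `fully_linked` (keys of diagnostic markers with no recombinant
#'       haplotype in any sampled offspring); `paintings` (per family and
#'       pool, the paternal/maternal haplotype-origin and allele matrices
#'       of the pool members).}
#'   }
#' @export
simulate_cross <- function(cfg, vcf_path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  # --- markers ---------------------------------------------------------
  markers <- do.call(rbind, lapply(names(cfg$scaffold_lengths), function(sc) {
    len <- cfg$scaffold_lengths[[sc]]
    n <- max(1L, round(cfg$marker_density * len / 1e6))
    data.frame(scaffold = sc, pos = sort(sample.int(len, n)),
               stringsAsFactors = FALSE)
  }))
  nm <- nrow(markers)
  on_causal <- markers$scaffold == cfg$causal$scaffold
  markers$diagnostic <- on_causal &
    stats::runif(nm) < cfg$diagnostic_fraction
  refalt <- t(vapply(seq_len(nm), function(i) sample(DNA_BASES, 2),
                     character(2)))
  markers$ref <- refalt[, 1]; markers$alt <- refalt[, 2]

  # --- parental haplotype alleles (0 = ref, 1 = alt) -------------------
  # Shared carrier father: hap 1 carries the mutant allele, hap 2 wild type.
  rand_hap <- function() stats::rbinom(nm, 1L, 0.5)
  father <- list(h1 = rand_hap(), h2 = rand_hap())
  father$h1[markers$diagnostic] <- 0L
  father$h2[markers$diagnostic] <- 1L
  mothers <- lapply(cfg$families, function(f) {
    m <- list(h1 = rand_hap(), h2 = rand_hap())
    m$h1[markers$diagnostic] <- 0L
    m$h2[markers$diagnostic] <- 0L
    m
  })

  # --- offspring -------------------------------------------------------
  fam_ids <- names(cfg$families)
  pools <- list()
  for (fam in fam_ids) {
    fcfg <- cfg$families[[fam]]
    aff <- list(); carr <- list()
    while (length(aff) < fcfg$n_affected_pool ||
           length(carr) < fcfg$n_carrier_pool) {
      gm <- draw_gamete(markers, cfg)  # maternal (affected parent)
      gp <- draw_gamete(markers, cfg)  # paternal (carrier parent)
      affected <- gp$causal_hap == 1L  # mother transmits mutant either way
      child <- list(
        maternal_allele = ifelse(gm$hap == 1L, mothers[[fam]]$h1,
                                 mothers[[fam]]$h2),
        paternal_allele = ifelse(gp$hap == 1L, father$h1, father$h2),
        maternal_hap = gm$hap, paternal_hap = gp$hap,
        paternal_causal_hap = gp$causal_hap)
      if (affected && length(aff) < fcfg$n_affected_pool)
        aff[[length(aff) + 1L]] <- child
      else if (!affected && length(carr) < fcfg$n_carrier_pool)
        carr[[length(carr) + 1L]] <- child
    }
    pools[[fam]] <- list(affected = aff, carrier = carr)
  }

  # --- emitted genotype classes (pre-miscall) --------------------------
  parent_class <- function(h) c("hom_ref", "het", "hom_alt")[h$h1 + h$h2 + 1L]
  pool_class <- function(members) {
    alle <- vapply(members, function(m) m$maternal_allele + m$paternal_allele,
                   integer(nm))  # nm x n matrix of per-member allele counts
    f <- rowSums(alle) / (2L * length(members))
    minor <- pmin(f, 1 - f)
    ifelse(minor < cfg$pool_hom_threshold,
           ifelse(f < 0.5, "hom_ref", "hom_alt"), "het")
  }
  sample_ids <- c(); classes <- NULL; design_rows <- list()
  for (fam in fam_ids) {
    ids <- paste0(fam, c("_father", "_mother", "_affected_pool",
                         "_carrier_pool"))
    cls <- cbind(parent_class(father),
                 parent_class(mothers[[fam]]),
                 pool_class(pools[[fam]]$affected),
                 pool_class(pools[[fam]]$carrier))
    colnames(cls) <- ids
    classes <- cbind(classes, cls)
    design_rows[[fam]] <- data.frame(
      sample_id = ids, family_id = fam,
      role = c("carrier_parent", "affected_parent", "affected_pool",
               "carrier_pool"),
      stringsAsFactors = FALSE)
  }
  design <- cross_design(do.call(rbind, design_rows))

  # --- truth (pre-miscall) ---------------------------------------------
  key <- paste0(markers$scaffold, ":", markers$pos)
  expc <- expected_class(design$samples$role, design$orientation)
  truth_ok <- rowSums(classes != matrix(expc, nm, ncol(classes),
                                        byrow = TRUE)) == 0L
  fully_linked <- markers$diagnostic
  for (fam in fam_ids) {
    for (pool in pools[[fam]]) {
      for (m in pool) {
        fully_linked <- fully_linked &
          m$paternal_hap == m$paternal_causal_hap
      }
    }
  }

  # --- miscall noise ----------------------------------------------------
  if (cfg$miscall_rate > 0) {
    flip <- which(matrix(stats::runif(length(classes)) < cfg$miscall_rate,
                         nrow(classes)))
    if (length(flip)) {
      concrete <- c("hom_ref", "het", "hom_alt")
      classes[flip] <- vapply(classes[flip], function(old)
        sample(setdiff(concrete, old), 1L), character(1))
    }
  }

  # --- drop markers invisible to a variant caller ----------------------
  seen_alt <- rowSums(classes == "het" | classes == "hom_alt") > 0L
  markers_out <- markers[seen_alt, , drop = FALSE]
  classes_out <- classes[seen_alt, , drop = FALSE]

  tbl <- data.frame(scaffold = markers_out$scaffold, pos = markers_out$pos,
                    ref = markers_out$ref, alt = markers_out$alt,
                    alt_index = 1L, in_repeat = FALSE,
                    stringsAsFactors = FALSE)
  variants <- new_coseg_variants(tbl, classes_out, colnames(classes_out))
  if (!is.null(vcf_path))
    write_sim_vcf(vcf_path, tbl, classes_out, cfg$scaffold_lengths)

  paintings <- lapply(pools, function(p) lapply(p, function(members) {
    list(maternal_allele = vapply(members, `[[`, integer(nm),
                                  "maternal_allele"),
         paternal_allele = vapply(members, `[[`, integer(nm),
                                  "paternal_allele"),
         paternal_hap = vapply(members, `[[`, integer(nm), "paternal_hap"),
         paternal_causal_hap = vapply(members, `[[`, integer(1),
                                      "paternal_causal_hap"))
  }))
  list(vcf = vcf_path, design = design, variants = variants,
       truth = list(causal = cfg$causal,
                    markers = markers,
                    coseg_markers = key[truth_ok],
                    fully_linked = key[fully_linked],
                    parental_haplotypes = list(father = father,
                                               mothers = mothers),
                    paintings = paintings),
       cfg = cfg)
}

#' Affected fraction among simulated offspring
#'
#' Draws `n` offspring of one simulated family (carrier x affected cross)
#' with the full gamete machinery and reports which are affected
#' (homozygous for the causal allele after recombination).  Used to check
#' the simulator's Mendelian expectation of one half.
#'
#' @param cfg a [sim_config()].
#' @param n number of offspring.
#' @return logical vector of length `n` (`TRUE` = affected).
#' @export
simulate_offspring_affected <- function(cfg, n) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  markers <- data.frame(scaffold = cfg$causal$scaffold, pos = cfg$causal$pos)
  vapply(seq_len(n), function(i) draw_gamete(markers, cfg)$causal_hap == 1L,
         logical(1))
}

# Minimal, well-formed VCF v4.3 writer for simulated genotype classes.
write_sim_vcf <- function(path, tbl, classes, scaffold_lengths) {
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
              missing = "./.")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.3",
               "##source=cosegscan_simulate_cross",
               sprintf("##contig=<ID=%s,length=%d>",
                       names(scaffold_lengths),
                       as.integer(scaffold_lengths)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(classes)),
                     collapse = "\t")), con)
  if (nrow(tbl)) {
    gts <- matrix(gt_map[classes], nrow(classes))
    body <- paste(tbl$scaffold, tbl$pos, ".", tbl$ref, tbl$alt, ".",
                  "PASS", ".", "GT",
                  apply(gts, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
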