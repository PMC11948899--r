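---
title: "Co-segregation mapping and insertion evidence: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-segregation mapping and insertion evidence: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosegscan)
```

# The mapping model

`cosegscan` localises a recessive mono-locus trait by mapping-by-sequencing:
whole-genome variant calls from the parents and phenotype-sorted offspring
pools of one or more families are screened for variants whose genotype
pattern matches the trait's inheritance, and the genomic region where such
variants concentrate is called as the candidate interval.

For a recessive allele *m*, a family consists of a carrier parent
(*m*/+), an affected parent (*m*/*m*), a pooled library of affected
offspring (*m*/*m*) and a pooled library of carrier offspring (*m*/+),
each genotyped as a single diploid sample.  At a variant fully linked to
the locus, the affected samples are homozygous and the carrier samples
heterozygous.  One subtlety of orientation: when the reference genome
itself derives from an individual carrying the mutant haplotype, affected
samples appear homozygous *reference* (0/0) rather than homozygous
alternate.  `cross_design()` makes this explicit
(`reference_carries_mutant`, the default, vs
`reference_carries_wildtype`); the filter itself is otherwise symmetric.

A variant *co-segregates* within a family when every affected-role sample
shows the orientation-expected homozygous class and every carrier-role
sample is heterozygous.  The combined verdict is the conjunction over
families, equivalent to the pattern holding across the union of all
libraries.  Mapping with two (or more) families is what suppresses the
by-chance co-segregating background regions a single family always shows.
Variants in repeat-masked regions (a RepeatMasker-style BED, 0-based
half-open) are excluded before classification.

## Handling choices in the filter

* **Multi-allelic records** are split per alternate allele; a genotype
  carrying any non-reference allele other than the split alt (e.g. `1/2`
  while splitting alt 1) is classed heterozygous for that split.  This
  preserves the hom-vs-het dichotomy without discarding multi-allelic
  sites.
* **Missing genotypes**: the default `missing_policy = "fail_variant"`
  treats a variant with any missing required genotype as
  non-co-segregating.  Low-coverage libraries produce more `./.` calls
  and more noise; strictness is the conservative default, and
  `"ignore_sample"` is available for thin data.
* **Phased genotypes** (`0|1`) are reduced to unphased classes.
* **FILTER** is not applied by default (`pass_only = FALSE`): the
  co-segregation pattern is itself a strong filter, and upstream callers
  differ in their FILTER dialects.  A switch enables PASS-only.
* A parent shared between families and sequenced as two libraries is
  treated as two samples, one per family; each library must independently
  show the expected class.  This is deliberately stricter than merging
  the libraries, and doubles as an internal consistency check on the
  shared parent.

# Window scan and interval call

`scan_windows()` tiles each scaffold with 1 Mb windows advancing by
100 kb (both configurable), anchored at coordinate 0, keeping flagged
terminal partial windows, and reports per window the proportion of
co-segregating variants.  Two denominators are implemented because the
natural definitions differ:

* `all_variants` (default): combined co-segregating / all non-masked
  variants in the window.
* `parental_coseg`: the denominator is restricted to variants whose
  pattern already holds in the parental libraries alone, so the
  proportion measures how often the offspring pools confirm a parentally
  consistent variant.

Both are exported and labelled; neither is asserted as the only correct
reading, and on simulated crosses both localise the same peak.

`call_interval()` selects windows reaching at least `threshold_fraction`
(default 0.9) of the global maximum proportion, merges
overlapping/adjacent selections, and returns the merged run containing
the arg-max window.  The 0.9 default is a documented choice: peak calling
here has no significance model (none is warranted by the design), and on
simulations 0.9 recovers a contiguous peak robustly while lower values
absorb neighbouring noise windows.  The call reports the co-segregating
variant count inside the interval and its density per Mb, rounded half
away from zero (345 variants over 5.7 Mb report as 61/Mb).  Runs of
assembly gaps (N stretches) are *not* subtracted from the interval length
by default — assemblies can disagree by hundreds of kb of Ns over the
same region — but `gap_runs` makes gap-aware length explicit when gap
coordinates are known.  With no defined window, or no co-segregating
variant anywhere, the call is an explicit no-signal object, not an error.

# Recombinant-based refinement

Individually genotyped offspring narrow the interval: an affected
individual heterozygous at a site inside the interval carries a
recombination breakpoint, and the causal locus must lie in that
individual's maximal run of phenotype-consistent sites, bounded
exclusively by the nearest inconsistent sites.
`refine_with_recombinants()` intersects the interval with every
individual's consistent segment.  When inconsistent sites split an
individual's sites into several candidate runs, the run with the largest
overlap with the current interval is used (ties: leftmost); individuals
consistent everywhere do not constrain.  The operation is
order-independent and can only shrink the interval; an empty intersection
raises an error naming the conflicting individuals, which operationally
signals a phenotyping or genotyping error, or a wrong interval.

# Insertion-spanning reads

Transcript evidence for a retroelement insertion comes from reads whose
alignment to the insertion-bearing transcript crosses an insert boundary.
`detect_junction_reads()` implements a start-window/soft-clip rule: for a
junction boundary *J* (the last base before the insert, or the last base
of the insert), a read is retained iff its alignment start lies in
[*J* − 80, *J* − 10] and every clipped region is strictly shorter than
5 bases.  For ~100 bp reads the window guarantees at least 10 aligned
bases on each side of the boundary.  Choices made explicit:

* the window is applied per junction (upstream and downstream
  independently), not as a joint requirement per read;
* hard clips count as clips — a hard-clipped chimeric alignment is no
  better evidence than a soft-clipped one;
* "< 5 bp" is a strict inequality;
* an internal clip op is a malformed record and raises an error.

The simulator labels each read with an independent per-base truth
(aligned span covers a junction with ≥ 10 bases each side), so the
detector-vs-truth differences — clipped reads, and spanning reads whose
start misses the window — are visible in tests rather than hidden inside
the rule.

# Coding consequence

`annotate_consequence()` splices the realised insert into the CDS after a
stated (not necessarily codon-aligned) position, translates in the
wild-type frame with the standard nuclear codon table (no selenocysteine
handling), and stops at the first in-frame stop.  It reports the protein
length, whether the protein is truncated relative to wild type, and the
number of novel residues after the last junction-complete codon that
differ from the wild-type residue at the same position.  A stop-free
mutant CDS is flagged `stop_loss` rather than silently reported as
non-truncated-by-stop.  Which genomic fragments of an element splice into
the realised insert is out of scope; the insert sequence is an input.

# Element copy scan

`scan_element_copies()` counts near-identical copies of an element in a
genome under two thresholds: aligned length ≥ 5000 bp and identity ≥ 95%
(both configurable).  The search is seed-and-extend: exact 31-mers
sampled every 16 bases along the query are anchored exactly
(`matchPDict`), anchors within a 64 bp diagonal band and without > 2 kb
genomic gaps are chained, chains covering less than a quarter of the
required match length are discarded (this removes chains produced by the
element's own terminal repeats cross-matching between neighbouring
copies, which would otherwise bridge distinct loci into one candidate),
and every surviving candidate region is verified by a gapped local
alignment (match +2, mismatch −3, gap open 5, gap extend 2).  Identity is
matches over alignment columns, so gaps count against identity.  Both
strands are searched; overlapping accepted hits collapse to one copy.
The copy criterion is the length/identity threshold pair — no particular
aligner's scoring is reproduced, and the scan is validated against
planted-copy truth, not against another tool's output.

Sensitivity arithmetic for the defaults: at 5% divergence an exact 31-mer
survives with probability 0.95^31 ≈ 0.20, so ~70 of the ~360 sampled
seeds anchor a full-length copy — far beyond the two-anchor requirement —
while a random 31-mer match in a 200 kb background is vanishingly rare,
giving a negligible false-positive rate (tested over 20 element-free
genomes).  Local alignment may shave a few diverged terminal bases off a
reported locus; boundaries are therefore accurate to a handful of bases,
not exact.

# The simulator

`simulate_cross()` generates the full statistical structure the mapping
assumes, so every stage can be scored against known truth:

* Two families, affected dam × shared carrier sire, the sire emitted as
  one library per family.  Pool sizes default to 10/14 and 18/18
  offspring — the study conditions for this design.
* Biallelic markers at 60/Mb over two 20 Mb scaffolds; causal locus at
  scaffold_1:11.5 Mb.
* On the causal scaffold, 70% of markers are *lineage-diagnostic*: the
  reference allele rides every mutant-lineage haplotype and the alternate
  allele the sire's wild-type haplotype, mimicking variants fixed between
  the morph and wild-type backgrounds (the signal the filter consumes).
  All other marker alleles are drawn independently per parental
  haplotype, so background co-segregation arises only by chance and is
  family-specific.  The 0.7 default leaves a realistic minority of
  uninformative sites inside the linked region.
* Meiosis: crossovers are Poisson with 0.5 per Mb per meiosis, uniform
  positions, no interference.  The rate is deliberately high for a
  vertebrate genome; it compresses linkage decay into a desk-scale 20 Mb
  scaffold so that interval recovery is a sharp, testable target.
  Affected offspring are those homozygous for the causal allele *after*
  recombination — recombinant offspring are real and are what the
  refinement stage consumes.
* Pool genotypes: a pool is emitted homozygous when the minor-allele
  fraction among its haplotypes is below 0.10, heterozygous otherwise.
  This is a stand-in for a diploid caller genotyping a pooled library as
  one sample; how a specific caller behaves on pools is not modelled.
  Genotype miscalls (default 0.5%) then replace emitted classes with a
  uniformly chosen other concrete class.
* Markers at which no emitted genotype shows the alternate allele are
  dropped, as a variant caller would not report them.

What the simulator does *not* emulate: read-level errors and coverage
(miscalls summarise them), reference bias, indel or structural variation
among markers, crossover interference, and linkage disequilibrium
structure in the founders.  Passing recovery tests therefore shows the
pipeline's logic is correct under the assumed genotype model, not that
any particular sequencing depth suffices in real data.

The companion generators follow the same pattern:
`simulate_junction_reads()` (uniform starts, parameterised clip model,
per-base truth labels) and `plant_element_copies()` (substitution-only
divergence by default, so planted identity is exact; optional prefix
truncation; random strand).  All generators are reproducible: identical
seed and configuration give byte-identical outputs.

# Synthetic reference fixtures

The worked examples run on synthetic stand-ins, built deterministically
in code (`reference_fixtures()`) and shipped as FASTA under
`inst/extdata/` with `synthetic_` filenames.  They satisfy every
published constraint the examples exercise: a 2643 bp CDS translating to
880 aa; a 397 bp insert placed after CDS position 605 whose transcript
encodes 4 novel residues and a premature stop, truncating the protein to
205 aa; a 5832 bp element with identical 300 bp terminal repeats, from
which the insert's three fragments are excised; and a second element copy
differing by exactly one substitution.  None of the sequences is
biological, and a test asserts the shipped files match the in-code
builder.

# Problem sizes and numerical conventions

The validation suite uses desk-scale problem sizes chosen to exercise
each property well away from its failure modes: exhaustive enumeration of
all 4^4 genotype-class assignments for the filter; 10,000 simulated reads
against a brute-force re-derivation of the junction rule; 100 simulated
crosses (seeds 1–100) for interval recovery with a ≥ 95/100 target; 20
zero-miscall crosses for exact truth-set equality; and 20 element-free
200 kb genomes for the copy-scan false-positive bound.  Density rounding
is half away from zero; window tiling is 0-based half-open anchored at 0;
VCF positions are 1-based; BED masks 0-based half-open.  Ties in interval
calling (several windows at the maximum) resolve to the run containing
the first arg-max window.

# Known limitations

* The pool-call model is a deliberate simplification; pools genotyped by
  a caller with explicit ploidy handling would need a different emission
  model.
* Interval resolution is floored by the window size; in the
  marker-limited regime (sparse markers, windows ≪ interval) resolution
  improves with marker density, which is the regime the density-doubling
  trend test exercises.
* `scan_element_copies()` collapses overlapping hits, so two copies
  planted (or evolved) nearly back-to-back on the same locus count once.
* Junction detection trusts the alignment's CIGAR; it does not
  re-examine read sequences.
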