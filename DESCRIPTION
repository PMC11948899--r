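Package: cosegscan
Title: Co-Segregation Mapping and Retrotransposon Insertion Evidence for
    Mendelian Crosses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mapping-by-sequencing of recessive Mendelian traits from
    multi-sample variant calls of parents and pooled offspring: a genotype
    co-segregation filter with repeat masking, sliding-window co-segregation
    proportion scans, candidate-interval calling with variant density, and
    interval refinement from Sanger-genotyped recombinant individuals.
    Companion tools detect reads spanning a retrotransposon insertion
    junction from CIGAR strings and alignment starts, annotate the coding
    consequence of a transcript insertion (premature stop, truncated
    protein), and count near-identical retroelement copies in a genome by a
    seed-and-extend search under length and identity thresholds.  A
    simulator generates two-family recessive crosses with pooled offspring
    and a known causal locus (VCF), reads tiling an insertion junction
    (SAM), and genomes with planted element copies (FASTA), against which
    every stage is validated.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
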