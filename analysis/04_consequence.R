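#!/usr/bin/env Rscript
# Coding consequence of the transcript insertion on the synthetic
# transcripts: splice the 397 bp insert after CDS position 605, translate,
# and report the premature stop.

suppressMessages(library(cosegscan))
dir.create("results", showWarnings = FALSE)

fx <- reference_fixtures()
ti <- transcript_insertion(fx$wt_cds, fx$stripe_insert, fx$insert_after)
report <- annotate_consequence(ti)
print(report)
cat(sprintf("Wild type: %d bp CDS -> %d aa protein\n",
            nchar(fx$wt_cds), report$wt_protein_length))
cat(sprintf("Insertion-bearing transcript: %d bp -> %d aa (%d novel residues, then stop)\n",
            nchar(report$mutant_cds), report$protein_length,
            report$novel_aa_after_junction))
write_consequence_json(report, "results/consequence.json")
cat("Wrote results/consequence.json\n")
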