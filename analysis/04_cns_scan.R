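#!/usr/bin/env Rscript
# Conserved non-coding sequence detection on the simulated four-taxon
# alignment: neutral-rate estimation, maximal-scoring segments,
# Karlin-Altschul P-values, and the conservation-score threshold
# (-log10 0.05).  The planted constrained block should come out as a CNS.

library(sweepfoot)

set.seed(20240904L)
rows <- read_fasta("results/inputs/alignment.fa")
block <- alignment_block(rows)

pn <- estimate_neutral_rate(block)
message(sprintf("-- estimated neutral mismatch rate: %.3f", pn))

calls <- call_cns(block, alpha = 0.05, n_null = 10000)
message(sprintf("-- %d maximal segments, %d called CNS", nrow(calls),
                sum(calls$is_cns)))
print(calls[calls$is_cns, ])

dir.create("results/cns", showWarnings = FALSE, recursive = TRUE)
write_bed(calls, "results/cns/segments.bed", chrom = "alignment",
          name_prefix = "seg", header = sprintf("p_neutral=%.3f", pn))
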