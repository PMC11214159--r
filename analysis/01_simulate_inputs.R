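#!/usr/bin/env Rscript
# Generates the synthetic inputs every later stage consumes: a neutral and
# a swept haplotype locus (FASTA), a BC1 cross with a planted QTL (CSV
# triplet), a four-taxon non-coding alignment with an embedded constrained
# block, and a two-group morphometric table.  Everything is seeded, so the
# whole analysis is reproducible end to end.

library(sweepfoot)

seed <- 20240901L
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)

message("-- haplotype loci (n = 22, 6 kb, theta 7.6e-3, rho 0.25 per site)")
neutral <- gen_neutral_locus(n = 22, length_bp = 6000, seed = seed)
sweep <- gen_sweep_locus(n = 22, length_bp = 6000, sweep_pos = 3000,
                         f = 0.9, seed = seed + 1)
write_haplotype_fasta(neutral, "results/inputs/locus_neutral.fa")
write_haplotype_fasta(sweep, "results/inputs/locus_sweep.fa")

message("-- BC1 cross: 132 individuals, 14 LGs, 1,540 markers, QTL on LG6")
cross <- gen_bc1(n_ind = 132, effect = 1, qtl_lg = 6, seed = seed + 2)
write_cross_csv(cross, "results/inputs", prefix = "bc1",
                header = sprintf("seed=%d qtl_lg=6 effect=1", seed + 2))

message("-- four-taxon alignment, 300 columns, constrained block [100,200)")
aln <- gen_alignment(n_rows = 4, length = 300, p_neutral = 0.3,
                     blocks = data.frame(start = 100, end = 200,
                                         p_constrained = 0.02),
                     seed = seed + 3)
write_fasta(aln$rows, "results/inputs/alignment.fa",
            info = list(seed = seed + 3))

message("-- morphometric table: control n = 20 vs knockdown n = 32")
morpho <- gen_morpho(group_shape_offsets = rbind(0, c(0.06, -0.02, 0.05,
                                                      -0.09)),
                     seed = seed + 4)
write.csv(morpho, "results/inputs/morpho.csv", row.names = FALSE)

message("inputs written under results/inputs/")
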