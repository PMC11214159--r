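#!/usr/bin/env Rscript
# Transcription-factor binding-site prediction in the candidate regulatory
# window flagged by the sweep scan: PWM scanning at relative score >= 0.95
# (5-12 bp motifs), then intersection with the SNPs segregating in the
# sample -- binding sites carrying SNPs are candidate causal differences.

library(sweepfoot)

loc <- read_haplotype_fasta("results/inputs/locus_sweep.fa")
track <- sliding_scan(loc, window_bp = 2000, step_bp = 1000)
peak <- find_peaks(track)$E
message(sprintf("-- candidate window [%d, %d)", peak$start, peak$end))

region <- substr(loc$ancestral, peak$start + 1, peak$end)
snps <- sweepfoot:::polarize_sites(loc)
snps_in <- snps$pos[snps$pos >= peak$start & snps$pos < peak$end] -
  peak$start

# small demonstration motif set in JASPAR flat format
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)
writeLines(c(
  ">MX0001.1 zf-A",
  "A [ 12  1  1 12  1 12 ]",
  "C [  1  1 12  1  1  1 ]",
  "G [  1 12  1  1  1  1 ]",
  "T [  1  1  1  1 12  1 ]",
  ">MX0002.1 hb-like",
  "A [  1  1 14  1  1  1  1 ]",
  "C [  1  1  1 14  1 14  1 ]",
  "G [ 14  1  1  1  1  1 14 ]",
  "T [  1 14  1  1 14  1  1 ]",
  ">MX0003.1 short3",
  "A [ 9 1 1 ]",
  "C [ 1 9 1 ]",
  "G [ 1 1 9 ]",
  "T [ 1 1 1 ]"), "results/inputs/motifs.jaspar")

pfms <- read_jaspar_pfm("results/inputs/motifs.jaspar")
sites <- scan_motifs(region, pfms, threshold = 0.95, width_filter = TRUE)
sites <- snp_overlap(sites, snps_in)

message(sprintf("-- %d sites at relative score >= 0.95; %d overlap a SNP",
                nrow(sites), attr(sites, "n_sites_with_snp")))
dir.create("results/tfbs", showWarnings = FALSE, recursive = TRUE)
write.table(sites, "results/tfbs/sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
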