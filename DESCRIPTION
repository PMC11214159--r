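Package: sweepfoot
Title: Selective-Sweep Footprints, Conserved Non-Coding Elements and
    Backcross QTL Mapping Around a Candidate Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Inference chain for localising a cis-regulatory candidate at a
    few-kb locus: polarized site-frequency-spectrum sweep statistics
    (Tajima's D, standardized Fay-Wu H, Zeng's E) in sliding windows, judged
    against a neutral infinite-sites coalescent null with recombination;
    conserved non-coding sequence detection by maximal-scoring segments with
    Karlin-Altschul P-values; covariate QTL scanning for a BC1 backcross by
    Haley-Knott regression with permutation thresholds, Bayesian credible
    intervals and variance explained; Burnaby size-corrected morphometrics;
    and position-weight-matrix binding-site scanning with SNP intersection.
    Includes seeded synthetic-data generators emulating each stage's inputs
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer
LinkingTo: Rcpp
Config/testthat/edition: 3
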