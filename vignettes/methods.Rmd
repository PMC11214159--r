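---
title: "Methods: sweep footprints, conserved elements and backcross QTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep footprints, conserved elements and backcross QTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

sweepfoot implements the chain of analyses used to localise a candidate
cis-regulatory element at a few-kb locus in a non-model beetle system:
sliding-window site-frequency-spectrum statistics judged against a neutral
coalescent null, conserved non-coding sequence (CNS) detection, covariate
QTL scanning in a BC1 backcross, Burnaby size-corrected morphometrics, and
PWM binding-site scanning with SNP intersection.  This vignette records the
models, the parameters that matter, and the design decisions, in the order
the pipeline runs.

## Polarized SFS statistics

Haplotypes are aligned with one ancestral (outgroup) sequence.  At each
site the derived allele is the sample allele differing from the ancestral
base.  Sites are used only if they are cleanly interpretable under the
infinite-sites model: any gap or N anywhere in the column, more than two
sample alleles, a polymorphic column whose ancestral base is absent among
the samples (unpolarizable), monomorphic columns and fixed-derived columns
are all excluded.  The derived SFS `S_i` (i = 1..n-1) feeds four standard
estimators of the population mutation rate:

* `theta_pi = sum 2 i (n-i) S_i / (n(n-1))` (pairwise diversity),
* `theta_W = S / a_n` with `a_n = sum_{i<n} 1/i` (Watterson),
* `theta_L = sum i S_i / (n-1)` (mean derived count),
* `theta_H = sum 2 i^2 S_i / (n(n-1))` (high-frequency weighted),

with the exact identity `theta_pi + theta_H = 2 theta_L`.  The three sweep
statistics are standardized contrasts: Tajima's D (`theta_pi - theta_W`),
the standardized Fay-Wu H (`theta_pi - theta_L`) and Zeng's E
(`theta_L - theta_W`), using the published variance approximations with
`theta = S/a_n` and `theta^2 = S(S-1)/(a_n^2 + b_n)` plugged in.  Two
numerical points:

* when `S = 0` the statistics are reported as `NA`, never 0;
* at `n = 2` (and for D also at `n = 3`, where `theta_pi` and `theta_W`
  coincide identically) the estimated variances collapse to zero together
  with the contrasts; the symmetric 0/0 case is reported as exactly 0.

The statistics are computed in sliding windows (default 2,000 bp, step
100 bp; the scan drivers in `analysis/` use step 1,000 bp for the 6-kb
demonstration loci).  Peaks are the window with maximal E and the windows
with minimal H and D, ties broken towards the smaller start coordinate.

A property worth knowing: under tight linkage (rho = 0) the three
standardized statistics have small but genuinely non-zero means (for
n = 20 and locus theta = 10, roughly -0.09 for D, +0.10 for H, -0.17 for
E; the variance standardizations are approximate).  Under the recombining
null in which they are actually used here (rho = 0.25 per site) the means
are indistinguishable from zero.  The test suite pins zero-centring at the
recombining configuration and checks the rho = 0 case at distribution
level against an independent coalescent oracle.

## The neutral coalescent null

`null_model()` / `null_distribution()` simulate the neutral infinite-sites
coalescent with crossover recombination, with constant large population
size.  Defaults follow the study conditions: n = 22 haplotypes, per-site
theta = 7.6e-3, per-site rho = 2.5e-1, window L = 2,000 bp, 10,000
replicates.  rho derives from the genetic map: recombination rate =
map length / genome size = 18 M / 1.9e8 bp = 9.5e-8 per bp, and
rho = theta x rate / mu with mu = 2.9e-9.  theta and rho are per-site
quantities multiplied by L (a `per_site = FALSE` switch accepts locus-wide
values, since simulator conventions differ on this point).

The simulator (`src/coalescent.cpp`) is an exact ancestral-recombination-
graph construction in the style of Hudson's ms: no sequential-Markov
approximation (the locus is small), segment lists with descendant-set
bitmasks, spans that reach their MRCA dropped, mutations Poisson on
ancestral branch length with uniform positions.  Every recorded mutation is
segregating and polarized by construction.  Replicates with `S = 0` are
dropped from the null rather than imputed.  Time is in coalescent units of
2N generations with theta = 4N mu conventions; only ratios matter for the
statistics.  The simulator was validated against analytic expectations
(`E[S] = theta a_n`) and, at the full study configuration, against an
independent simulator at distribution level (S, D, H and E).

Empirical probabilities are `P(Sim <= Obs)`, the proportion of defined
simulated values at or below the observed value (ties count; the raw
proportion is the default because a reported probability of 0.0000 is only
possible without a pseudocount; a `(k+1)/(reps+1)` mode exists).  A peak is
significant when `P >= 0.95` for E (upper tail) and `P < 0.05` for H and D
(lower tails, strict).

### Scan-level null and the sweep flag

Comparing the most extreme window of a scanned locus against a
single-window null is anti-conservative: the maximum of several windows
beats a per-window quantile far more than 5% of the time.
`run_sweep_pipeline()` therefore builds its null at scan level: whole
neutral loci of the scanned length are simulated, scanned with the same
window and step, and the per-replicate peak E / minimum H / minimum D form
the null distributions.  By construction the per-statistic false-positive
rate is the nominal alpha.  The single-window null remains available
(`null_distribution()`) and is what the calibration checks at the study
configuration use.

The pipeline calls a locus swept when at least two of the three statistics
are significant.  A majority vote is used because the statistics peak at
different sweep ages: H is most powerful immediately after fixation, E
later during the recovery phase, D with the accumulating excess of rare
variants.  Conjunctions of specific pairs encode an assumption about sweep
age; the majority vote does not, and in simulations at the generator's
conditions (below) it detects 80-85% of planted sweeps at f = 0.9 while
flagging 0-3% of neutral loci.  The per-statistic booleans are always
reported so the per-statistic reading can be applied instead.

## Synthetic data

The generators define the conditions under which the pipeline is tested.

* `gen_neutral_locus()`: one coalescent replicate converted to sequences; a
  random ancestral sequence, each mutation at a distinct bp with a random
  derived base.  Defaults: n = 22, theta = 7.6e-3/site, rho = 0.25/site.
* `gen_sweep_locus()`: the sweep footprint is an explicit genealogical
  distortion, not a forward selection simulation: a fraction f of lineages
  (default 0.9) coalesces instantly into a star-like core, applied per site
  with probability `exp(-distance/decay_bp)` (decay 1,000 bp) around the
  swept position.  This produces the tested signature -- excess
  high-frequency derived alleles decaying with distance -- with a tunable,
  documented strength.  `f = 0` reproduces the neutral generator exactly.
* `gen_bc1()`: BC1 genotypes as a two-state Markov chain along 14 linkage
  groups (Kosambi-consistent recombination fractions), 1,540 markers over
  1,790 cM by default, mirroring the study's map density (0.9 markers/cM);
  trait = effect x I(heterozygous at QTL) + gamma x covariate + N(0,1),
  covariate genetically independent of the QTL, correlation 0.5 by default.
* `gen_alignment()`: rows mutated from a common reference; each column is
  hit with probability p (one random row substituted), p = 0.3 outside and
  0.02 inside planted constrained blocks in the calibration scenario.
* `gen_morpho()`: log-scale measurements with a common isometric size
  factor per specimen, group shape offsets, and residual noise.

Everything is seeded and bit-reproducible; seeds and parameters are written
into output file headers.  What the generators do **not** emulate: real
demography (bottlenecks, structure, growth), genotyping error and missing
data patterns, alignment error, phylogenetic rate variation among branches,
and measurement error correlated with size.  Passing tests demonstrate
calibration and recovery under the stated models, not robustness to those
real-data features.

## CNS detection

The full phylogenetically-weighted footprinting algorithm is simplified to
a column-identity two-rate model that preserves its statistical skeleton:
estimate a neutral rate, score constrained evolution per column by log
odds, extract maximal segments, convert scores to P-values by
Karlin-Altschul statistics, threshold the conservation score.

* Neutral rate: fraction of unmasked columns not identical across rows,
  clipped to [0.01, 0.99]; needs >= 100 unmasked columns.  Columns are
  scored identical/non-identical across all rows (no pairwise averaging)
  for determinism.
* Scores: `log((1-p_c)/(1-p_n))` per identical column, `log(p_c/p_n)` per
  mismatch.  The constrained rate is not observable from one alignment;
  default `p_c = p_n / 5`, configurable.  Masked (annotated coding)
  columns score 0, so calls are invariant to adding masked columns.
* Segments: all maximal-scoring positive subsequences (Ruzzo-Tompa).
* `lambda` is the unique positive root of
  `(1-p_n) e^(lambda s_match) + p_n e^(lambda s_mis) = 1` (bisection,
  |f| < 1e-12; requires negative expected neutral score).  `K` is fitted
  from simulated null blocks (default 10,000) by matching the empirical
  upper tail (80th-98th percentiles) of the maximal-segment-score
  distribution to `P(M <= x) = exp(-K m e^(-lambda x))`; the upper tail is
  used because that is where alpha-level calls live, and because the
  two-valued (lattice) scores make the asymptotic formula approximate.
* Segment P-value: `1 - exp(-K m e^(-lambda score))` with m = unmasked
  columns; conservation score `-log10(P)`; CNS iff conservation score
  strictly exceeds `-log10(0.05)`.

## QTL scanning

The scan is Haley-Knott regression on conditional genotype probabilities
rather than multiple imputation: deterministic, fast, and asymptotically
equivalent at the emulated marker density (0.9/cM).  Probabilities of the
heterozygous genotype on a 1-cM grid condition on the nearest non-missing
flanking markers through a two-state Markov chain with recombination
fractions from the inverse Kosambi map function (Haldane by flag).  At a
typed marker the probability is 0 or 1.

`LOD = (n/2) log10(RSS0/RSS1)` compares `trait ~ covariate` against
`trait ~ covariate + P(h)`.  A constant covariate is dropped (equals no
covariate); a covariate collinear with the trait is a degeneracy error,
not an infinite LOD.  The genome-wide threshold permutes the (trait,
covariate) rows jointly against the genotypes -- preserving the
trait-covariate correlation, which is the point of the covariate design --
10,000 times and takes the 1-alpha quantile of the genome-wide maximum.
Joint permutation leaves RSS0 and the null design invariant, so each
permutation costs two matrix cross-products; permutations are processed in
chunks of 250 to bound memory.  The credible interval normalizes `10^LOD`
over one linkage group as a posterior on the grid and grows the smallest
contiguous interval from the peak (towards the denser neighbour) until the
requested mass is covered.  Variance explained is the LOD-implied
R-squared, `1 - 10^(-2 LOD / n)`; as a plain R-squared it carries the
usual upward small-sample bias (about `(1-R^2)/n`, ~1 point at n = 82),
visible in the recovery numbers.

X-chromosome-specific permutation counting and genotype-error-LOD cleaning
are out of scope; all linkage groups are treated as autosomal and input
genotypes are taken as-is.

## Morphometrics

Body size is the geometric mean of the measurements.  Burnaby adjustment
works on natural logs: with the isometric axis `(1,...,1)/sqrt(p)` each
log row is projected perpendicular to the axis, which makes its mean --
the log body size -- exactly zero, i.e. body size one after
exponentiation.  The isometric axis is the default because the geometric-
mean size metric corresponds to it exactly; a pooled-PC1 (allometric) axis
is available, followed by re-centring each specimen to log size zero.
Adjustment is idempotent and preserves between-group differences of log
shape ratios exactly.  Group testing (ANOVA/GLM) is deliberately left to
standard tools on the adjusted table.

## PWM scanning

JASPAR-format count matrices are converted to log2-odds PWMs with a 0.1
pseudocount per cell and a uniform background (both configurable; the
upstream scanner's exact defaults are not public knowledge, so these are
documented rather than asserted equivalent).  Every position is scored on
both strands (minus strand via the reverse-complement matrix), rescaled as
`(score - min)/(max - min)` over the attainable score range, and reported
at relative score >= 0.95 (inclusive).  Windows containing N are skipped;
a motif-width filter restricts to 5-12 bp motifs when set.  SNP
intersection uses 0-based half-open site intervals.

## Problem sizes used by the checks

The acceptance checks run, per fresh session: the 10,000-replicate null at
the full study configuration; a 500-replicate scan-level null over 6-kb
loci with 40 planted-sweep and 40 neutral seeds; 60-100 null BC1 crosses
with 10,000 permutations each on a compact 112-marker map (the calibration
property is map-size free); 30-40 localization seeds at n = 200 on the
full 1,540-marker map; 300-400 variance-explained seeds at n = 82; 40
planted-CNS seeds and 200 null alignments.  These sizes give Monte-Carlo
standard errors comfortably inside the tolerances being checked while
keeping a full run in minutes on one CPU.

## Known limitations

* The sweep generator's instant star-like core corresponds to a sweep
  observed immediately at fixation; Zeng's E has limited power in exactly
  that regime, which is why the detection rule is a majority vote.
* K-A P-values on lattice scores are approximate; K is calibrated by
  simulation to compensate, and the false-CNS rate is verified empirically.
* The CNS model ignores phylogeny (column identity across all rows); with
  many or very unevenly diverged rows the neutral-rate estimate becomes
  conservative.
* Diploid VCF input assumes phased genotypes when expanding to haplotypes
  (an option fails on unphased records instead); how the original
  resequencing data were haploidized is not modelled.
* Whether sweep statistics should be computed on phased haplotypes or
  genotype approximations is exposed as input choice, not decided here.
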