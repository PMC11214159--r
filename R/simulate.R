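# Synthetic-data generators.  Each generator takes an explicit seed, is
# bit-reproducible given it, and records the seed and parameters in the
# object (and in file headers when written).

new_haplotype_set <- function(sequences, ancestral, L, seed, params) {
  structure(list(sequences = sequences, ancestral = ancestral,
                 start = 0L, end = as.integer(L),
                 seed = seed, params = params),
            class = c("haplotype_set", "haplotype_window"))
}

# integer bp positions for continuous [0,1) mutation positions, kept
# distinct (infinite sites on a finite grid): colliding sites move to the
# nearest free position
assign_positions <- function(u, L) {
  bp <- floor(u * L)
  dup <- which(duplicated(bp))
  if (length(dup)) {
    free <- setdiff(seq_len(L) - 1L, bp)
    if (length(free) < length(dup))
      stop("more mutations than sites; increase length_bp")
    for (i in dup) {
      j <- which.min(abs(free - bp[i]))
      bp[i] <- free[j]
      free <- free[-j]
    }
  }
  as.integer(bp)
}

#' Generate a neutral locus as haplotypes plus a perfect ancestral record
#'
#' Simulates one neutral coalescent replicate (with recombination) over the
#' locus, draws a random ancestral sequence, and places each infinite-sites
#' mutation at a distinct bp with a random derived base.
#'
#' @param n haplotypes (default 22, the resequencing sample size emulated).
#' @param length_bp locus length (default 2000).
#' @param theta_site per-site population mutation rate (default 7.6e-3).
#' @param rho_site per-site population recombination rate (default 0.25).
#' @param seed RNG seed.
#' @return a `haplotype_set` (also a [haplotype_window()]): named sample
#'   sequences `hap01..`, `ancestral` sequence, seed and parameters.
#' @export
gen_neutral_locus <- function(n = 22L, length_bp = 2000L,
                              theta_site = 7.6e-3, rho_site = 2.5e-1,
                              seed = 1L) {
  set.seed(seed)
  gen_locus_impl(n, length_bp, theta_site, rho_site, f = 0,
                 sweep_pos = NA, decay_bp = NA, seed = seed)
}

#' Generate a locus carrying a selective-sweep footprint
#'
#' Simulates a neutral locus, then forces a fraction `f` of the sampled
#' lineages to coalesce instantly (star-like core genealogy) at sites near
#' `sweep_pos`: each segregating site adopts the core distortion with
#' probability `exp(-distance / decay_bp)`, so the excess of high-frequency
#' derived alleles decays with distance from the swept site.  `f = 0` is a
#' no-op and reproduces [gen_neutral_locus()] exactly at the same seed.
#'
#' @inheritParams gen_neutral_locus
#' @param sweep_pos bp position of the swept site (default locus centre).
#' @param f fraction of lineages captured by the sweep, in `[0, 1]`.
#' @param decay_bp footprint decay length in bp (default 1000).
#' @return a `haplotype_set`.
#' @export
gen_sweep_locus <- function(n = 22L, length_bp = 2000L,
                            theta_site = 7.6e-3, rho_site = 2.5e-1,
                            sweep_pos = length_bp / 2, f = 0.9,
                            decay_bp = 1000, seed = 1L) {
  if (f < 0 || f > 1) stop("config error: f must be in [0, 1]")
  set.seed(seed)
  gen_locus_impl(n, length_bp, theta_site, rho_site, f, sweep_pos,
                 decay_bp, seed)
}

gen_locus_impl <- function(n, length_bp, theta_site, rho_site, f,
                           sweep_pos, decay_bp, seed) {
  L <- as.integer(length_bp)
  sim <- .sim_arg_cpp(n, theta_site * L, rho_site * L, 1L,
                      detail = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  S <- length(sim$pos)
  hap <- matrix(rep(anc, each = n), nrow = n)
  if (S > 0) {
    bp <- assign_positions(sim$pos, L)
    derived <- vapply(bp, function(p)
      sample(setdiff(bases, anc[p + 1L]), 1L), character(1))
    carriers <- sim$carriers
    if (f > 0) {
      core <- sample.int(n, round(f * n))
      if (length(core) >= 2L) {
        pr <- exp(-abs(bp - sweep_pos) / decay_bp)
        swept <- runif(S) < pr
        for (s in which(swept))
          carriers[s, core] <- carriers[s, core[1L]]
      }
    }
    for (s in seq_len(S))
      hap[carriers[s, ], bp[s] + 1L] <- derived[s]
  }
  seqs <- apply(hap, 1L, paste, collapse = "")
  names(seqs) <- sprintf("hap%02d", seq_len(n))
  params <- list(n = n, length_bp = L, theta_site = theta_site,
                 rho_site = rho_site, f = f, sweep_pos = sweep_pos,
                 decay_bp = decay_bp)
  new_haplotype_set(seqs, paste(anc, collapse = ""), L, seed, params)
}

#' Generate a BC1 cross with an optional planted QTL
#'
#' Genotypes are simulated as a two-state Markov chain along each linkage
#' group with recombination fractions from the inverse Kosambi map function;
#' segregation is 1:1 by construction.  The scanned trait is
#' `intercept + effect * I(h at QTL) + gamma * covariate + noise` with the
#' covariate genetically independent of the QTL; `gamma` is chosen so the
#' trait-covariate correlation under the null equals
#' `covariate_correlation`.  Phenotypes are on the log scale with residual
#' SD 1, so `effect` is in phenotype-SD units.
#'
#' @param n_ind individuals (default 132).
#' @param n_lg linkage groups (default 14).
#' @param markers_per_lg markers per group (default 110, mirroring 1,533
#'   markers overall).
#' @param lg_length_cM length of each group (default 1790/14 cM).
#' @param qtl_lg,qtl_cM planted QTL location (linkage group and position).
#' @param effect additive QTL effect in residual-SD units (0 = null cross).
#' @param covariate_correlation trait-covariate correlation (|r| < 1).
#' @param missing_rate fraction of genotypes set missing (default 0).
#' @param seed RNG seed.
#' @return a [cross_data()] with traits `head_width` (scanned trait) and
#'   `thorax_width` (covariate); attributes `qtl_lg`, `qtl_cM`, `seed`.
#' @export
gen_bc1 <- function(n_ind = 132L, n_lg = 14L, markers_per_lg = 110L,
                    lg_length_cM = 1790 / 14, qtl_lg = NULL,
                    qtl_cM = NULL, effect = 0,
                    covariate_correlation = 0.5, missing_rate = 0,
                    seed = 1L) {
  stopifnot(abs(covariate_correlation) < 1, is.finite(effect))
  set.seed(seed)
  if (is.null(qtl_lg)) qtl_lg <- min(6L, n_lg)
  if (qtl_lg > n_lg) stop("config error: qtl_lg exceeds n_lg")
  if (is.null(qtl_cM)) qtl_cM <- lg_length_cM / 2

  geno <- NULL; map <- NULL; qtl_geno <- NULL
  for (lg in seq_len(n_lg)) {
    mpos <- seq(0, lg_length_cM, length.out = markers_per_lg)
    pos <- mpos
    qidx <- NA_integer_
    if (lg == qtl_lg) {
      pos <- sort(unique(c(mpos, qtl_cM)))
      qidx <- match(qtl_cM, pos)
    }
    r <- kosambi_r(diff(pos))
    G <- matrix(0L, n_ind, length(pos))
    G[, 1L] <- rbinom(n_ind, 1L, 0.5)
    for (k in seq_along(r)) {
      flip <- rbinom(n_ind, 1L, r[k])
      G[, k + 1L] <- ifelse(flip == 1L, 1L - G[, k], G[, k])
    }
    if (!is.na(qidx)) {
      qtl_geno <- G[, qidx]
      keep <- match(mpos, pos)
    } else keep <- seq_along(pos)
    gm <- matrix(c("b", "h")[G[, keep, drop = FALSE] + 1L], n_ind)
    colnames(gm) <- sprintf("m%02d_%03d", lg, seq_along(mpos))
    geno <- cbind(geno, gm)
    map <- rbind(map, data.frame(marker = colnames(gm), lg = lg,
                                 pos = mpos))
  }
  if (missing_rate > 0)
    geno[runif(length(geno)) < missing_rate] <- NA

  covariate <- rnorm(n_ind)
  rho <- covariate_correlation
  gamma <- rho / sqrt(1 - rho^2)
  trait <- effect * qtl_geno + gamma * covariate + rnorm(n_ind)
  phen <- data.frame(head_width = trait, thorax_width = covariate)
  out <- cross_data(geno, map, phen)
  attr(out, "qtl_lg") <- qtl_lg
  attr(out, "qtl_cM") <- qtl_cM
  attr(out, "qtl_geno") <- qtl_geno
  attr(out, "seed") <- seed
  out
}

#' Generate a multi-species non-coding alignment with constrained blocks
#'
#' Rows are mutated from a common random reference: each column is hit by a
#' substitution (one random row changed to a different base) with
#' probability `p_neutral`, or `p_constrained` inside a planted block, so
#' the per-column mismatch probability equals the per-column substitution
#' probability.
#'
#' @param n_rows aligned sequences (default 4).
#' @param length alignment columns (default 300).
#' @param p_neutral per-column substitution probability outside blocks.
#' @param blocks data.frame with 0-based half-open `start`, `end`,
#'   `p_constrained`; blocks must not overlap.
#' @param seed RNG seed.
#' @return an [alignment_block()] with attributes `blocks` and `seed`.
#' @export
gen_alignment <- function(n_rows = 4L, length = 300L, p_neutral = 0.3,
                          blocks = NULL, seed = 1L) {
  stopifnot(p_neutral > 0, p_neutral < 1)
  set.seed(seed)
  p <- rep(p_neutral, length)
  if (!is.null(blocks) && nrow(blocks)) {
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    if (nrow(blocks) > 1 &&
        any(blocks$start[-1] < blocks$end[-nrow(blocks)]))
      stop("config error: overlapping blocks")
    for (i in seq_len(nrow(blocks))) {
      idx <- (blocks$start[i] + 1L):blocks$end[i]
      p[idx] <- blocks$p_constrained[i]
    }
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length, replace = TRUE)
  mat <- matrix(rep(ref, each = n_rows), nrow = n_rows)
  hit <- runif(length) < p
  for (j in which(hit)) {
    i <- sample.int(n_rows, 1L)
    mat[i, j] <- sample(setdiff(bases, ref[j]), 1L)
  }
  rows <- apply(mat, 1L, paste, collapse = "")
  names(rows) <- sprintf("taxon%d", seq_len(n_rows))
  out <- alignment_block(rows)
  attr(out, "blocks") <- blocks
  attr(out, "seed") <- seed
  out
}

#' Generate a log-scale allometric morphometric table
#'
#' `log x_ij = mu_j + s_i + delta[group, j] + eps` with a common
#' isometric size factor `s_i ~ N(0, size_sd)` per specimen; when the group
#' shape offsets are size-orthogonal (rows of `group_shape_offsets` sum to
#' zero) the Burnaby adjustment removes `s_i` exactly.
#'
#' @param groups group labels.
#' @param n_per_group specimens per group (recycled).
#' @param p number of measurements (default 4).
#' @param group_shape_offsets matrix (groups x p) of log-scale shape
#'   offsets; default 0.
#' @param size_sd SD of the log size factor (default 0.1).
#' @param noise_sd residual log-scale SD (default 0.02).
#' @param mu baseline log measurements (default log of typical mm values).
#' @param seed RNG seed.
#' @return data.frame with `id`, `group` and `p` measurement columns (mm);
#'   attribute `seed`.
#' @export
gen_morpho <- function(groups = c("control", "knockdown"),
                       n_per_group = c(20L, 32L), p = 4L,
                       group_shape_offsets = NULL, size_sd = 0.1,
                       noise_sd = 0.02,
                       mu = log(c(5.0, 4.1, 6.2, 7.4))[seq_len(p)],
                       seed = 1L) {
  stopifnot(p >= 2L)
  set.seed(seed)
  n_per_group <- rep_len(n_per_group, length(groups))
  if (is.null(group_shape_offsets))
    group_shape_offsets <- matrix(0, length(groups), p)
  grp <- rep(groups, n_per_group)
  n <- length(grp)
  s <- rnorm(n, 0, size_sd)
  lx <- matrix(rep(mu, each = n), n) + s +
    group_shape_offsets[match(grp, groups), , drop = FALSE] +
    matrix(rnorm(n * p, 0, noise_sd), n)
  out <- data.frame(id = sprintf("sp%03d", seq_len(n)), group = grp,
                    exp(lx))
  names(out)[-(1:2)] <-
    if (p <= 4L) c("head_width", "head_length", "thorax_width",
                   "thorax_length")[seq_len(p)]
    else sprintf("dim%02d", seq_len(p))
  attr(out, "seed") <- seed
  out
}
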