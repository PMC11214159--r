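# Independent oracle implementations used to cross-check package routines.
# These deliberately share no code with the package internals.

# --- no-recombination Kingman coalescent, infinite sites -------------------
# Builds the genealogy level by level (k lineages coalesce at rate
# k(k-1)/2 in units of 2N generations), drops Poisson mutations on each
# lineage during each level with rate theta/2 per unit time, and returns the
# vector of derived-allele counts (one per mutation).
oracle_coalescent_counts <- function(n, theta_locus) {
  desc <- as.list(rep(1L, n))       # descendant count per active lineage
  counts <- integer(0)
  for (k in n:2) {
    t_k <- rexp(1, rate = k * (k - 1) / 2)
    nmut <- rpois(k, theta_locus / 2 * t_k)
    for (j in which(nmut > 0)) {
      d <- desc[[j]]
      if (d < n) counts <- c(counts, rep.int(d, nmut[j]))
    }
    pair <- sample.int(k, 2)
    desc[[pair[1]]] <- desc[[pair[1]]] + desc[[pair[2]]]
    desc[[pair[2]]] <- NULL
  }
  counts
}

# --- Tajima's D, independent transcription of the 1989 standardization -----
oracle_tajima_d <- function(n, counts_per_class) {
  S <- sum(counts_per_class)
  if (S < 1) return(NA_real_)
  i <- seq_len(n - 1)
  pihat <- sum(counts_per_class * i * (n - i)) / choose(n, 2)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  watterson <- S / a1
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pihat - watterson) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# --- theta_pi from explicit pairwise sequence differences ------------------
# Builds a 0/1 haplotype matrix realizing the SFS and averages Hamming
# distances over all pairs.
oracle_pi_pairwise <- function(n, counts_per_class) {
  sites <- unlist(lapply(seq_len(n - 1), function(i)
    rep.int(i, counts_per_class[i])))
  if (!length(sites)) return(0)
  H <- vapply(sites, function(i) {
    v <- integer(n); v[sample.int(n, i)] <- 1L; v
  }, integer(n))
  tot <- 0
  np <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    tot <- tot + sum(H[a, ] != H[b, ])
    np <- np + 1
  }
  tot / np
}

# --- maximal scoring subsequences by exhaustive enumeration ----------------
# A candidate (i, j] (0-based half-open) is "monotone" when every proper
# prefix and suffix has positive score (cumsum characterization); the
# maximal scoring subsequences are the monotone candidates maximal under
# containment.
oracle_maximal_segments <- function(scores) {
  m <- length(scores)
  cs <- c(0, cumsum(scores))
  cand <- list()
  for (i in 0:(m - 1)) for (j in (i + 1):m) {
    if (cs[j + 1] - cs[i + 1] <= 0) next
    if (cs[i + 1] >= min(cs[(i + 2):(j + 1)])) next  # prefix fails
    if (cs[j + 1] < max(cs[(i + 1):j])) next         # suffix fails
    cand[[length(cand) + 1]] <- c(i, j)
  }
  keep <- rep(TRUE, length(cand))
  for (a in seq_along(cand)) for (b in seq_along(cand)) {
    if (a != b && keep[a] &&
        cand[[b]][1] <= cand[[a]][1] && cand[[a]][2] <= cand[[b]][2] &&
        !identical(cand[[a]], cand[[b]]))
      keep[a] <- FALSE
  }
  cand <- cand[keep]
  if (!length(cand))
    return(data.frame(start = integer(), end = integer(),
                      score = numeric()))
  out <- data.frame(start = vapply(cand, `[`, numeric(1), 1),
                    end = vapply(cand, `[`, numeric(1), 2))
  out$score <- cs[out$end + 1] - cs[out$start + 1]
  out[order(out$start), ]
}

# --- PWM scoring by explicit loops -----------------------------------------
oracle_pwm_hits <- function(sequence, mat, threshold) {
  chars <- strsplit(sequence, "")[[1]]
  w <- ncol(mat)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mins <- sum(apply(mat, 2, min)); maxs <- sum(apply(mat, 2, max))
  hits <- data.frame(start = integer(), strand = character(),
                     rel = numeric())
  for (s in seq_len(length(chars) - w + 1)) {
    word <- chars[s:(s + w - 1)]
    if (any(!word %in% c("A", "C", "G", "T"))) next
    for (strand in c("+", "-")) {
      ww <- if (strand == "+") word else rev(unname(comp[word]))
      sc <- 0
      for (k in seq_len(w)) sc <- sc + mat[ww[k], k]
      rel <- (sc - mins) / (maxs - mins)
      if (rel >= threshold)
        hits <- rbind(hits, data.frame(start = s - 1L, strand = strand,
                                       rel = rel))
    }
  }
  hits
}

# --- BC1 genotype probability by enumeration over the hidden state ---------
oracle_genoprob_h <- function(g_left, g_right, d1_cM, d2_cM) {
  r <- function(d) 0.5 * tanh(2 * d / 100)
  r1 <- r(d1_cM); r2 <- r(d2_cM)
  trans <- function(a, b, rr) if (a == b) 1 - rr else rr
  num <- den <- 0
  for (q in c("b", "h")) {
    w <- trans(g_left, q, r1) * trans(q, g_right, r2)
    den <- den + w
    if (q == "h") num <- num + w
  }
  num / den
}

# --- credible-interval mass by direct summation ----------------------------
oracle_interval_mass <- function(lod, lo, hi) {
  w <- 10^(lod - max(lod))
  sum(w[lo:hi]) / sum(w)
}
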