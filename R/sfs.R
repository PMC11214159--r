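#' Haplotype window
#'
#' Container for n aligned haploid sequences plus one aligned ancestral
#' (outgroup) sequence over the same locus.  Sequences are strings over
#' A/C/G/T/N/-; coordinates are 0-based half-open.
#'
#' @param sequences named character vector of n aligned haplotypes (equal
#'   length).
#' @param ancestral single aligned ancestral sequence of the same length.
#' @param start,end locus coordinates in bp; `end - start` must equal the
#'   alignment length.
#' @return An object of class `haplotype_window`.
#' @export
haplotype_window <- function(sequences, ancestral, start = 0L,
                             end = start + nchar(ancestral)) {
  sequences <- toupper(sequences)
  ancestral <- toupper(ancestral)
  if (length(sequences) < 2L)
    stop("need at least 2 sample haplotypes")
  L <- unique(nchar(c(sequences, ancestral)))
  if (length(L) != 1L)
    stop("alignment error: sequences and ancestral differ in length")
  if (end - start != L)
    stop("end - start must equal the alignment length")
  structure(list(sequences = sequences, ancestral = ancestral,
                 start = as.integer(start), end = as.integer(end)),
            class = "haplotype_window")
}

#' @export
print.haplotype_window <- function(x, ...) {
  cat(sprintf("haplotype_window: %d haplotypes + ancestral, %d bp [%d, %d)\n",
              length(x$sequences), x$end - x$start, x$start, x$end))
  invisible(x)
}

#' Derived site-frequency spectrum
#'
#' @param n sample size (number of haplotypes).
#' @param counts integer vector of length `n - 1`; `counts[i]` is the number
#'   of segregating sites whose derived allele is carried by exactly `i`
#'   haplotypes.
#' @return An object of class `derived_sfs` with fields `n`, `counts`, `S`.
#' @export
derived_sfs <- function(n, counts) {
  n <- as.integer(n)
  if (n < 2L) stop("input error: n must be >= 2")
  if (length(counts) != n - 1L)
    stop("counts must have length n - 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(n = n, counts = as.numeric(counts), S = sum(counts)),
            class = "derived_sfs")
}

#' @export
print.derived_sfs <- function(x, ...) {
  cat(sprintf("derived_sfs: n = %d, S = %d\n", x$n, as.integer(x$S)))
  invisible(x)
}

# per-site polarization against the ancestral sequence: returns a data.frame
# with one row per usable segregating site (column index 0-based within the
# window, derived-allele count).  Exclusions follow the infinite-sites
# reading: any gap/N in any row, >2 sample alleles, sites unpolarizable
# because the ancestral base is absent among >1 sample alleles, monomorphic
# and fixed-derived sites.
polarize_sites <- function(window) {
  stopifnot(inherits(window, "haplotype_window"))
  n <- length(window$sequences)
  L <- window$end - window$start
  mat <- matrix(unlist(strsplit(window$sequences, "", fixed = TRUE),
                       use.names = FALSE),
                nrow = n, byrow = TRUE)
  anc <- strsplit(window$ancestral, "", fixed = TRUE)[[1]]

  bases <- c("A", "C", "G", "T")
  ok <- colSums(matrix(mat %in% bases, nrow = n)) == n & anc %in% bases
  diff_anc <- colSums(mat != rep(anc, each = n))
  # candidate variable sites only
  cand <- which(ok & diff_anc > 0L & diff_anc < n)
  # sites where all samples differ from ancestral but are monomorphic are
  # fixed-derived; those appear with diff_anc == n and are already dropped.
  keep <- logical(length(cand))
  count <- integer(length(cand))
  for (k in seq_along(cand)) {
    col <- mat[, cand[k]]
    u <- unique(col)
    if (length(u) > 2L) next                       # >2 sample alleles
    if (!(anc[cand[k]] %in% u)) next               # unpolarizable
    keep[k] <- TRUE
    count[k] <- sum(col != anc[cand[k]])
  }
  data.frame(pos = cand[keep] - 1L, count = count[keep])
}

#' Polarize a haplotype window into a derived SFS
#'
#' Uses the ancestral/outgroup sequence to orient alleles: at each usable
#' site the derived allele is the sample allele differing from the ancestral
#' base.  Sites with any gap/N, more than two sample alleles, an ancestral
#' base absent from a polymorphic sample, monomorphic sites and fixed-derived
#' sites are excluded, so only polarizable segregating sites contribute.
#'
#' @param window a [haplotype_window()].
#' @return A [derived_sfs()].
#' @export
polarize <- function(window) {
  sites <- polarize_sites(window)
  n <- length(window$sequences)
  counts <- tabulate(sites$count, nbins = n - 1L)
  derived_sfs(n, counts)
}

harmonic_constants <- function(n) {
  i <- seq_len(n - 1L)
  list(a_n = sum(1 / i), b_n = sum(1 / i^2))
}

#' SFS-weighted theta estimators
#'
#' Computes the four standard estimators of the population mutation rate from
#' a derived (polarized) SFS: pairwise diversity theta_pi, Watterson's
#' theta_W, theta_L (mean derived-allele count) and Fay-Wu's theta_H, plus
#' the harmonic constants a_n and b_n.  The algebraic identity
#' `theta_pi + theta_H == 2 * theta_L` holds exactly.
#'
#' @param sfs a [derived_sfs()].
#' @return A list of class `theta_set` with fields `theta_pi`, `theta_w`,
#'   `theta_l`, `theta_h`, `a_n`, `b_n`, `n`, `S`.
#' @export
theta_estimators <- function(sfs) {
  stopifnot(inherits(sfs, "derived_sfs"))
  n <- sfs$n
  i <- seq_len(n - 1L)
  Si <- sfs$counts
  hc <- harmonic_constants(n)
  structure(list(
    theta_pi = sum(2 * i * (n - i) * Si) / (n * (n - 1)),
    theta_w  = sfs$S / hc$a_n,
    theta_l  = sum(i * Si) / (n - 1),
    theta_h  = sum(2 * i^2 * Si) / (n * (n - 1)),
    a_n = hc$a_n, b_n = hc$b_n, n = n, S = sfs$S
  ), class = "theta_set")
}

#' Tajima's D
#'
#' Standardized contrast `theta_pi - theta_W`, low when rare alleles (for
#' example singletons) are in excess.  Undefined (`NA`) when the window has
#' no segregating sites.
#'
#' @param sfs a [derived_sfs()].
#' @return Numeric scalar, `NA_real_` when `S == 0`.
#' @export
tajimas_d <- function(sfs) {
  th <- theta_estimators(sfs)
  if (th$S < 1) return(NA_real_)
  n <- th$n
  a1 <- th$a_n
  a2 <- th$b_n
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  S <- th$S
  standardized_contrast(th$theta_pi - th$theta_w,
                        e1 * S + e2 * S * (S - 1))
}

# contrast / sqrt(variance), with the degenerate n = 2 / S = 1 case where
# the variance estimate collapses to zero: a zero contrast is exactly zero
# (the symmetric case), a non-zero contrast is undefined
standardized_contrast <- function(num, var) {
  if (var <= 0) {
    if (abs(num) < 1e-12) return(0)
    return(NA_real_)
  }
  num / sqrt(var)
}

# moments of theta used inside the H and E standardizations:
# theta-hat = S/a_n and theta-squared-hat = S(S-1)/(a_n^2 + b_n)
theta_moments <- function(th) {
  list(t1 = th$S / th$a_n,
       t2 = th$S * (th$S - 1) / (th$a_n^2 + th$b_n))
}

#' Standardized Fay and Wu's H
#'
#' Standardized contrast `theta_pi - theta_L`, low in the presence of
#' numerous high-frequency derived alleles -- the footprint of a recent
#' sweep when variation is polarized against an outgroup.
#'
#' @inheritParams tajimas_d
#' @return Numeric scalar, `NA_real_` when `S == 0`.
#' @export
fay_wu_h_std <- function(sfs) {
  th <- theta_estimators(sfs)
  if (th$S < 1) return(NA_real_)
  n <- th$n
  tm <- theta_moments(th)
  bn1 <- th$b_n + 1 / n^2
  v <- (n - 2) / (6 * (n - 1)) * tm$t1 +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * tm$t2
  standardized_contrast(th$theta_pi - th$theta_l, v)
}

#' Zeng's E
#'
#' Standardized contrast `theta_L - theta_W`, high when high-frequency
#' derived alleles are in excess relative to the number of segregating
#' sites.
#'
#' @inheritParams tajimas_d
#' @return Numeric scalar, `NA_real_` when `S == 0`.
#' @export
zengs_e <- function(sfs) {
  th <- theta_estimators(sfs)
  if (th$S < 1) return(NA_real_)
  n <- th$n
  tm <- theta_moments(th)
  v <- (n / (2 * (n - 1)) - 1 / th$a_n) * tm$t1 +
    (th$b_n / th$a_n^2 +
       2 * (n / (n - 1))^2 * th$b_n -
       2 * (n * th$b_n - n + 1) / ((n - 1) * th$a_n) -
       (3 * n + 1) / (n - 1)) * tm$t2
  standardized_contrast(th$theta_l - th$theta_w, v)
}

sfs_from_counts <- function(n, derived_counts) {
  derived_sfs(n, tabulate(derived_counts, nbins = n - 1L))
}

window_stats_row <- function(n, derived_counts) {
  sfs <- sfs_from_counts(n, derived_counts)
  c(S = sfs$S, D = tajimas_d(sfs), H = fay_wu_h_std(sfs), E = zengs_e(sfs))
}

#' Sliding-window sweep statistics along a locus
#'
#' Polarizes the locus once against the ancestral sequence and computes
#' Tajima's D, standardized Fay-Wu H and Zeng's E in sliding windows.
#' Windows without segregating sites carry `NA` statistics.
#'
#' @param locus a [haplotype_window()] spanning the whole locus.
#' @param window_bp window size in bp (default 2000).
#' @param step_bp step between window starts in bp (default 100).
#' @return data.frame with columns `start`, `end`, `S`, `D`, `H`, `E`
#'   (coordinates 0-based half-open in locus coordinates).
#' @export
sliding_scan <- function(locus, window_bp = 2000L, step_bp = 100L) {
  if (window_bp <= 0 || step_bp <= 0)
    stop("config error: window_bp and step_bp must be positive")
  L <- locus$end - locus$start
  if (window_bp > L)
    stop("config error: window_bp exceeds locus length")
  n <- length(locus$sequences)
  sites <- polarize_sites(locus)
  starts <- seq.int(0L, L - window_bp, by = step_bp)
  out <- t(vapply(starts, function(s) {
    inwin <- sites$count[sites$pos >= s & sites$pos < s + window_bp]
    window_stats_row(n, inwin)
  }, numeric(4)))
  data.frame(start = starts + locus$start,
             end = starts + locus$start + window_bp,
             S = as.integer(out[, "S"]),
             D = out[, "D"], H = out[, "H"], E = out[, "E"])
}

#' Identify sweep-statistic peaks along a window track
#'
#' Returns the window maximizing Zeng's E and the windows minimizing
#' standardized Fay-Wu H and Tajima's D; ties are broken by the smallest
#' start coordinate.  Windows with undefined statistics are ignored.
#'
#' @param track data.frame as returned by [sliding_scan()].
#' @return list with elements `E`, `H`, `D`, each a one-row data.frame
#'   (`start`, `end`, `value`).
#' @export
find_peaks <- function(track) {
  track <- track[order(track$start), , drop = FALSE]
  pick <- function(stat, decreasing) {
    v <- track[[stat]]
    ok <- which(!is.na(v))
    if (!length(ok))
      stop("no-peak error: all windows have undefined statistics")
    idx <- if (decreasing) ok[which.max(v[ok])] else ok[which.min(v[ok])]
    data.frame(start = track$start[idx], end = track$end[idx],
               value = v[idx])
  }
  list(E = pick("E", TRUE), H = pick("H", FALSE), D = pick("D", FALSE))
}
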