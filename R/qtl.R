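#' BC1 cross data
#'
#' Genotypes are coded `"b"` (homozygous for the recurrent parent) and `"h"`
#' (heterozygous); anything else is treated as missing.  Marker positions
#' must be non-decreasing within a linkage group.
#'
#' @param genotypes character matrix, individuals x markers, colnames =
#'   marker names.
#' @param map data.frame with columns `marker`, `lg`, `pos` (cM).
#' @param phenotypes data.frame of numeric traits (rows = individuals).
#' @return object of class `cross_data`.
#' @export
cross_data <- function(genotypes, map, phenotypes) {
  genotypes <- as.matrix(genotypes)
  genotypes[!(genotypes %in% c("b", "h"))] <- NA
  stopifnot(all(c("marker", "lg", "pos") %in% names(map)))
  map <- map[match(colnames(genotypes), map$marker), , drop = FALSE]
  if (anyNA(map$marker)) stop("markers missing from map")
  for (lg in unique(map$lg)) {
    p <- map$pos[map$lg == lg]
    if (is.unsorted(p)) stop("input error: map positions not ordered")
  }
  structure(list(genotypes = genotypes, map = map,
                 phenotypes = as.data.frame(phenotypes)),
            class = "cross_data")
}

#' Filter markers by the expected 1:1 segregation ratio
#'
#' Drops markers whose observed b:h split deviates from 1:1 by a 1-df
#' chi-square test at level `alpha` (missing genotypes excluded from the
#' counts).
#'
#' @param cross a [cross_data()].
#' @param alpha significance level (default 0.05); markers with P >= alpha
#'   are retained.
#' @return the filtered [cross_data()].
#' @export
filter_markers <- function(cross, alpha = 0.05) {
  g <- cross$genotypes
  nb <- colSums(g == "b", na.rm = TRUE)
  nh <- colSums(g == "h", na.rm = TRUE)
  chisq <- (nb - nh)^2 / (nb + nh)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  keep <- !is.na(p) & p >= alpha
  if (!any(keep)) stop("empty-cross error: all markers removed")
  cross_data(cross$genotypes[, keep, drop = FALSE],
             cross$map[keep, , drop = FALSE],
             cross$phenotypes)
}

#' Kosambi map function (distance to recombination fraction)
#'
#' @param d_cM map distance in cM.
#' @return recombination fraction `0.5 * tanh(2 * d)` with `d` in Morgans.
#' @export
kosambi_r <- function(d_cM) 0.5 * tanh(2 * d_cM / 100)

#' Haldane map function (distance to recombination fraction)
#' @param d_cM map distance in cM.
#' @return recombination fraction `0.5 * (1 - exp(-2 d))`, `d` in Morgans.
#' @export
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# conditional P(genotype == "h") at position q between (possibly missing)
# flanking marker genotypes, two-state Markov chain with recombination
# fractions from the chosen map function; all arguments vectorised over
# grid positions
cond_prob_h <- function(gl, gr, r1, r2) {
  # forward message (P(b), P(h)) from the left marker
  pl_h <- ifelse(is.na(gl), 0.5, ifelse(gl == "h", 1 - r1, r1))
  pl_b <- 1 - pl_h
  # likelihood of the right marker given the hidden genotype
  pr_h <- ifelse(is.na(gr), 1, ifelse(gr == "h", 1 - r2, r2))
  pr_b <- ifelse(is.na(gr), 1, ifelse(gr == "h", r2, 1 - r2))
  wh <- pl_h * pr_h
  wb <- pl_b * pr_b
  wh / (wh + wb)
}

#' Genotype probabilities on a cM grid
#'
#' Probability of the heterozygous genotype at each grid position,
#' conditional on the nearest non-missing flanking markers, with
#' recombination fractions from the inverse map function (Kosambi by
#' default).  At a typed marker the probability is 0 or 1.
#'
#' @param cross a [cross_data()].
#' @param grid_step_cM grid spacing in cM (default 1); marker positions are
#'   always included.
#' @param map_fun `"kosambi"` (default) or `"haldane"`.
#' @return list with `grid` (data.frame `lg`, `pos`) and `prob`
#'   (individuals x grid-positions matrix of P(h)).
#' @export
genotype_probabilities <- function(cross, grid_step_cM = 1,
                                   map_fun = c("kosambi", "haldane")) {
  map_fun <- match.arg(map_fun)
  rf <- if (map_fun == "kosambi") kosambi_r else haldane_r
  g <- cross$genotypes
  nind <- nrow(g)
  grids <- list(); probs <- list()
  for (lg in unique(cross$map$lg)) {
    sel <- which(cross$map$lg == lg)
    pos <- cross$map$pos[sel]
    gpos <- sort(unique(c(seq(min(pos), max(pos), by = grid_step_cM), pos)))
    gl <- g[, sel, drop = FALSE]
    pm <- matrix(NA_real_, nind, length(gpos))
    for (i in seq_len(nind)) {
      gi <- gl[i, ]
      typed <- which(!is.na(gi))
      if (!length(typed)) {
        pm[i, ] <- 0.5
        next
      }
      tp <- pos[typed]
      # nearest typed marker at or left of q / at or right of q
      li <- findInterval(gpos, tp)
      ri <- findInterval(gpos, tp, left.open = TRUE) + 1L
      glv <- ifelse(li >= 1L, gi[typed[pmax(li, 1L)]], NA)
      grv <- ifelse(ri <= length(tp), gi[typed[pmin(ri, length(tp))]], NA)
      r1 <- ifelse(li >= 1L, rf(gpos - tp[pmax(li, 1L)]), 0.5)
      r2 <- ifelse(ri <= length(tp), rf(tp[pmin(ri, length(tp))] - gpos), 0.5)
      pm[i, ] <- cond_prob_h(glv, grv, r1, r2)
    }
    grids[[as.character(lg)]] <- data.frame(lg = lg, pos = gpos)
    probs[[as.character(lg)]] <- pm
  }
  list(grid = do.call(rbind, grids), prob = do.call(cbind, probs))
}

# shared pieces for the Haley-Knott regression: null design, residuals and
# the permutation-invariant cross-products
hk_setup <- function(cross, trait, covariate, grid_step_cM, map_fun) {
  y <- cross$phenotypes[[trait]]
  if (is.null(y)) stop("unknown trait: ", trait)
  if (!is.null(covariate) && is.null(cross$phenotypes[[covariate]]))
    stop("unknown covariate: ", covariate)
  cv <- if (is.null(covariate)) NULL else cross$phenotypes[[covariate]]
  # a constant covariate is collinear with the intercept: drop it, so that
  # passing a constant equals passing no covariate at all
  if (!is.null(cv) && stats::var(cv, na.rm = TRUE) < 1e-24) cv <- NULL
  X <- if (is.null(cv)) matrix(1, length(y), 1) else cbind(1, cv)
  keep <- stats::complete.cases(cbind(y, X))
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  gp <- genotype_probabilities(cross, grid_step_cM, map_fun)
  G <- gp$prob[keep, , drop = FALSE]
  qrX <- qr(X)
  r0 <- qr.resid(qrX, y)
  rss0 <- sum(r0^2)
  if (rss0 < 1e-10 * sum(y^2) || rss0 == 0)
    stop("degenerate model: trait is collinear with the covariate")
  list(y = y, X = X, G = G, grid = gp$grid, qrX = qrX, r0 = r0,
       rss0 = rss0, n = length(y))
}

lod_from_parts <- function(rss0, num, den, n) {
  gain <- ifelse(den > 1e-12, num / den, 0)
  rss1 <- pmax(rss0 - gain, 1e-300)
  pmax((n / 2) * log10(rss0 / rss1), 0)
}

#' Single-QTL LOD scan by Haley-Knott regression
#'
#' At each grid position compares `trait ~ covariate` against
#' `trait ~ covariate + P(h)` by regression on the conditional genotype
#' probability: `LOD = (n/2) * log10(RSS0 / RSS1)`.
#'
#' @param cross a [cross_data()].
#' @param trait phenotype column to scan.
#' @param covariate optional phenotype column used as covariate.
#' @param grid_step_cM grid spacing (default 1 cM).
#' @param map_fun map function for genotype probabilities.
#' @return data.frame of class `lod_curve`: `lg`, `pos`, `lod`; attribute
#'   `covariate_used`.
#' @export
scan_lod <- function(cross, trait, covariate = NULL, grid_step_cM = 1,
                     map_fun = "kosambi") {
  s <- hk_setup(cross, trait, covariate, grid_step_cM, map_fun)
  Gres <- qr.resid(s$qrX, s$G)
  num <- as.numeric(crossprod(Gres, s$r0))^2
  den <- colSums(Gres^2)
  out <- s$grid
  out$lod <- lod_from_parts(s$rss0, num, den, s$n)
  attr(out, "covariate_used") <- if (is.null(covariate)) NA_character_
                                 else covariate
  class(out) <- c("lod_curve", "data.frame")
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the (trait, covariate) rows jointly against the genotypes
#' `n_perm` times, records the genome-wide maximum LOD of each permuted
#' scan, and returns the `1 - alpha` quantile.  Joint permutation preserves
#' the trait-covariate correlation, so the null respects the correlated
#' trait design.
#'
#' @inheritParams scan_lod
#' @param n_perm number of permutations (default 10000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param chunk permutations processed per block (memory control).
#' @return numeric threshold; attribute `"max_lods"` holds all permuted
#'   maxima.
#' @export
permutation_threshold <- function(cross, trait, covariate = NULL,
                                  n_perm = 10000L, alpha = 0.05,
                                  grid_step_cM = 1, map_fun = "kosambi",
                                  chunk = 250L) {
  if (n_perm < 1) stop("config error: n_perm must be >= 1")
  s <- hk_setup(cross, trait, covariate, grid_step_cM, map_fun)
  n <- s$n
  G <- s$G
  p <- ncol(G)
  gsum <- colSums(G)
  gss <- colSums(G^2)
  A <- solve(crossprod(s$X))
  has_cov <- ncol(s$X) == 2L
  cvec <- if (has_cov) s$X[, 2L] else NULL

  # jointly permuting (y, covariate) against genotypes is equivalent to
  # leaving the null fit alone and permuting the genotype rows; RSS0, X'X,
  # colSums(G) and colSums(G^2) are invariant, so each permutation needs
  # only two crossproducts
  maxlod <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    nb <- min(chunk, n_perm - done)
    P <- vapply(seq_len(nb), function(i) sample.int(n), integer(n))
    Rt <- matrix(s$r0[P], n, nb)
    Sr <- crossprod(G, Rt)                    # p x nb
    if (has_cov) {
      Ct <- matrix(cvec[P], n, nb)
      Sc <- crossprod(G, Ct)
      den <- gss -
        (A[1, 1] * gsum^2 + 2 * A[1, 2] * gsum * Sc + A[2, 2] * Sc^2)
    } else {
      den <- matrix(gss - A[1, 1] * gsum^2, p, nb)
    }
    lod <- lod_from_parts(s$rss0, Sr^2, den, n)
    dim(lod) <- c(p, nb)
    maxlod[done + seq_len(nb)] <- apply(lod, 2L, max)
    done <- done + nb
  }
  thr <- quantile(maxlod, 1 - alpha, names = FALSE, type = 1)
  attr(thr, "max_lods") <- maxlod
  thr
}

#' Bayesian credible interval for QTL location
#'
#' Normalizes `10^LOD` over one linkage group as a posterior on the grid and
#' returns the smallest contiguous interval containing the peak with mass at
#' least `prob` (grown greedily from the peak towards the higher-density
#' neighbour).
#'
#' @param curve a `lod_curve` from [scan_lod()].
#' @param lg linkage group (defaults to the group containing the global
#'   peak).
#' @param prob coverage probability (default 0.95).
#' @return list `lg`, `start`, `end` (cM), `peak_pos`, `coverage`.
#' @export
bayes_interval <- function(curve, lg = NULL, prob = 0.95) {
  if (is.null(lg)) lg <- curve$lg[which.max(curve$lod)]
  cc <- curve[curve$lg == lg, , drop = FALSE]
  if (!nrow(cc)) stop("no positions on linkage group ", lg)
  if (all(cc$lod == 0))
    stop("undefined-interval error: flat zero LOD curve")
  w <- 10^(cc$lod - max(cc$lod))
  w <- w / sum(w)
  i <- which.max(cc$lod)
  lo <- hi <- i
  mass <- w[i]
  while (mass < prob && (lo > 1L || hi < nrow(cc))) {
    wl <- if (lo > 1L) w[lo - 1L] else -Inf
    wr <- if (hi < nrow(cc)) w[hi + 1L] else -Inf
    if (wl >= wr) { lo <- lo - 1L; mass <- mass + w[lo] }
    else { hi <- hi + 1L; mass <- mass + w[hi] }
  }
  list(lg = lg, start = cc$pos[lo], end = cc$pos[hi],
       peak_pos = cc$pos[i], coverage = mass)
}

#' Proportion of phenotypic variance explained by a QTL
#'
#' `1 - 10^(-2 * LOD / n)`, the R-squared implied by the LOD of the QTL
#' model against the null model.
#'
#' @param lod_at_peak LOD score at the QTL peak.
#' @param n number of individuals in the fit.
#' @return proportion in `[0, 1)`.
#' @export
variance_explained <- function(lod_at_peak, n) {
  stopifnot(n >= 2, lod_at_peak >= 0)
  1 - 10^(-2 * lod_at_peak / n)
}
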