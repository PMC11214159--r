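#' Alignment block for CNS detection
#'
#' Holds >= 2 aligned sequences (rows) plus an optional mask of columns to
#' exclude from scoring (typically annotated coding regions).
#'
#' @param rows named character vector of aligned sequences, equal length.
#' @param mask optional logical vector (length = alignment columns); `TRUE`
#'   marks masked columns, or a two-column matrix/data.frame of 0-based
#'   half-open `(start, end)` ranges to mask.
#' @return object of class `alignment_block`.
#' @export
alignment_block <- function(rows, mask = NULL) {
  rows <- toupper(rows)
  if (length(rows) < 2L) stop("need >= 2 aligned rows")
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("rows differ in length")
  m <- logical(L)
  if (!is.null(mask)) {
    if (is.logical(mask)) {
      stopifnot(length(mask) == L)
      m <- mask
    } else {
      mask <- as.matrix(mask)
      for (i in seq_len(nrow(mask))) {
        s <- max(0L, mask[i, 1]); e <- min(L, mask[i, 2])
        if (e > s) m[(s + 1L):e] <- TRUE
      }
    }
  }
  structure(list(rows = rows, length = L, ids = names(rows), mask = m),
            class = "alignment_block")
}

# logical vector: TRUE where all rows carry the same base (masked columns NA)
column_identity <- function(block) {
  mat <- matrix(unlist(strsplit(block$rows, "", fixed = TRUE),
                       use.names = FALSE),
                nrow = length(block$rows), byrow = TRUE)
  ident <- colSums(mat != rep(mat[1L, ], each = nrow(mat))) == 0L
  ident[block$mask] <- NA
  ident
}

#' Estimate the neutral per-column mismatch rate
#'
#' Fraction of unmasked alignment columns that are not fully identical
#' across rows, clipped to `[0.01, 0.99]`.  This is the neutral evolutionary
#' rate against which constrained (slowly evolving) segments are scored.
#'
#' @param block an [alignment_block()].
#' @return scalar mismatch probability.
#' @export
estimate_neutral_rate <- function(block) {
  ident <- column_identity(block)
  ident <- ident[!is.na(ident)]
  if (length(ident) < 100L)
    stop("estimation error: need >= 100 unmasked columns")
  min(max(mean(!ident), 0.01), 0.99)
}

#' Two-rate log-odds scoring scheme for constrained evolution
#'
#' Column scores are the log odds of the constrained model against the
#' neutral model: `log((1 - p_c) / (1 - p_n))` for an identical column and
#' `log(p_c / p_n)` for a mismatching column.  Requires
#' `0 < p_constrained < p_neutral < 1` so that the expected score under the
#' neutral model is negative and the match score positive.
#'
#' @param p_neutral neutral per-column mismatch probability.
#' @param p_constrained constrained mismatch probability (default
#'   `p_neutral / 5`).
#' @return object of class `score_scheme` (uncalibrated: `lambda`/`K` are
#'   `NULL` until [calibrate_karlin_altschul()]).
#' @export
score_scheme <- function(p_neutral, p_constrained = p_neutral / 5) {
  if (!(p_constrained > 0 && p_constrained < p_neutral && p_neutral < 1))
    stop("require 0 < p_constrained < p_neutral < 1")
  s_match <- log((1 - p_constrained) / (1 - p_neutral))
  s_mismatch <- log(p_constrained / p_neutral)
  e_neutral <- (1 - p_neutral) * s_match + p_neutral * s_mismatch
  if (e_neutral >= 0)
    stop("expected neutral column score must be negative")
  structure(list(p_neutral = p_neutral, p_constrained = p_constrained,
                 s_match = s_match, s_mismatch = s_mismatch,
                 lambda = NULL, K = NULL, m_calibration = NULL),
            class = "score_scheme")
}

#' Column-wise log-odds scores
#'
#' One score per alignment column: `s_match` where all rows agree,
#' `s_mismatch` otherwise; masked columns score 0 so they neither extend nor
#' break segments (CNS calls are therefore invariant to adding masked
#' columns).
#'
#' @param block an [alignment_block()].
#' @param scheme a [score_scheme()].
#' @return numeric vector, length = alignment columns.
#' @export
column_scores <- function(block, scheme) {
  ident <- column_identity(block)
  s <- ifelse(is.na(ident), 0, ifelse(ident, scheme$s_match,
                                      scheme$s_mismatch))
  as.numeric(s)
}

#' All maximal-scoring subsequences (Ruzzo-Tompa)
#'
#' Decomposes a score vector into the complete set of disjoint
#' maximal-scoring positive subsequences.
#'
#' @param scores finite numeric vector.
#' @return data.frame with 0-based half-open `start`, `end` and `score`,
#'   in coordinate order.
#' @export
maximal_segments <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  out <- .ruzzo_tompa_cpp(as.numeric(scores))
  out[order(out$start), , drop = FALSE]
}

# draw null (neutral-model) column score vectors and return the max
# maximal-segment score for each
null_segment_maxima <- function(scheme, m, n_null) {
  vapply(seq_len(n_null), function(i) {
    mis <- runif(m) < scheme$p_neutral
    sc <- ifelse(mis, scheme$s_mismatch, scheme$s_match)
    seg <- .ruzzo_tompa_cpp(sc)
    if (nrow(seg)) max(seg$score) else 0
  }, numeric(1))
}

#' Calibrate Karlin-Altschul parameters for a scoring scheme
#'
#' `lambda` is the unique positive root of
#' `(1 - p_n) * exp(lambda * s_match) + p_n * exp(lambda * s_mismatch) = 1`
#' (bisection to `|f| < 1e-12`).  `K` is estimated from simulated null
#' blocks by matching the empirical upper tail of the maximal-segment-score
#' distribution to the Gumbel form
#' `P(M <= x) = exp(-K * m * exp(-lambda * x))`, unless supplied.
#'
#' @param scheme a [score_scheme()].
#' @param K optional known K (skips simulation).
#' @param m number of columns used for the K-calibration blocks (defaults to
#'   500).
#' @param n_null number of simulated null blocks (default 10000).
#' @return the scheme with `lambda`, `K` and `m_calibration` filled in.
#' @export
calibrate_karlin_altschul <- function(scheme, K = NULL, m = 500L,
                                      n_null = 10000L) {
  stopifnot(inherits(scheme, "score_scheme"))
  pn <- scheme$p_neutral
  if ((1 - pn) * scheme$s_match + pn * scheme$s_mismatch >= 0)
    stop("calibration error: expected neutral score is not negative, ",
         "no positive root for lambda")
  f <- function(l) {
    (1 - pn) * exp(l * scheme$s_match) + pn * exp(l * scheme$s_mismatch) - 1
  }
  # bracket the positive root: f(0) = 0, f'(0) < 0, f -> Inf
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 0
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-12) break
    if (fm < 0) lo <- mid else hi <- mid
  }
  lambda <- mid
  if (lambda <= 1e-8) stop("calibration error: no positive root for lambda")
  if (is.null(K)) {
    M <- null_segment_maxima(scheme, m, n_null)
    # fit K on the upper tail, where the alpha-level calls live
    qs <- seq(0.80, 0.98, by = 0.02)
    xs <- quantile(M, qs, names = FALSE, type = 8)
    Fh <- vapply(xs, function(x) mean(M <= x), numeric(1))
    ok <- Fh > 0 & Fh < 1 & xs > 0
    if (!any(ok)) stop("calibration error: degenerate null maxima")
    K <- stats::median(-log(Fh[ok]) * exp(lambda * xs[ok]) / m)
  }
  scheme$lambda <- lambda
  scheme$K <- K
  scheme$m_calibration <- m
  scheme
}

segment_pvalue <- function(score, lambda, K, m) {
  1 - exp(-K * m * exp(-lambda * score))
}

#' Call conserved non-coding segments
#'
#' Scores the alignment columns, extracts all maximal-scoring segments, and
#' converts each segment score into a Karlin-Altschul P-value with
#' `m` = number of unmasked columns.  The conservation score is
#' `-log10(P)`; segments with conservation score strictly greater than
#' `-log10(alpha)` are flagged as CNSs.
#'
#' @param block an [alignment_block()].
#' @param scheme a calibrated [score_scheme()]; if `NULL`, the neutral rate
#'   is estimated from the block and the scheme calibrated with defaults.
#' @param alpha significance level for the CNS flag (default 0.05).
#' @param n_null null blocks for K calibration when calibrating here.
#' @return data.frame of class `cns_calls`: `start`, `end` (0-based
#'   half-open columns), `score`, `p_value`, `conservation_score`, `is_cns`,
#'   in coordinate order.
#' @export
call_cns <- function(block, scheme = NULL, alpha = 0.05, n_null = 10000L) {
  if (is.null(scheme)) {
    scheme <- score_scheme(estimate_neutral_rate(block))
    scheme <- calibrate_karlin_altschul(scheme, m = sum(!block$mask),
                                        n_null = n_null)
  }
  if (is.null(scheme$lambda) || is.null(scheme$K))
    stop("uncalibrated scheme: run calibrate_karlin_altschul() first")
  sc <- column_scores(block, scheme)
  seg <- maximal_segments(sc)
  m <- sum(!block$mask)
  p <- segment_pvalue(seg$score, scheme$lambda, scheme$K, m)
  out <- data.frame(start = seg$start, end = seg$end, score = seg$score,
                    p_value = p,
                    conservation_score = -log10(pmax(p, .Machine$double.xmin)))
  out$is_cns <- out$conservation_score > -log10(alpha)
  class(out) <- c("cns_calls", "data.frame")
  out
}
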