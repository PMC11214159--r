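#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR flat/pfm format: a `>ID NAME` header followed by four
#' count rows (A, C, G, T), with or without the row letter and square
#' brackets.
#'
#' @param path file path.
#' @return list of `pfm` objects (fields `id`, `name`, `counts` 4 x w matrix
#'   with rownames A/C/G/T, `width`).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("parse error: no '>' headers in ", path)
  out <- vector("list", length(hdr))
  ends <- c(hdr[-1] - 1L, length(lines))
  for (k in seq_along(hdr)) {
    h <- sub("^>\\s*", "", lines[hdr[k]])
    parts <- strsplit(h, "\\s+")[[1]]
    body <- lines[(hdr[k] + 1L):ends[k]]
    if (length(body) != 4L)
      stop("parse error: motif ", parts[1], " does not have 4 count rows")
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*", "", trimws(ln))
      ln <- gsub("[][]", " ", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L)
      stop("parse error: ragged count rows for motif ", parts[1])
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[k]] <- pfm(id = parts[1],
                    name = if (length(parts) > 1) parts[2] else parts[1],
                    counts = counts)
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Position frequency matrix
#'
#' @param id,name motif identifiers.
#' @param counts 4 x w non-negative matrix, rows A, C, G, T.
#' @return object of class `pfm`.
#' @export
pfm <- function(id, name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || ncol(counts) < 1L)
    stop("input error: counts must be a 4 x w matrix with w >= 1")
  if (any(counts < 0) || any(colSums(counts) <= 0))
    stop("input error: negative counts or empty column")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(id = id, name = name, counts = counts,
                 width = ncol(counts)), class = "pfm")
}

#' Convert a PFM to a log-odds PWM
#'
#' Adds a pseudocount per cell, normalizes each column to probabilities, and
#' takes log2 odds against the background; the minimum and maximum
#' attainable word scores (column-wise minima/maxima sums) are attached for
#' relative-score scaling.
#'
#' @param x a [pfm()].
#' @param pseudocount pseudocount added to every cell (default 0.1).
#' @param background background base frequencies (A, C, G, T); default
#'   uniform.
#' @return object of class `pwm`: `mat` (4 x w log2-odds), `min_score`,
#'   `max_score`, plus the source id/name/width.
#' @export
pfm_to_pwm <- function(x, pseudocount = 0.1, background = rep(0.25, 4)) {
  stopifnot(inherits(x, "pfm"))
  pr <- sweep(x$counts + pseudocount, 2,
              colSums(x$counts + pseudocount), "/")
  mat <- log2(pr / background)
  structure(list(id = x$id, name = x$name, mat = mat, width = x$width,
                 min_score = sum(apply(mat, 2, min)),
                 max_score = sum(apply(mat, 2, max))),
            class = "pwm")
}

revcomp_pwm <- function(pwm) {
  m <- pwm$mat[c("T", "G", "C", "A"), rev(seq_len(pwm$width)), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pwm$mat <- m
  pwm
}

pwm_window_scores <- function(codes, mat, w) {
  npos <- length(codes) - w + 1L
  if (npos < 1L) return(numeric(0))
  s <- numeric(npos)
  idx <- seq_len(npos)
  for (k in seq_len(w)) {
    ck <- codes[idx + k - 1L]
    sk <- mat[cbind(ck, k)]
    s <- s + ifelse(is.na(ck), NA_real_, sk)   # NA propagates N-containing
  }
  s
}

#' Scan a sequence with a PWM at a relative-score threshold
#'
#' Scores every position on both strands (minus strand via the
#' reverse-complement matrix), rescales to
#' `(score - min) / (max - min)` and reports sites with relative score
#' `>= threshold`.  Windows containing N are skipped.
#'
#' @param sequence character string over A/C/G/T/N.
#' @param pwm a [pfm_to_pwm()] result.
#' @param threshold relative-score threshold in `[0, 1]` (default 0.95,
#'   inclusive).
#' @return data.frame with `motif`, `start`, `end` (0-based half-open),
#'   `strand`, `score`, `relative_score`, sorted by `start`.
#' @export
scan_pwm <- function(sequence, pwm, threshold = 0.95) {
  stopifnot(inherits(pwm, "pwm"), threshold >= 0, threshold <= 1)
  rng <- pwm$max_score - pwm$min_score
  if (rng < 1e-9)
    stop("degenerate motif: max and min attainable scores coincide")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  codes <- match(chars, c("A", "C", "G", "T"))
  hits <- list()
  for (strand in c("+", "-")) {
    m <- if (strand == "+") pwm$mat else revcomp_pwm(pwm)$mat
    sc <- pwm_window_scores(codes, m, pwm$width)
    rel <- (sc - pwm$min_score) / rng
    sel <- which(!is.na(rel) & rel >= threshold)
    if (length(sel))
      hits[[strand]] <- data.frame(
        motif = pwm$id, start = sel - 1L, end = sel - 1L + pwm$width,
        strand = strand, score = sc[sel], relative_score = rel[sel])
  }
  out <- if (length(hits)) do.call(rbind, hits)
  else data.frame(motif = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric(),
                  relative_score = numeric())
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan with several motifs, optionally keeping only 5-12 bp sites
#'
#' @param sequence character string over A/C/G/T/N.
#' @param pfms list of [pfm()] objects.
#' @param threshold relative-score threshold.
#' @param width_filter if `TRUE`, keep only motifs of width 5 to 12 bp.
#' @param ... passed to [pfm_to_pwm()].
#' @return combined data.frame of binding sites.
#' @export
scan_motifs <- function(sequence, pfms, threshold = 0.95,
                        width_filter = FALSE, ...) {
  if (width_filter)
    pfms <- Filter(function(p) p$width >= 5 && p$width <= 12, pfms)
  res <- lapply(pfms, function(p)
    scan_pwm(sequence, pfm_to_pwm(p, ...), threshold))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Annotate binding sites with overlapping SNPs
#'
#' A SNP at position `x` (same 0-based coordinate system as the sites)
#' overlaps a site when `start <= x < end`.
#'
#' @param sites data.frame from [scan_pwm()]/[scan_motifs()].
#' @param snp_positions integer vector of SNP positions.
#' @return the sites with added `n_snps` and comma-separated `snp_hits`
#'   columns; attribute `"n_sites_with_snp"` gives the summary count.
#' @export
snp_overlap <- function(sites, snp_positions) {
  snp_positions <- sort(unique(as.integer(snp_positions)))
  ov <- lapply(seq_len(nrow(sites)), function(i) {
    snp_positions[snp_positions >= sites$start[i] &
                    snp_positions < sites$end[i]]
  })
  sites$n_snps <- lengths(ov)
  sites$snp_hits <- vapply(ov, paste, character(1), collapse = ",")
  attr(sites, "n_sites_with_snp") <- sum(sites$n_snps > 0)
  sites
}
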