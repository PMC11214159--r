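#' Geometric-mean body size
#'
#' The geometric mean of a specimen's measurements is the body-size metric;
#' for a matrix, one size per row.
#'
#' @param x positive numeric vector (one specimen) or matrix/data.frame of
#'   measurements (specimens x dimensions).
#' @return numeric scalar or vector of geometric means.
#' @export
body_size <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (any(x <= 0)) stop("input error: measurements must be positive")
  if (is.matrix(x)) exp(rowMeans(log(x))) else exp(mean(log(x)))
}

#' Burnaby size correction with back-projection
#'
#' Projects log-transformed measurements into the space perpendicular to the
#' body-size axis and back-projects so every adjusted specimen has
#' log body size exactly zero (body size = one).  With the default isometric
#' axis `(1, ..., 1)/sqrt(p)` the size axis corresponds exactly to the
#' geometric-mean body size; `axis = "pc1"` instead removes the first
#' principal component of the pooled log covariance (allometric size), then
#' recentres each specimen to geometric mean one.
#'
#' @param x matrix/data.frame of positive measurements (specimens x p >= 2
#'   dimensions); non-measurement columns are not allowed (subset first).
#' @param axis `"isometric"` (default) or `"pc1"`.
#' @return matrix of adjusted measurements on the original (mm) scale, with
#'   every row's geometric mean equal to 1.
#' @export
burnaby_adjust <- function(x, axis = c("isometric", "pc1")) {
  axis <- match.arg(axis)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (ncol(x) < 2L) stop("input error: need p >= 2 measurements")
  if (any(x <= 0)) stop("input error: measurements must be positive")
  lx <- log(x)
  p <- ncol(x)
  g <- if (axis == "isometric") rep(1, p) / sqrt(p)
  else {
    v <- eigen(stats::cov(lx), symmetric = TRUE)$vectors[, 1L]
    if (sum(v) < 0) v <- -v
    v
  }
  proj <- lx - (lx %*% g) %*% t(g)
  # back-projection: force log body size (row mean) to exactly zero
  proj <- proj - rowMeans(proj)
  out <- exp(proj)
  dimnames(out) <- dimnames(x)
  out
}
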