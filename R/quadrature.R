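# Numerical quadrature primitives.
#
# Two workhorses live here:
#  * Gauss-Legendre node/weight generation (Golub-Welsch on the Jacobi
#    matrix), cached per order;
#  * bivariate standard-normal strip probabilities
#    P(zlo < Z <= zhi, W > wlo) for correlated (Z, W), computed by
#    composite Gauss-Legendre integration of the conditional normal CDF.
#    These are the rectangle probabilities behind every discrete-scale
#    likelihood in the package.

.gauss_legendre <- function(k) {
  key <- sprintf("gl%d", k)
  cached <- .bimeta_env[[key]]
  if (!is.null(cached)) return(cached)
  if (k == 1L) {
    out <- list(x = 0, w = 2)
  } else {
    i <- seq_len(k - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, k, k)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    out <- list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
  }
  .bimeta_env[[key]] <- out
  out
}

# Composite Gauss-Legendre nodes/weights over segments defined by `edges`
# (ascending). Returns list(x, w) with sum(w * f(x)) ~ integral.
.composite_gl <- function(edges, k = 5L) {
  gl <- .gauss_legendre(k)
  nseg <- length(edges) - 1L
  mid <- (edges[-1] + edges[-(nseg + 1L)]) / 2
  hw <- (edges[-1] - edges[-(nseg + 1L)]) / 2
  x <- rep(mid, each = k) + rep(hw, each = k) * rep(gl$x, nseg)
  w <- rep(hw, each = k) * rep(gl$w, nseg)
  list(x = x, w = w)
}

# Segment edges over [lo, hi] with width <= h.
.seg_edges <- function(lo, hi, h) {
  if (hi <= lo) return(NULL)
  n <- max(1L, ceiling((hi - lo) / h))
  seq(lo, hi, length.out = n + 1L)
}

# P(zlo < Z <= zhi, W > wlo) for standard bivariate normal (Z, W) with
# correlation rho. Vectorised over intervals; wlo may be scalar or one
# value per interval.
.strip_upper <- function(zlo, zhi, wlo, rho) {
  nn <- max(length(zlo), length(zhi), length(wlo))
  zlo <- rep_len(zlo, nn); zhi <- rep_len(zhi, nn); wlo <- rep_len(wlo, nn)
  out <- numeric(nn)
  lo <- .clamp(zlo, -8.5, 8.5)
  hi <- .clamp(zhi, -8.5, 8.5)
  live <- hi > lo
  if (!any(live)) return(out)
  if (abs(rho) < 1e-12) {
    out[live] <- (pnorm(hi[live]) - pnorm(lo[live])) * pnorm(wlo[live], lower.tail = FALSE)
    return(out)
  }
  s <- sqrt(max(1 - rho^2, 1e-12))
  idx <- which(live)
  h <- max(0.12, 0.45 * s)   # segment width follows the conditional scale
  width <- hi[idx] - lo[idx]
  nseg <- pmax(1L, ceiling(width / h))
  gl <- .gauss_legendre(5L)
  k <- 5L
  seg_int <- rep.int(seq_along(idx), nseg)          # interval id per segment
  pos <- sequence(nseg)                             # 1..nseg within interval
  segw <- (width / nseg)[seg_int]
  mid <- lo[idx][seg_int] + (pos - 0.5) * segw
  hw <- segw / 2
  nsegt <- length(mid)
  x <- rep(mid, each = k) + rep(hw, each = k) * rep.int(gl$x, nsegt)
  w <- rep(hw, each = k) * rep.int(gl$w, nsegt)
  wl <- rep(wlo[idx][seg_int], each = k)
  vals <- w * dnorm(x) * pnorm((rho * x - wl) / s)
  out[idx] <- as.numeric(rowsum(vals, rep(seg_int, each = k)))
  pmax(out, 0)
}

#' Bivariate standard-normal distribution function
#'
#' `P(Z <= h, W <= k)` for a standard bivariate normal pair with
#' correlation `rho`. Used internally for rectangle probabilities in the
#' discrete-scale likelihoods; exposed because it is handy for checking
#' them against independent oracles.
#'
#' @param h,k Upper limits (vectorised, recycled to common length).
#' @param rho Correlation in (-1, 1).
#' @return Vector of probabilities.
#' @examples
#' pbvnorm(0, 0, 0.5)  # 1/4 + asin(0.5)/(2*pi)
#' @export
pbvnorm <- function(h, k, rho) {
  if (abs(rho) >= 1) .stopf("|rho| must be < 1")
  nn <- max(length(h), length(k))
  h <- rep_len(h, nn); k <- rep_len(k, nn)
  pnorm(h) - .strip_upper(rep(-Inf, nn), h, k, rho)
}
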