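# The meta-d' model (maximum-likelihood, equal-variance, response-specific
# type 2 criteria, type 1 criterion held at its relative position).
#
# Type 2 rating probabilities conditional on (stimulus, response) come from
# an SDT observer whose sensitivity is meta-d' instead of d'; the type 1
# criterion is scaled to meta_c = c * meta-d'/d' so its relative position
# is preserved. A padding constant (1/(2n) per cell) stabilises sparse
# tables before fitting.

#' Stimulus x response x rating count table
#'
#' @param trials Discrete-scale recognition trial table.
#' @param n Number of rating points (default: from the table).
#' @return A 2 x 2 x n array with dimnames stimulus (S1/S2),
#'   response (S1/S2), rating (1..n).
#' @export
count_table_recognition <- function(trials, n = NULL) {
  if (is.null(n)) n <- .parse_scale(trials$scale[1])$n
  .check_discrete(trials, n)
  out <- array(0, dim = c(2L, 2L, n),
               dimnames = list(stimulus = c("S1", "S2"),
                               response = c("S1", "S2"),
                               rating = seq_len(n)))
  for (i in seq_len(nrow(trials))) {
    s <- if (trials$stimulus[i] == "S1") 1L else 2L
    r <- if (trials$response[i] == "S1") 1L else 2L
    k <- as.integer(trials$confidence[i])
    out[s, r, k] <- out[s, r, k] + 1
  }
  out
}

# Rating probabilities conditional on response for one stimulus mean.
# Returns list(r1 = length-n vector, r2 = length-n vector) where r1[j] is
# P(rating j | response S1, stimulus), highest confidence farthest from
# meta_c.
.metad_cond_probs <- function(mu, meta_c, t2c_r1, t2c_r2) {
  n <- length(t2c_r1) + 1L
  # S1 response region (-inf, meta_c]; boundaries ascending:
  b1 <- c(-Inf, t2c_r1, meta_c)
  p1 <- pnorm(b1[-1] - mu) - pnorm(b1[-(n + 1L)] - mu)    # rating n..1
  b2 <- c(meta_c, t2c_r2, Inf)
  p2 <- pnorm(b2[-1] - mu) - pnorm(b2[-(n + 1L)] - mu)    # rating 1..n
  P1 <- pnorm(meta_c - mu)
  list(r1 = rev(p1) / max(P1, 1e-300),
       r2 = p2 / max(1 - P1, 1e-300))
}

#' Fit the meta-d' model with padding
#'
#' @param counts 2 x 2 x n count array (see [count_table_recognition()]).
#' @param options List: `n_starts` (default 2), `start_seed`, `maxit`,
#'   `factr`, `padding` (default `1/(2n)` added to every cell).
#' @return Object of class `bim_metad_fit`: `meta_d`, `d_prime`,
#'   `criterion`, `meta_c`, ascending `criteria_rS1` / `criteria_rS2`, the
#'   per-response criterion summaries `M_CrS1`, `SD_CrS1`, `M_CrS2`,
#'   `SD_CrS2`, `meta_d_ratio`, `loglik`, `converged`.
#' @export
metad_fit <- function(counts, options = list()) {
  if (length(dim(counts)) != 3L || any(dim(counts)[1:2] != 2L))
    .stopf("counts must be a 2 x 2 x n array")
  n <- dim(counts)[3]
  opt <- .fit_defaults(modifyList(list(n_starts = 2L), options))
  pad <- opt$padding %||% (1 / (2 * n))
  cts <- counts + pad

  # type 1 parameters from the padded response totals
  n_s1 <- sum(cts[1, , ]); n_s2 <- sum(cts[2, , ])
  HR <- sum(cts[2, 2, ]) / n_s2
  FAR <- sum(cts[1, 2, ]) / n_s1
  sdt <- sdt_from_rates(.clamp(HR, 1e-6, 1 - 1e-6), .clamp(FAR, 1e-6, 1 - 1e-6))
  d1 <- sdt$d_prime
  c1 <- sdt$criterion

  k <- n - 1L
  # theta = (meta_d, log-increments below meta_c (k), above meta_c (k))
  theta0 <- c(d1, rep(log(0.4), 2 * k))
  lower <- c(-8, rep(-7, 2 * k))
  upper <- c(8, rep(2, 2 * k))

  unpack <- function(th) {
    meta_d <- th[1]
    meta_c <- if (abs(d1) > 1e-3) c1 * meta_d / d1 else c1
    t2c_r1 <- meta_c - rev(cumsum(exp(th[2:(1 + k)])))         # ascending
    t2c_r2 <- meta_c + cumsum(exp(th[(2 + k):(1 + 2 * k)]))    # ascending
    list(meta_d = meta_d, meta_c = meta_c, t2c_r1 = t2c_r1, t2c_r2 = t2c_r2)
  }

  obj <- function(th) {
    p <- unpack(th)
    nll <- 0
    for (s in 1:2) {
      mu <- if (s == 1) -p$meta_d / 2 else p$meta_d / 2
      pr <- .metad_cond_probs(mu, p$meta_c, p$t2c_r1, p$t2c_r2)
      nll <- nll - sum(cts[s, 1, ] * log(pmax(pr$r1, 1e-300))) -
        sum(cts[s, 2, ] * log(pmax(pr$r2, 1e-300)))
    }
    list(value = nll, grad = NULL)
  }
  starts <- .make_starts(theta0, opt$n_starts, 0.3, opt$start_seed, lower, upper)
  best <- .mle_multistart(obj, starts, lower, upper, opt$maxit, opt$factr,
                          has_grad = FALSE)
  p <- unpack(best$par)
  structure(list(meta_d = p$meta_d, d_prime = d1, criterion = c1,
                 meta_c = p$meta_c,
                 criteria_rS1 = p$t2c_r1, criteria_rS2 = p$t2c_r2,
                 M_CrS1 = mean(p$t2c_r1), SD_CrS1 = stats::sd(p$t2c_r1),
                 M_CrS2 = mean(p$t2c_r2), SD_CrS2 = stats::sd(p$t2c_r2),
                 meta_d_ratio = if (abs(d1) > 1e-3) p$meta_d / d1 else NA_real_,
                 loglik = -best$value, converged = best$n_converged,
                 padding = pad),
            class = "bim_metad_fit")
}
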