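# Discrete-scale likelihoods: bivariate-normal rectangle probabilities.
#
# On an n-point scale the observer bins the noiseless posterior probability
# with the fixed unit-scale criteria i/n, which map to criteria on the
# standardised experience deviation z. Cell probabilities are rectangles of
# the standard bivariate normal (z, w) with correlation rho, where w is the
# strength deviation (recall: recalled iff w > -mu_m; recognition: the
# response region is bounded at C -/+ d'/2).

# z-scale bin edges (ascending) implied by (P_exp, M_conf) on an n-point
# scale for a cell whose predicted confidence is Phi(a + b z) with b > 0.
.z_edges_up <- function(n, P_exp, M_conf) {
  a <- canonical_cell_shift(M_conf, P_exp)
  b <- .canonical_slope(P_exp)
  c(-Inf, (qnorm(seq_len(n - 1L) / n) - a) / b, Inf)
}

# Cell probability matrix for recall: rows outcome 0/1, columns bins 1..n.
.recall_cells <- function(n, mu_m, rho, P_exp, M_conf) {
  edges <- .z_edges_up(n, P_exp, M_conf)
  zlo <- edges[-(n + 1L)]
  zhi <- edges[-1L]
  p1 <- .strip_upper(zlo, zhi, -mu_m, rho)
  ptot <- pnorm(zhi) - pnorm(zlo)
  rbind(`0` = pmax(ptot - p1, 0), `1` = p1)
}

# Cell probabilities for recognition, one stimulus at a time.
# Returns a list with matrices [response r1/r2, bin] summing to 1 per
# stimulus.
.recog_cells <- function(n, P_exp, rho, M_conf, d_prime, criterion) {
  b <- .canonical_slope(P_exp)
  out <- list()
  for (stim in c("s1", "s2")) {
    mu_s <- if (stim == "s1") -d_prime / 2 else d_prime / 2
    wlo <- criterion - mu_s            # response S2 iff w > wlo
    # S2 responses: p(z) = Phi(a2 + b z), increasing in z
    edges2 <- .z_edges_up(n, P_exp, M_conf[[paste0(stim, "_r2")]])
    pr2 <- .strip_upper(edges2[-(n + 1L)], edges2[-1L], wlo, rho)
    # S1 responses: p(z) = Phi(a1 - b z), decreasing in z
    a1 <- canonical_cell_shift(M_conf[[paste0(stim, "_r1")]], P_exp)
    qcut <- qnorm(seq_len(n - 1L) / n)
    # bin i: z in ((a1 - qnorm(i/n))/b, (a1 - qnorm((i-1)/n))/b]
    zlo <- (a1 - c(qcut, Inf)) / b
    zhi <- (a1 - c(-Inf, qcut)) / b
    tot <- pnorm(zhi) - pnorm(zlo)
    pr1 <- pmax(tot - .strip_upper(zlo, zhi, wlo, rho), 0)
    m <- rbind(r1 = pr1, r2 = pr2)
    out[[stim]] <- m
  }
  out
}

.check_discrete <- function(trials, n) {
  conf <- trials$confidence
  if (any(conf != round(conf)) || any(conf < 1) || any(conf > n))
    .stopf("discrete confidence must be integers in 1..%d", n)
}

#' Log-likelihood: recall task, discrete confidence
#'
#' Multinomial log-likelihood over the 2n (outcome x bin) cells, each a
#' standard-bivariate-normal rectangle probability.
#'
#' @param trials Trial table of discrete-scale recall trials.
#' @param params A [recall_params()] object.
#' @param n Number of scale points; taken from the trial table's scale
#'   descriptor when omitted.
#' @return Scalar log-likelihood.
#' @export
loglik_recall_discrete <- function(trials, params, n = NULL) {
  stopifnot(inherits(params, "bim_recall_params"))
  if (is.null(n)) n <- .parse_scale(trials$scale[1])$n
  .check_discrete(trials, n)
  cells <- .recall_cells(n, params$mu_m, params$rho, params$P_exp, params$M_conf)
  idx <- cbind(trials$outcome + 1L, as.integer(trials$confidence))
  sum(log(pmax(cells[idx], 1e-300)))
}

#' Log-likelihood: recognition task, discrete confidence
#'
#' Conditional on the stimulus shown, cell probabilities over
#' (response x bin) come from bivariate rectangles with the response
#' region bounding the strength deviation; they sum to 1 per stimulus.
#'
#' @inheritParams loglik_recall_discrete
#' @param params A [recognition_params()] object.
#' @return Scalar log-likelihood.
#' @export
loglik_recognition_discrete <- function(trials, params, n = NULL) {
  stopifnot(inherits(params, "bim_recognition_params"))
  if (is.null(n)) n <- .parse_scale(trials$scale[1])$n
  if (any(is.na(trials$stimulus)) || any(is.na(trials$response)))
    .stopf("recognition trials need stimulus and response")
  .check_discrete(trials, n)
  cells <- .recog_cells(n, params$P_exp, params$rho, params$M_conf,
                        params$d_prime, params$criterion)
  ll <- 0
  for (stim in c("S1", "S2")) {
    sel <- trials$stimulus == stim
    if (!any(sel)) next
    m <- cells[[tolower(stim)]]
    idx <- cbind(ifelse(trials$response[sel] == "S1", 1L, 2L),
                 as.integer(trials$confidence[sel]))
    ll <- ll + sum(log(pmax(m[idx], 1e-300)))
  }
  ll
}
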