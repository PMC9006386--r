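# Restricted stochastic detection and retrieval model (SDRM).
#
# Strength and experience are standard bivariate normal with correlation
# rho; the strength mean is fixed at 0 and recall requires strength above a
# free criterion C_M. Confidence comes from comparing experience against
# n-1 free, ordered criteria. Criterion variability (sigma_M, sigma_C) is
# fixed at 0 here -- the identifiable single-condition form. The
# two-condition variant shares criteria up to a scale factor beta.

#' SDRM parameter set (restricted: no criterion variability)
#'
#' @param C_M Recall criterion on the strength distribution.
#' @param rho Strength-experience correlation, |rho| < 1.
#' @param criteria Strictly increasing vector of n-1 confidence criteria on
#'   the experience distribution.
#' @return Object of class `bim_sdrm_params`.
#' @export
sdrm_params <- function(C_M, rho, criteria) {
  if (abs(rho) >= 1) .stopf("|rho| must be < 1")
  if (length(criteria) < 1L || any(diff(criteria) <= 0))
    .stopf("criteria must be strictly increasing")
  structure(list(C_M = C_M, rho = rho, criteria = as.numeric(criteria),
                 sigma_M = 0, sigma_C = 0),
            class = "bim_sdrm_params")
}

# Cell probabilities: rows outcome 0/1, columns bins 1..n.
.sdrm_cells <- function(C_M, rho, criteria) {
  n <- length(criteria) + 1L
  edges <- c(-Inf, criteria, Inf)
  zlo <- edges[-(n + 1L)]
  zhi <- edges[-1L]
  p1 <- .strip_upper(zlo, zhi, C_M, rho)
  ptot <- pnorm(zhi) - pnorm(zlo)
  rbind(`0` = pmax(ptot - p1, 0), `1` = p1)
}

#' SDRM log-likelihood
#'
#' @param trials Discrete-scale recall trial table.
#' @param params A [sdrm_params()] object.
#' @return Scalar log-likelihood.
#' @export
sdrm_loglik <- function(trials, params) {
  stopifnot(inherits(params, "bim_sdrm_params"))
  n <- length(params$criteria) + 1L
  .check_discrete(trials, n)
  cells <- .sdrm_cells(params$C_M, params$rho, params$criteria)
  idx <- cbind(trials$outcome + 1L, as.integer(trials$confidence))
  sum(log(pmax(cells[idx], 1e-300)))
}

# Ordered criteria via first-criterion + log-increments.
.sdrm_unpack_criteria <- function(th_c) {
  c1 <- th_c[1]
  if (length(th_c) == 1L) return(c1)
  cumsum(c(c1, exp(th_c[-1])))
}

.sdrm_theta0 <- function(counts, n) {
  N <- sum(counts)
  cum <- cumsum(colSums(counts))[seq_len(n - 1L)] / N
  cum <- .clamp(cum, 1 / (2 * N), 1 - 1 / (2 * N))
  crit0 <- qnorm(cummax(cum + cumsum(rep(1e-8, n - 1L))))
  incs <- pmax(diff(crit0), 0.05)
  acc <- .clamp(sum(counts[2, ]) / N, 1 / (2 * N), 1 - 1 / (2 * N))
  list(C_M = -qnorm(acc), crit = c(crit0[1], log(incs)))
}

#' Fit the restricted SDRM
#'
#' Maximum likelihood over (C_M, rho, n-1 ordered criteria); ordering is
#' enforced by a first-criterion plus log-increment parameterisation.
#'
#' @param trials Discrete-scale recall trial table.
#' @param n Number of scale points (default: from the trial table).
#' @param options As in [fit_bim()]; default 5 starts.
#' @return A `bim_fit` whose estimates contain `C_M`, `rho`, `criteria`,
#'   and the criterion summaries `M_criteria`, `SD_criteria`.
#' @export
sdrm_fit <- function(trials, n = NULL, options = list()) {
  if (is.null(n)) n <- .parse_scale(trials$scale[1])$n
  .check_discrete(trials, n)
  opt <- .fit_defaults(modifyList(list(n_starts = 5L), options))
  counts <- matrix(0, 2L, n)
  idx <- cbind(trials$outcome + 1L, as.integer(trials$confidence))
  for (i in seq_len(nrow(idx))) counts[idx[i, 1], idx[i, 2]] <-
      counts[idx[i, 1], idx[i, 2]] + 1

  t0 <- .sdrm_theta0(counts, n)
  rho0 <- .safe_cor(trials$confidence, trials$outcome)
  rho0 <- .clamp(if (is.na(rho0)) 0 else rho0, -0.9, 0.9)
  theta0 <- c(t0$C_M, atanh(rho0), t0$crit)
  lower <- c(-5, -.ATANH_BOUND, -6, rep(-7, n - 2L))
  upper <- c(5, .ATANH_BOUND, 6, rep(2, n - 2L))

  obj <- function(th) {
    crit <- .sdrm_unpack_criteria(th[-(1:2)])
    cells <- .sdrm_cells(th[1], tanh(th[2]), crit)
    list(value = -sum(counts * log(pmax(cells, 1e-300))), grad = NULL)
  }
  starts <- .make_starts(theta0, opt$n_starts, 0.5, opt$start_seed, lower, upper)
  best <- .mle_multistart(obj, starts, lower, upper, opt$maxit, opt$factr,
                          has_grad = FALSE)
  crit <- .sdrm_unpack_criteria(best$par[-(1:2)])
  est <- list(C_M = best$par[1], rho = tanh(best$par[2]), criteria = crit,
              M_criteria = mean(crit), SD_criteria = stats::sd(crit))
  .new_fit(est, -best$value, nrow(trials), best$n_converged, opt$n_starts,
           character(0), "sdrm", sprintf("discrete:%d", n))
}

#' Fit the two-condition SDRM with rescaled criteria
#'
#' Joint maximum likelihood over two conditions: condition B's confidence
#' criteria are the condition A criteria scaled by a free beta > 0;
#' C_M and rho are free per condition.
#'
#' @param trials_a,trials_b Discrete-scale recall trial tables for the two
#'   conditions (same n).
#' @param n Number of scale points (default: from condition A's table).
#' @param options As in [fit_bim()].
#' @return A `bim_fit` with per-condition estimates and `beta`.
#' @export
sdrm2_fit <- function(trials_a, trials_b, n = NULL, options = list()) {
  if (is.null(trials_b) || !is.data.frame(trials_b) || nrow(trials_b) < 1L)
    .stopf("sdrm2_fit needs two non-empty conditions")
  if (is.null(n)) n <- .parse_scale(trials_a$scale[1])$n
  .check_discrete(trials_a, n)
  .check_discrete(trials_b, n)
  opt <- .fit_defaults(modifyList(list(n_starts = 4L), options))

  cts <- lapply(list(trials_a, trials_b), function(tt) {
    m <- matrix(0, 2L, n)
    idx <- cbind(tt$outcome + 1L, as.integer(tt$confidence))
    for (i in seq_len(nrow(idx))) m[idx[i, 1], idx[i, 2]] <-
        m[idx[i, 1], idx[i, 2]] + 1
    m
  })

  t0a <- .sdrm_theta0(cts[[1]], n)
  t0b <- .sdrm_theta0(cts[[2]], n)
  r0 <- vapply(list(trials_a, trials_b), function(tt) {
    r <- .safe_cor(tt$confidence, tt$outcome)
    .clamp(if (is.na(r)) 0 else r, -0.9, 0.9)
  }, numeric(1))
  theta0 <- c(t0a$C_M, t0b$C_M, atanh(r0), t0a$crit, 0)
  k <- n - 1L
  lower <- c(-5, -5, rep(-.ATANH_BOUND, 2), -6, rep(-7, n - 2L), -3)
  upper <- c(5, 5, rep(.ATANH_BOUND, 2), 6, rep(2, n - 2L), 3)

  obj <- function(th) {
    crit_a <- .sdrm_unpack_criteria(th[5:(4 + k)])
    beta <- exp(th[5 + k])
    crit_b <- beta * crit_a
    if (any(diff(crit_b) <= 0)) return(list(value = 1e10, grad = NULL))
    nll <- -sum(cts[[1]] * log(pmax(.sdrm_cells(th[1], tanh(th[3]), crit_a), 1e-300))) -
      sum(cts[[2]] * log(pmax(.sdrm_cells(th[2], tanh(th[4]), crit_b), 1e-300)))
    list(value = nll, grad = NULL)
  }
  starts <- .make_starts(theta0, opt$n_starts, 0.4, opt$start_seed, lower, upper)
  best <- .mle_multistart(obj, starts, lower, upper, opt$maxit, opt$factr,
                          has_grad = FALSE)
  crit_a <- .sdrm_unpack_criteria(best$par[5:(4 + k)])
  beta <- exp(best$par[5 + k])
  est <- list(C_M_a = best$par[1], C_M_b = best$par[2],
              rho_a = tanh(best$par[3]), rho_b = tanh(best$par[4]),
              criteria_a = crit_a, criteria_b = beta * crit_a, beta = beta)
  .new_fit(est, -best$value, nrow(trials_a) + nrow(trials_b),
           best$n_converged, opt$n_starts, character(0), "sdrm2",
           sprintf("discrete:%d", n))
}
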