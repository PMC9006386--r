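# Maximum-likelihood fitting.
#
# Optimisation runs on transformed coordinates -- logit for P_exp and the
# M_conf cells, atanh for rho, identity (bounded [-5, 5]) for mu_m -- with
# a bounded quasi-Newton optimiser and multiple restarts jittered around
# method-of-moments initial values. Continuous-confidence objectives carry
# analytic gradients from the quadrature engine; discrete objectives are
# cheap and use finite differences.

.LOGIT_BOUND <- 7
.ATANH_BOUND <- 2.9   # |rho| <= 0.9939

.fit_defaults <- function(options) {
  modifyList(list(n_starts = 10L, start_seed = 1L, jitter_sd = 1,
                  maxit = 500L, factr = 1e7, init = NULL,
                  drop_degenerate = TRUE),
             options %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Jittered start list around theta0 (first start is theta0 itself).
.make_starts <- function(theta0, n_starts, jitter_sd, seed, lower, upper) {
  .with_seed(seed, function() {
    starts <- vector("list", n_starts)
    starts[[1]] <- theta0
    if (n_starts > 1L) {
      for (i in 2:n_starts) {
        th <- theta0 + rnorm(length(theta0), 0, jitter_sd)
        starts[[i]] <- .clamp(th, lower + 1e-6, upper - 1e-6)
      }
    }
    starts
  })
}

# Multistart bounded quasi-Newton on negative log-likelihood.
# obj(theta) must return list(value = negloglik, grad = numeric or NULL).
.mle_multistart <- function(obj, starts, lower, upper, maxit, factr,
                            has_grad = TRUE) {
  cache <- new.env(parent = emptyenv())
  fn <- function(th) {
    r <- obj(th)
    cache$th <- th; cache$grad <- r$grad
    if (!is.finite(r$value)) return(1e10)
    r$value
  }
  gr <- if (has_grad) {
    function(th) {
      if (!is.null(cache$th) && isTRUE(all.equal(th, cache$th, tolerance = 0)))
        return(cache$grad)
      obj(th)$grad
    }
  } else NULL
  best <- NULL
  n_ok <- 0L
  for (th0 in starts) {
    res <- tryCatch(
      optim(th0, fn = fn, gr = gr, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0L) n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) .stopf("all optimisation starts failed")
  best$n_converged <- n_ok
  best
}

.new_fit <- function(estimates, loglik, n_trials, converged, starts,
                     dropped_params, task, scale, extra = list()) {
  structure(c(list(estimates = estimates, loglik = loglik,
                   n_trials = n_trials, converged = converged,
                   starts = starts, dropped_params = dropped_params,
                   task = task, scale = .scale_string(scale)), extra),
            class = "bim_fit")
}

#' @export
print.bim_fit <- function(x, ...) {
  cat(sprintf("model fit: %s task, %s scale, %d trials\n",
              x$task, x$scale, x$n_trials))
  est <- unlist(x$estimates)
  cat(paste(sprintf("  %-10s %8.4f", names(est), est), collapse = "\n"), "\n")
  cat(sprintf("  log-likelihood %.3f (%d/%d starts converged)\n",
              x$loglik, x$converged, x$starts))
  if (length(x$dropped_params))
    cat("  dropped:", paste(x$dropped_params, collapse = ", "), "\n")
  invisible(x)
}

# Numeric Jacobian of a cheap vector-valued map (central differences).
.num_jacobian <- function(f, theta, eps = 1e-6) {
  f0 <- f(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    tp <- tm <- theta
    tp[j] <- tp[j] + eps
    tm[j] <- tm[j] - eps
    J[, j] <- (f(tp) - f(tm)) / (2 * eps)
  }
  J
}

# ---- recall -------------------------------------------------------------

.fit_recall <- function(trials, scale, opt) {
  y <- trials$outcome
  conf <- trials$confidence
  n <- length(y)
  degenerate <- length(unique(y)) == 1L && isTRUE(opt$drop_degenerate)
  dropped <- if (degenerate) c("mu_m", "rho") else character(0)
  sc <- .parse_scale(scale)

  m0 <- if (sc$type == "continuous") mean(conf) else (mean(conf) - 0.5) / sc$n
  m0 <- .clamp(m0, 0.02, 0.98)
  acc <- .clamp(mean(y), 1 / (2 * n), 1 - 1 / (2 * n))
  rho0 <- if (degenerate) 0 else .safe_cor(conf, y)
  rho0 <- .clamp(if (is.na(rho0)) 0 else rho0, -0.9, 0.9)

  if (degenerate) {
    theta0 <- c(qlogis(0.5), qlogis(m0))
    lower <- rep(-.LOGIT_BOUND, 2); upper <- rep(.LOGIT_BOUND, 2)
    unpack <- function(th) list(P_exp = plogis(th[1]), M_conf = plogis(th[2]),
                                mu_m = NA_real_, rho = NA_real_)
    natfun <- function(th) as.numeric(.nat_recall(0, 0, plogis(th[1]),
                                                  plogis(th[2]),
                                                  drop_performance = TRUE))
    nat_dim <- c(1L, 4L)
  } else {
    theta0 <- c(qlogis(0.5), qlogis(m0), qnorm(acc), atanh(rho0))
    lower <- c(-.LOGIT_BOUND, -.LOGIT_BOUND, -5, -.ATANH_BOUND)
    upper <- c(.LOGIT_BOUND, .LOGIT_BOUND, 5, .ATANH_BOUND)
    unpack <- function(th) list(P_exp = plogis(th[1]), M_conf = plogis(th[2]),
                                mu_m = th[3], rho = tanh(th[4]))
    natfun <- function(th) as.numeric(.nat_recall(th[3], tanh(th[4]),
                                                  plogis(th[1]), plogis(th[2])))
    nat_dim <- c(2L, 4L)
  }
  if (!is.null(opt$init)) {
    ini <- opt$init
    theta0 <- if (degenerate) {
      c(qlogis(.clamp(ini$P_exp, 1e-3, 1 - 1e-3)),
        qlogis(.clamp(ini$M_conf, 1e-3, 1 - 1e-3)))
    } else {
      c(qlogis(.clamp(ini$P_exp, 1e-3, 1 - 1e-3)),
        qlogis(.clamp(ini$M_conf, 1e-3, 1 - 1e-3)),
        .clamp(ini$mu_m, -5, 5),
        atanh(.clamp(ini$rho, -0.993, 0.993)))
    }
  }

  if (sc$type == "continuous") {
    grp <- if (degenerate) rep(0L, n) else y
    obj <- function(th) {
      nat <- matrix(natfun(th), nat_dim[1], nat_dim[2])
      res <- .cont_loglik_nat(conf, grp, nat, sigma = 0.025, want_grad = TRUE)
      J <- .num_jacobian(natfun, th)
      list(value = -res$loglik, grad = -as.numeric(crossprod(J, res$grad)))
    }
    has_grad <- TRUE
  } else {
    counts <- matrix(0, 2L, sc$n)
    idx <- cbind(y + 1L, as.integer(conf))
    for (i in seq_len(nrow(idx))) counts[idx[i, 1], idx[i, 2]] <-
        counts[idx[i, 1], idx[i, 2]] + 1
    obj <- function(th) {
      p <- unpack(th)
      cells <- if (degenerate) {
        edges <- .z_edges_up(sc$n, p$P_exp, p$M_conf)
        pr <- pnorm(edges[-1]) - pnorm(edges[-(sc$n + 1L)])
        rbind(pr, pr)  # outcome rows identical; only observed row counts
      } else {
        .recall_cells(sc$n, p$mu_m, p$rho, p$P_exp, p$M_conf)
      }
      list(value = -sum(counts * log(pmax(cells, 1e-300))), grad = NULL)
    }
    has_grad <- FALSE
  }

  starts <- .make_starts(theta0, opt$n_starts, opt$jitter_sd, opt$start_seed,
                         lower, upper)
  best <- .mle_multistart(obj, starts, lower, upper, opt$maxit, opt$factr,
                          has_grad = has_grad)
  est <- unpack(best$par)
  .new_fit(est, -best$value, n, best$n_converged, opt$n_starts, dropped,
           "recall", scale)
}

# Degenerate discrete recall: the bin-probability row used above ignores
# the outcome dimension, matching the continuous path's P(cell|z) = 1.

# ---- recognition --------------------------------------------------------

.sdt_plugin <- function(trials) {
  s2 <- trials$stimulus == "S2"
  n2 <- sum(s2); n1 <- sum(!s2)
  if (n1 == 0L || n2 == 0L)
    .stopf("recognition fits need both stimulus types for the SDT plug-in")
  HR <- sum(trials$response[s2] == "S2") / n2
  FAR <- sum(trials$response[!s2] == "S2") / n1
  if (HR == 0) HR <- 1 / (2 * n2)
  if (HR == 1) HR <- 1 - 1 / (2 * n2)
  if (FAR == 0) FAR <- 1 / (2 * n1)
  if (FAR == 1) FAR <- 1 - 1 / (2 * n1)
  sdt_from_rates(HR, FAR)
}

.fit_recognition <- function(trials, scale, opt) {
  sc <- .parse_scale(scale)
  sdt <- .sdt_plugin(trials)
  cellidx <- .recog_cell_index(trials)
  conf <- trials$confidence
  n <- nrow(trials)

  m0 <- vapply(1:4, function(k) {
    v <- conf[cellidx == k]
    if (!length(v)) return(0.5)
    m <- if (sc$type == "continuous") mean(v) else (mean(v) - 0.5) / sc$n
    .clamp(m, 0.02, 0.98)
  }, numeric(1))

  theta0 <- c(qlogis(0.5), atanh(0), qlogis(m0))
  if (!is.null(opt$init)) {
    ini <- opt$init
    theta0 <- c(qlogis(.clamp(ini$P_exp, 1e-3, 1 - 1e-3)),
                atanh(.clamp(ini$rho, -0.993, 0.993)),
                qlogis(.clamp(unlist(ini$M_conf)[.M_CONF_CELLS], 1e-3, 1 - 1e-3)))
  }
  lower <- c(-.LOGIT_BOUND, -.ATANH_BOUND, rep(-.LOGIT_BOUND, 4))
  upper <- -lower

  unpack <- function(th) list(P_exp = plogis(th[1]), rho = tanh(th[2]),
                              M_conf = stats::setNames(plogis(th[3:6]),
                                                       .M_CONF_CELLS))
  natfun <- function(th) {
    p <- unpack(th)
    as.numeric(.nat_recognition(p$P_exp, p$rho, as.list(p$M_conf),
                                sdt$d_prime, sdt$criterion))
  }

  if (sc$type == "continuous") {
    grp <- cellidx - 1L
    obj <- function(th) {
      nat <- matrix(natfun(th), 4L, 4L)
      res <- .cont_loglik_nat(conf, grp, nat, sigma = 0.025, want_grad = TRUE)
      J <- .num_jacobian(natfun, th)
      list(value = -res$loglik, grad = -as.numeric(crossprod(J, res$grad)))
    }
    has_grad <- TRUE
  } else {
    counts <- list(s1 = matrix(0, 2L, sc$n), s2 = matrix(0, 2L, sc$n))
    for (i in seq_len(n)) {
      stim <- tolower(trials$stimulus[i])
      r <- if (trials$response[i] == "S1") 1L else 2L
      counts[[stim]][r, as.integer(conf[i])] <-
        counts[[stim]][r, as.integer(conf[i])] + 1
    }
    obj <- function(th) {
      p <- unpack(th)
      cells <- .recog_cells(sc$n, p$P_exp, p$rho, as.list(p$M_conf),
                            sdt$d_prime, sdt$criterion)
      nll <- -sum(counts$s1 * log(pmax(cells$s1, 1e-300))) -
        sum(counts$s2 * log(pmax(cells$s2, 1e-300)))
      list(value = nll, grad = NULL)
    }
    has_grad <- FALSE
  }

  starts <- .make_starts(theta0, opt$n_starts, opt$jitter_sd, opt$start_seed,
                         lower, upper)
  best <- .mle_multistart(obj, starts, lower, upper, opt$maxit, opt$factr,
                          has_grad = has_grad)
  est <- unpack(best$par)
  est$d_prime <- sdt$d_prime
  est$criterion <- sdt$criterion
  empty <- .M_CONF_CELLS[tabulate(cellidx, 4L) == 0L]
  .new_fit(est, -best$value, n, best$n_converged, opt$n_starts, character(0),
           "recognition", scale,
           extra = list(rho_unreliable = TRUE, empty_cells = empty))
}

#' Fit the Bayesian metamemory model by maximum likelihood
#'
#' Dispatches on task and confidence scale; recall fits estimate
#' (`P_exp`, `M_conf`, `mu_m`, `rho`), recognition fits plug in type I
#' d'/C from the observed hit/false-alarm rates (0/1 rates replaced by
#' 1/(2N)) and estimate (`P_exp`, `rho`, four `M_conf` cells). When every
#' recall outcome is identical, `mu_m` and `rho` are unidentifiable and are
#' dropped (reported in `dropped_params`); the confidence-only model is
#' fitted instead.
#'
#' Fits are deterministic: multistart jitters derive from
#' `options$start_seed`.
#'
#' @param trials A trial table.
#' @param task `"recall"` or `"recognition"`; defaults to the table's task.
#' @param scale Scale descriptor; defaults to the table's scale column.
#' @param options List: `n_starts` (default 10), `start_seed` (default 1),
#'   `jitter_sd` (1), `maxit` (500), `factr` (1e7), `init` (optional named
#'   list of warm-start parameter values).
#' @return Object of class `bim_fit` with `estimates`, `loglik`,
#'   `n_trials`, `converged` (number of converged starts), `starts`,
#'   `dropped_params`; recognition fits also carry `rho_unreliable = TRUE`
#'   (rho is poorly recoverable in recognition) and `empty_cells`.
#' @export
fit_bim <- function(trials, task = NULL, scale = NULL, options = list()) {
  if (nrow(trials) < 1L) .stopf("need at least one trial")
  task <- task %||% trials$task[1]
  scale <- scale %||% trials$scale[1]
  opt <- .fit_defaults(options)
  switch(match.arg(task, c("recall", "recognition")),
         recall = .fit_recall(trials, scale, opt),
         recognition = .fit_recognition(trials, scale, opt))
}

#' Parameter-free confidence transfer across conditions
#'
#' Given a continuous-scale recall fit in a source condition, estimates the
#' standardised experience deviation on each trial by inverting the
#' noiseless predicted-confidence transform at the reported confidence
#' (clamped to 0.001..0.999), then recomputes predicted confidence under
#' a different prior belief, keeping the source experience weight. The
#' target belief is supplied as a believed proportion correct and mapped to
#' a belief mean via the probit.
#'
#' @param fit_source A `bim_fit` from continuous recall data.
#' @param trials_source The trial table the fit was obtained from.
#' @param prior_belief_target Believed proportion recalled in the target
#'   condition, strictly inside (0, 1).
#' @return Numeric vector of predicted confidences, one per source trial.
#' @export
transfer_predict_confidence <- function(fit_source, trials_source,
                                        prior_belief_target) {
  stopifnot(inherits(fit_source, "bim_fit"))
  if (fit_source$task != "recall" || fit_source$scale != "continuous")
    .stopf("transfer prediction needs a continuous-scale recall fit")
  if (!.is_prob(prior_belief_target))
    .stopf("prior_belief_target must lie strictly inside (0, 1)")
  P_exp <- fit_source$estimates$P_exp
  M_conf <- fit_source$estimates$M_conf
  P_b <- 1 - P_exp
  a <- canonical_cell_shift(M_conf, P_exp)
  b <- .canonical_slope(P_exp)
  r <- .clamp(trials_source$confidence, 0.001, 0.999)
  z_hat <- (qnorm(r) - a) / b
  mu_b_t <- qnorm(prior_belief_target)
  pnorm((z_hat * P_exp + mu_b_t * P_b) / sqrt(P_b))
}

#' Source-implied prior belief of a recall fit
#'
#' The believed proportion correct implied by a fitted (P_exp, M_conf)
#' pair under the convention that experience deviations are centred
#' (mu_e = 0), so that the belief mean absorbs the non-identifiable
#' location. Feeding this into [transfer_predict_confidence()] reproduces
#' the source confidences up to clamping.
#'
#' @param fit A `bim_fit` for recall data.
#' @return Probability.
#' @export
implied_prior_belief <- function(fit) {
  P_exp <- fit$estimates$P_exp
  a <- canonical_cell_shift(fit$estimates$M_conf, P_exp)
  pnorm(a / sqrt(1 - P_exp))
}
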