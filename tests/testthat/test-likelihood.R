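test_that("continuous recall likelihood factorises when rho = 0", {
  set.seed(17)
  tt <- simulate_recall(recall_params(0.3, 0, P_exp = 0.6, M_conf = 0.55),
                        sim_config(40, "continuous", 8))
  p <- recall_params(0.3, 0, P_exp = 0.6, M_conf = 0.55)
  ll <- loglik_recall_continuous(tt, p)
  # outcome part x confidence-only part
  ll_out <- sum(dbinom(tt$outcome, 1, pnorm(0.3), log = TRUE))
  nat <- bimeta:::.nat_recall(0, 0, 0.6, 0.55, drop_performance = TRUE)
  ll_conf <- bimeta:::.cont_loglik_nat(tt$confidence,
                                       rep(0L, nrow(tt)), nat)$loglik
  expect_equal(ll, ll_out + ll_conf, tolerance = 1e-8)
})

test_that("continuous likelihood agrees with a simulation oracle", {
  # binned (confidence x outcome) masses, including the censored points,
  # against 10^6 simulated trials
  set.seed(23)
  cases <- list(c(0.5, 0.5, 0.7, 0.6), c(-1, -0.6, 0.2, 0.3),
                c(1.5, 0.8, 0.9, 0.85), c(0.3, 0.4, 0.12, 0.5))
  n <- 1e6
  for (cs in cases) {
    mu_m <- cs[1]; rho <- cs[2]; P <- cs[3]; M <- cs[4]
    p <- recall_params(mu_m, rho, P_exp = P, M_conf = M)
    tt <- simulate_recall(p, sim_config(n, "continuous", 77))
    edges <- seq(0, 1, by = 0.125)
    for (y in 0:1) {
      sel <- tt$outcome == y
      for (side in c(0, 1)) {
        emp <- mean(sel & tt$confidence == side)
        thr <- cont_L1(side, y, mu_m, rho, P, M)
        se <- sqrt(max(thr * (1 - thr), 1e-12) / n)
        expect_lt(abs(emp - thr), 3.8 * se + 5e-6)
      }
      for (i in 1:8) {
        lo <- edges[i]; hi <- edges[i + 1]
        emp <- mean(sel & tt$confidence > lo & tt$confidence < hi)
        rg <- seq(lo + 1e-9, hi - 1e-9, length.out = 101)
        vals <- cont_L1(rg, rep(y, 101), mu_m, rho, P, M)
        thr <- sum((vals[-1] + vals[-101]) / 2 * diff(rg))
        se <- sqrt(max(thr * (1 - thr), 1e-12) / n)
        expect_lt(abs(emp - thr), 3.8 * se + 5e-6)
      }
    }
  }
})

test_that("recognition continuous likelihood: cell masses and MC oracle", {
  P <- 0.65; rho <- 0.5; d <- 1.2; C <- 0.3
  M4 <- c(s1_r1 = 0.7, s1_r2 = 0.35, s2_r1 = 0.3, s2_r2 = 0.75)
  nat <- bimeta:::.nat_recognition(P, rho, as.list(M4), d, C)
  L1g <- function(r, g) vapply(seq_along(r), function(i)
    exp(bimeta:::.cont_loglik_nat(r[i], g[i], nat)$loglik), numeric(1))
  # per-stimulus total mass (over both responses) is 1
  # r-grid graded toward 0/1 where the density of predicted confidence can
  # diverge (integrably) for probit slopes above 1
  rgrid <- sort(unique(c(exp(seq(log(1e-8), log(0.01), length.out = 80)),
                         seq(0.01, 0.99, by = 5e-4),
                         1 - exp(seq(log(1e-8), log(0.01), length.out = 80)))))
  nr <- length(rgrid)
  for (stim in 0:1) {
    tot <- 0
    for (g in (2 * stim):(2 * stim + 1)) {
      vals <- L1g(rgrid, rep(g, nr))
      tot <- tot + sum((vals[-1] + vals[-nr]) / 2 * diff(rgrid)) +
        L1g(0, g) + L1g(1, g)
    }
    expect_equal(tot, 1, tolerance = 2e-5)
  }
  # MC oracle on cell masses over coarse bins
  p2 <- recognition_params(d, C, rho, P_exp = P, M_conf = M4)
  n_per <- 5e5
  t2 <- simulate_recognition(p2, sim_config(n_per, "continuous", 5))
  grp <- bimeta:::.recog_cell_index(t2) - 1L
  edges <- seq(0, 1, by = 0.25)
  for (g in 0:3) {
    sel <- grp == g
    stim_n <- n_per  # trials per stimulus
    for (i in 1:4) {
      lo <- edges[i]; hi <- edges[i + 1]
      emp <- sum(sel & t2$confidence > lo & t2$confidence < hi) / stim_n
      rg <- seq(lo + 1e-9, hi - 1e-9, length.out = 101)
      vals <- L1g(rg, rep(g, 101))
      thr <- sum((vals[-1] + vals[-101]) / 2 * diff(rg))
      se <- sqrt(max(thr * (1 - thr), 1e-12) / stim_n)
      expect_lt(abs(emp - thr), 3.8 * se + 5e-6)
    }
  }
})

test_that("discrete cell tables normalise and match quadrature oracles", {
  set.seed(3)
  for (k in 1:20) {
    pars <- rand_recall_par()
    cells <- bimeta:::.recall_cells(7, pars$mu_m, pars$rho, pars$P_exp,
                                    pars$M_conf)
    expect_equal(sum(cells), 1, tolerance = 1e-10)
    if (k <= 5) {
      # brute-force rectangle check for one interior cell
      edges <- bimeta:::.z_edges_up(7, pars$P_exp, pars$M_conf)
      bf <- integrate(function(z) dnorm(z) *
                        pnorm((pars$rho * z + pars$mu_m) / sqrt(1 - pars$rho^2)),
                      edges[4], edges[5], rel.tol = 1e-12)$value
      expect_equal(unname(cells[2, 4]), bf, tolerance = 1e-6)
    }
  }
  # rho = 0 independence
  cells0 <- bimeta:::.recall_cells(5, 0.7, 0, 0.4, 0.6)
  expect_equal(cells0[2, ] / colSums(cells0), rep(pnorm(0.7), 5),
               tolerance = 1e-9)
  # recognition tables normalise per stimulus; the fully symmetric case is
  # equiprobable across all (response x bin) cells when the probit slope on
  # the experience deviation is 1, i.e. P_exp = (sqrt(5) - 1) / 2
  P_unif <- (sqrt(5) - 1) / 2
  cl <- bimeta:::.recog_cells(4, P_unif, 0, list(s1_r1 = 0.5, s1_r2 = 0.5,
                                                 s2_r1 = 0.5, s2_r2 = 0.5), 0, 0)
  expect_equal(sum(cl$s1), 1, tolerance = 1e-10)
  expect_equal(sum(cl$s2), 1, tolerance = 1e-10)
  expect_equal(as.numeric(cl$s1), rep(1 / 8, 8), tolerance = 1e-9)
})

test_that("analytic gradients match finite differences", {
  set.seed(12)
  tt <- simulate_recall(recall_params(0.4, 0.5, P_exp = 0.6, M_conf = 0.55),
                        sim_config(80, "continuous", 11))
  natfun <- function(th) as.numeric(
    bimeta:::.nat_recall(th[3], tanh(th[4]), plogis(th[1]), plogis(th[2])))
  val <- function(th) {
    nat <- matrix(natfun(th), 2, 4)
    bimeta:::.cont_loglik_nat(tt$confidence, tt$outcome, nat)$loglik
  }
  for (k in 1:3) {
    th <- c(rnorm(2, 0, 0.7), rnorm(1, 0, 0.5), rnorm(1, 0, 0.5))
    nat <- matrix(natfun(th), 2, 4)
    r <- bimeta:::.cont_loglik_nat(tt$confidence, tt$outcome, nat,
                                   want_grad = TRUE)
    J <- bimeta:::.num_jacobian(natfun, th)
    g <- as.numeric(crossprod(J, r$grad))
    gn <- vapply(1:4, function(j) {
      e <- rep(0, 4); e[j] <- 1e-5
      (val(th + e) - val(th - e)) / 2e-5
    }, numeric(1))
    expect_equal(g, gn, tolerance = 1e-4)
  }
})

test_that("log-likelihood peaks near the generating parameters", {
  pars <- list(mu_m = 0.5, rho = 0.4, P_exp = 0.65, M_conf = 0.55)
  p <- recall_params(pars$mu_m, pars$rho, P_exp = pars$P_exp,
                     M_conf = pars$M_conf)
  tt <- simulate_recall(p, sim_config(1e4, "continuous", 19))
  ll0 <- loglik_recall_continuous(tt, p)
  perturb <- function(which, delta) {
    q <- pars; q[[which]] <- q[[which]] + delta
    q$P_exp <- min(max(q$P_exp, 0.01), 0.99)
    q$M_conf <- min(max(q$M_conf, 0.01), 0.99)
    q$rho <- min(max(q$rho, -0.95), 0.95)
    loglik_recall_continuous(tt, recall_params(q$mu_m, q$rho, P_exp = q$P_exp,
                                               M_conf = q$M_conf))
  }
  for (w in names(pars)) {
    expect_gt(ll0, perturb(w, 0.5) + 1)
    expect_gt(ll0, perturb(w, -0.5) + 1)
  }
})

test_that("fitting recovers parameters and is deterministic", {
  p <- recall_params(0.4, 0.5, P_exp = 0.6, M_conf = 0.55)
  tt <- simulate_recall(p, sim_config(500, "continuous", 4))
  f1 <- fit_bim(tt)
  f2 <- fit_bim(tt)
  expect_identical(f1$estimates, f2$estimates)
  expect_lt(abs(f1$estimates$P_exp - 0.6), 0.1)
  expect_lt(abs(f1$estimates$M_conf - 0.55), 0.05)
  expect_lt(abs(f1$estimates$mu_m - 0.4), 0.2)
  expect_lt(abs(f1$estimates$rho - 0.5), 0.15)
  # discrete fit on the same generative process
  td <- simulate_recall(p, sim_config(500, "discrete:7", 4))
  fd <- fit_bim(td)
  expect_lt(abs(fd$estimates$P_exp - 0.6), 0.12)
  expect_lt(abs(fd$estimates$mu_m - 0.4), 0.2)
})

test_that("all-identical outcomes drop mu_m and rho", {
  tt <- make_recall_trials(rep(1, 10), c(0.7, 0.8, 0.75, 0.9, 0.66,
                                         0.85, 0.72, 0.8, 0.77, 0.95))
  f <- fit_bim(tt)
  expect_setequal(f$dropped_params, c("mu_m", "rho"))
  expect_true(is.na(f$estimates$mu_m))
  expect_lt(abs(f$estimates$M_conf - mean(tt$confidence)), 0.1)
  # with drop_degenerate = FALSE the parameters stay in the fit
  f2 <- fit_bim(tt, options = list(drop_degenerate = FALSE))
  expect_length(f2$dropped_params, 0)
  expect_false(is.na(f2$estimates$mu_m))
})

test_that("recognition fit plugs in SDT and flags rho as unreliable", {
  p <- recognition_params(1.2, 0.3, 0.5, P_exp = 0.65,
                          M_conf = c(0.7, 0.35, 0.3, 0.75))
  tt <- simulate_recognition(p, sim_config(300, "continuous", 6))
  f <- fit_bim(tt, options = list(n_starts = 4L))
  s2 <- tt$stimulus == "S2"
  HR <- mean(tt$response[s2] == "S2")
  FAR <- mean(tt$response[!s2] == "S2")
  expect_equal(f$estimates$d_prime, qnorm(HR) - qnorm(FAR), tolerance = 1e-10)
  expect_true(isTRUE(f$rho_unreliable))
  expect_lt(abs(f$estimates$P_exp - 0.65), 0.12)
  expect_lt(max(abs(f$estimates$M_conf - p$M_conf)), 0.12)
})

test_that("discrete and continuous fits of one process agree on P_exp", {
  # internal-coherence property on a 7-point scale
  set.seed(55)
  n_sets <- 18
  pc <- pd <- tr <- numeric(n_sets)
  for (k in seq_len(n_sets)) {
    pars <- rand_recall_par()
    p <- recall_params(pars$mu_m, pars$rho, P_exp = pars$P_exp,
                       M_conf = pars$M_conf)
    tc <- simulate_recall(p, sim_config(500, "continuous", 300 + k))
    td <- tc
    td$confidence <- as.numeric(bin_confidence(tc$confidence, 7))
    td$scale <- "discrete:7"
    pc[k] <- fit_bim(tc, options = list(n_starts = 4L))$estimates$P_exp
    pd[k] <- fit_bim(td, options = list(n_starts = 4L))$estimates$P_exp
    tr[k] <- pars$P_exp
  }
  expect_gt(cor(pc, pd), 0.8)
})

test_that("transfer prediction behaves like the inference it inverts", {
  p <- recall_params(0.2, 0.4, P_exp = 0.6, M_conf = 0.55)
  tt <- simulate_recall(p, sim_config(60, "continuous", 21))
  f <- fit_bim(tt)
  # identity transfer at the source's implied belief
  pred <- transfer_predict_confidence(f, tt, implied_prior_belief(f))
  expect_equal(pred, pmin(pmax(tt$confidence, 0.001), 0.999),
               tolerance = 1e-10)
  # strictly monotone in the target belief
  expect_true(all(transfer_predict_confidence(f, tt, 0.8) >
                    transfer_predict_confidence(f, tt, 0.3)))
  expect_error(transfer_predict_confidence(f, tt, 1), "inside")
  # two conditions sharing per-trial experience: the model-based transfer
  # predicts the target condition better than the raw source confidences
  set.seed(61)
  n <- 300
  z <- rnorm(n)
  P <- 0.6; b <- P / sqrt(1 - P)
  mu_b_a <- qnorm(0.45); mu_b_b <- qnorm(0.7)
  conf_a <- pmin(pmax(pnorm((z * P + mu_b_a * (1 - P)) / sqrt(1 - P)) +
                        rnorm(n, 0, 0.025), 0), 1)
  conf_b <- pmin(pmax(pnorm((z * P + mu_b_b * (1 - P)) / sqrt(1 - P)) +
                        rnorm(n, 0, 0.025), 0), 1)
  ta <- make_recall_trials(rbinom(n, 1, 0.5), conf_a)
  fa <- fit_bim(ta)
  pred_b <- transfer_predict_confidence(fa, ta, 0.7)
  expect_gt(cor(pred_b, conf_b), cor(conf_a, conf_b) - 0.02)
  expect_gt(cor(pred_b, conf_b), 0.9)
})
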