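# Continuous-confidence likelihood engine.
#
# Per trial the likelihood is
#   L(r, cell) = E_z[ P(cell | z) * g(r | p(z)) ],  z ~ N(0, 1),
# with p(z) = Phi(a + b z) the trial-level predicted confidence in the
# canonical (identifiable) parameterisation, P(cell | z) = Phi(c + d z) the
# probability of the observed outcome / response region given z, and g the
# N(0, sigma^2) reporting kernel censored at 0 and 1.
#
# Writing u = a + b z (so u ~ N(a, b^2) and p = Phi(u)), the integral is
# discretised onto nodes in predicted-confidence space:
#   L(r) = sum_j W_j * phi_sigma(r - t_j),  t_j = Phi(u_j),
# which the C++ kernel evaluates per trial with windowing. The reporting
# kernel has SD sigma = 0.025, far narrower than any fixed Hermite rule
# resolves, so node placement is adaptive in |b|:
#  * |b| small: p(z) is nearly degenerate; nodes resolve N(a, b^2) in
#    u-space and automatically oversample the kernel.
#  * |b| large: the density of p is wide (possibly edge-divergent); nodes
#    resolve the kernel on a uniform t-grid with geometric grading toward
#    0 and 1 where the density of p can blow up integrably.
# Censored masses at exactly 0/1 are integrated in u-space, where the
# integrand is bounded and Gaussian-tailed, so no truncation error arises.
#
# Gradients: each group's four natural parameters (a, b, c, d) enter node
# weights as dW_j/dnat = W_j * ratio_j; model-parameter gradients are
# assembled by chaining through a numerically differentiated map.

.CONT_B_SWITCH <- 0.2

# Mills ratio phi(x)/Phi(x), stable in the deep lower tail.
.mills <- function(x) exp(dnorm(x, log = TRUE) - pnorm(x, log.p = TRUE))

# Node-level ratio matrix for natural parameters (a, b, c, d).
.nat_ratios <- function(z, b, lam, d) {
  cbind((z - lam * d) / b,
        (z^2 - 1 - lam * d * z) / b,
        lam,
        lam * z)
}

# Mass of predicted confidence falling below/above the t-grid cut, plus
# gradient; relevant only for extreme |b| where the density of p piles up
# against 0/1 harder than the geometric grid reaches.
.tail_mass <- function(a, b, cc, d, u_from, u_to) {
  zero <- list(mass = 0, grad = c(0, 0, 0, 0))
  if (u_from >= u_to) return(zero)
  bb <- abs(b)
  edges <- .seg_edges(u_from, u_to, max(bb / 8, min(0.3, bb / 3)))
  q <- .composite_gl(edges, 5L)
  u <- q$x
  z <- (u - a) / b
  arg <- cc + d * z
  w <- q$w * dnorm(u, a, bb) * exp(pnorm(arg, log.p = TRUE))
  lam <- .mills(arg)
  R <- .nat_ratios(z, b, lam, d)
  list(mass = sum(w), grad = as.numeric(crossprod(R, w)))
}

# Build kernel nodes shared by all groups with common (a, b).
# Returns list(t, u, z, glw, base) where base = glw * density factor
# common to the block, to be multiplied by each group's Phi(c + d z).
.block_nodes <- function(a, b, sigma) {
  bb <- abs(b)
  if (bb < .CONT_B_SWITCH) {
    q <- .composite_gl(.seg_edges(a - 8.5 * bb, a + 8.5 * bb, 17 * bb / 48), 8L)
    u <- q$x
    t <- pnorm(u)
    base <- q$w * dnorm(u, a, bb)
    list(branch = "u", t = t, u = u, base = base,
         t_cut_low = 0, t_cut_high = 0)
  } else {
    slo <- pnorm(a - 8.5 * bb)
    shi <- pnorm(a + 8.5 * bb)
    h <- min(0.025, 0.05 * bb)
    lo_u <- max(0.0125, slo)
    hi_u <- min(0.9875, shi)
    t_lo <- tc_hi <- NULL
    # geometric grading toward 0
    if (slo < 0.0125) {
      bottom <- max(1e-32, slo * 1e-3)
      nseg <- ceiling(log(0.0125 / bottom) / log(8))
      t_lo <- 0.0125 * 8^(-(nseg:0))
    }
    # geometric grading toward 1 (tracked as distance tc = 1 - t)
    if (shi > 0.9875) {
      top <- max(1e-32, pnorm(a + 8.5 * bb, lower.tail = FALSE) * 1e-3)
      nseg <- ceiling(log(0.0125 / top) / log(8))
      tc_hi <- 0.0125 * 8^(-(nseg:0))   # ascending in tc = 1 - t
    }
    u_all <- t_all <- base_all <- NULL
    add <- function(tvals, uvals, w) {
      t_all <<- c(t_all, tvals); u_all <<- c(u_all, uvals); base_all <<- c(base_all, w)
    }
    if (!is.null(t_lo)) {
      q <- .composite_gl(t_lo, 5L)
      u <- qnorm(q$x)
      add(q$x, u, q$w * exp(dnorm(u, a, bb, log = TRUE) - dnorm(u, log = TRUE)))
    }
    if (hi_u > lo_u) {
      q <- .composite_gl(.seg_edges(lo_u, hi_u, h), 5L)
      u <- qnorm(q$x)
      add(q$x, u, q$w * exp(dnorm(u, a, bb, log = TRUE) - dnorm(u, log = TRUE)))
    }
    if (!is.null(tc_hi)) {
      q <- .composite_gl(tc_hi, 5L)             # nodes in tc-space, ascending tc
      u <- qnorm(q$x, lower.tail = FALSE)       # P(U > u) = tc
      # ascending t means descending tc
      ord <- order(1 - q$x)
      add((1 - q$x)[ord], u[ord],
          (q$w * exp(dnorm(u, a, bb, log = TRUE) - dnorm(u, log = TRUE)))[ord])
    }
    ord <- order(t_all)
    list(branch = "t", t = t_all[ord], u = u_all[ord], base = base_all[ord],
         t_cut_low = if (is.null(t_lo)) 0 else t_lo[1],
         t_cut_high = if (is.null(tc_hi)) 0 else tc_hi[1])
  }
}

# Evaluate log-likelihood (and optionally gradient w.r.t. the 4G natural
# parameters) for continuous-confidence data.
# conf: reported confidences; grp: 0-based group index per trial;
# nat: G x 4 matrix with columns (a, b, c, d).
.cont_loglik_nat <- function(conf, grp, nat, sigma = 0.025, want_grad = FALSE) {
  G <- nrow(nat)
  t_nodes <- w_nodes <- ratio_mats <- vector("list", G)
  L0 <- L1 <- Mlow <- Mhigh <- numeric(G)
  G0 <- G1 <- Glow <- Ghigh <- matrix(0, 4, G)
  key <- paste(signif(nat[, 1], 12), signif(nat[, 2], 12))
  for (blk in unique(key)) {
    members <- which(key == blk)
    a <- nat[members[1], 1]; b <- nat[members[1], 2]
    nodes <- .block_nodes(a, b, sigma)
    z <- (nodes$u - a) / b
    # censoring sigmoids depend only on node position; shared per block.
    # Sub-grid tail masses sit at t ~ 0 / t ~ 1 where the sigmoid is 1/2.
    cens0 <- pnorm(-nodes$t / sigma)
    cens1 <- pnorm((nodes$t - 1) / sigma)
    for (g in members) {
      cc <- nat[g, 3]; d <- nat[g, 4]
      arg <- cc + d * z
      lPy <- pnorm(arg, log.p = TRUE)
      W <- nodes$base * exp(lPy)
      t_nodes[[g]] <- nodes$t
      w_nodes[[g]] <- W
      if (nodes$t_cut_low > 0) {
        tm <- .tail_mass(a, b, cc, d, a - 8.5 * abs(b), qnorm(nodes$t_cut_low))
        Mlow[g] <- tm$mass; Glow[, g] <- tm$grad
      }
      if (nodes$t_cut_high > 0) {
        tm <- .tail_mass(a, b, cc, d, -qnorm(nodes$t_cut_high), a + 8.5 * abs(b))
        Mhigh[g] <- tm$mass; Ghigh[, g] <- tm$grad
      }
      L0[g] <- sum(W * cens0) + 0.5 * Mlow[g]
      L1[g] <- sum(W * cens1) + 0.5 * Mhigh[g]
      if (want_grad) {
        lam <- exp(dnorm(arg, log = TRUE) - lPy)
        R <- .nat_ratios(z, b, lam, d)
        ratio_mats[[g]] <- R
        G0[, g] <- crossprod(R, W * cens0) + 0.5 * Glow[, g]
        G1[, g] <- crossprod(R, W * cens1) + 0.5 * Ghigh[, g]
      } else ratio_mats[[g]] <- matrix(0, 0, 4)
    }
  }
  res <- cpp_cont_loglik(conf, as.integer(grp), t_nodes, w_nodes, ratio_mats,
                         L0, L1, G0, G1, Mlow, Mhigh, Glow, Ghigh,
                         sigma, want_grad)
  if (want_grad) {
    # reorder from per-group (a,b,c,d) blocks to the column-major layout of
    # as.numeric(nat), i.e. (a_1..a_G, b_1..b_G, c_1..c_G, d_1..d_G)
    res$grad <- as.numeric(t(matrix(res$grad, 4L, G)))
  }
  res
}

# ---- task-specific natural-parameter maps -------------------------------

# Recall: groups (outcome 0, outcome 1); theta = (mu_m, rho, P_exp, M_conf)
# given as a plain list. If drop_performance, a single group with
# P(cell|z) = 1 is used (degenerate all-same-outcome data).
.nat_recall <- function(mu_m, rho, P_exp, M_conf, drop_performance = FALSE) {
  a <- canonical_cell_shift(M_conf, P_exp)
  b <- .canonical_slope(P_exp)
  if (drop_performance)
    return(matrix(c(a, b, Inf, 0), 1, 4,
                  dimnames = list(NULL, c("a", "b", "c", "d"))))
  s <- sqrt(1 - rho^2)
  rbind(c(a, b, -mu_m / s, -rho / s),   # outcome 0
        c(a, b,  mu_m / s,  rho / s))   # outcome 1
}

# Recognition: groups in cell order s1_r1, s1_r2, s2_r1, s2_r2.
# M_conf is the named length-4 cell vector.
.nat_recognition <- function(P_exp, rho, M_conf, d_prime, criterion) {
  b <- .canonical_slope(P_exp)
  s <- sqrt(1 - rho^2)
  out <- matrix(NA_real_, 4, 4, dimnames = list(.M_CONF_CELLS, c("a", "b", "c", "d")))
  i <- 0
  for (stim in c("S1", "S2")) {
    mu_s <- if (stim == "S1") -d_prime / 2 else d_prime / 2
    for (resp in c("r1", "r2")) {
      i <- i + 1
      cell <- paste0(tolower(stim), "_", resp)
      a <- canonical_cell_shift(M_conf[[cell]], P_exp)
      if (resp == "r2") {
        out[i, ] <- c(a, b, (mu_s - criterion) / s, rho / s)
      } else {
        out[i, ] <- c(a, -b, (criterion - mu_s) / s, -rho / s)
      }
    }
  }
  out
}

# ---- public log-likelihoods --------------------------------------------

.check_recall_cont <- function(trials) {
  if (!all(trials$task == "recall")) .stopf("expected recall trials")
  if (any(trials$confidence < 0 | trials$confidence > 1))
    .stopf("continuous confidence must lie in [0, 1]")
  if (!all(trials$outcome %in% c(0L, 1L))) .stopf("outcome must be 0/1")
}

#' Log-likelihood: recall task, continuous confidence
#'
#' @param trials Trial table of continuous-scale recall trials.
#' @param params A [recall_params()] object (fit style, or generative -- the
#'   identifiable summary is used).
#' @return Scalar log-likelihood.
#' @export
loglik_recall_continuous <- function(trials, params) {
  stopifnot(inherits(params, "bim_recall_params"))
  .check_recall_cont(trials)
  nat <- .nat_recall(params$mu_m, params$rho, params$P_exp, params$M_conf)
  .cont_loglik_nat(trials$confidence, trials$outcome, nat,
                   sigma = params$sigma_noise)$loglik
}

#' Log-likelihood: recognition task, continuous confidence
#'
#' The SDT parameters inside `params` are treated as plug-ins (not
#' penalised); the likelihood conditions on the stimulus shown.
#'
#' @param trials Trial table of continuous-scale recognition trials.
#' @param params A [recognition_params()] object.
#' @return Scalar log-likelihood.
#' @export
loglik_recognition_continuous <- function(trials, params) {
  stopifnot(inherits(params, "bim_recognition_params"))
  if (!all(trials$task == "recognition")) .stopf("expected recognition trials")
  if (any(is.na(trials$stimulus)) || any(is.na(trials$response)))
    .stopf("recognition trials need stimulus and response")
  nat <- .nat_recognition(params$P_exp, params$rho, params$M_conf,
                          params$d_prime, params$criterion)
  grp <- .recog_cell_index(trials) - 1L
  .cont_loglik_nat(trials$confidence, grp, nat,
                   sigma = params$sigma_noise)$loglik
}

.recog_cell_index <- function(trials) {
  match(paste0(tolower(trials$stimulus), "_",
               sub("S", "r", trials$response)), .M_CONF_CELLS)
}
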