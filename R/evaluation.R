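# Experiment harnesses: parameter recovery, model cross-correlations,
# leave-one-out cross-validated log-likelihood, blockwise refitting, and
# confidence binning.

#' Bin continuous confidence onto an n-point scale
#'
#' Equal-width bins over the unit interval, lower-inclusive with the top
#' bin closed at 1. Inputs on a 0-100 percentage scale are normalised
#' first (detected when any value exceeds 1).
#'
#' @param confidence Numeric vector in 0..1 (or 0..100).
#' @param n Number of bins (default 7).
#' @return Integer bins in 1..n.
#' @examples
#' bin_confidence(c(0, 0.5, 2/7, 1), n = 7)  # 1 4 3 7
#' @export
bin_confidence <- function(confidence, n = 7L) {
  n <- as.integer(n)
  if (n < 2L) .stopf("n must be >= 2")
  if (any(!is.finite(confidence))) .stopf("confidence must be finite")
  if (any(confidence > 1)) confidence <- confidence / 100
  if (any(confidence < 0 | confidence > 1))
    .stopf("confidence out of range [0, 1] (or 0..100)")
  .bin_unit_interval(confidence, n)
}

.default_ranges <- list(mu_m = c(-2, 2), rho = c(-0.9, 0.9),
                        P_exp = c(0.1, 0.9), M_conf = c(0.1, 0.9),
                        d_prime = c(-3, 3), criterion = c(-1, 1))

.runif_range <- function(r) runif(1, r[1], r[2])

#' Parameter-recovery experiment
#'
#' Samples parameter sets uniformly from `ranges`, simulates one dataset
#' per set, refits the model, and reports the Pearson correlation between
#' true and fitted values per parameter. Recall reports correlations both
#' over all datasets and after excluding datasets whose outcomes are all
#' identical (where mu_m and rho are dropped); recognition M_conf
#' correlations exclude datasets with an empty (stimulus, response) cell.
#'
#' @param task `"recall"` or `"recognition"`.
#' @param scale Scale descriptor.
#' @param n_trials Trials per dataset (per stimulus for recognition).
#' @param n_datasets Number of simulated datasets (default 1000).
#' @param ranges Named list of c(lo, hi) ranges; defaults to mu_m (-2, 2),
#'   rho (-.9, .9), P_exp and M_conf (.1, .9), d' (-3, 3), C (-1, 1).
#' @param seed Master seed; per-dataset seeds derive from it.
#' @param fit_options Options forwarded to [fit_bim()].
#' @param progress Print a dot every 100 datasets.
#' @return Object of class `bim_recovery_report`: `correlations` (named),
#'   `correlations_excluded` (recall: after degenerate exclusion;
#'   recognition: per-cell M_conf after empty-cell exclusion), `draws`
#'   (data.frame of true/fitted values), `n_excluded`.
#' @export
recovery_experiment <- function(task = "recall", scale = "continuous",
                                n_trials = 10L, n_datasets = 1000L,
                                ranges = list(), seed = 1L,
                                fit_options = list(), progress = FALSE) {
  task <- match.arg(task, c("recall", "recognition"))
  rng <- modifyList(.default_ranges, ranges)
  seeds <- .derive_seeds(seed, 2L * n_datasets)
  draw_seeds <- seeds[seq_len(n_datasets)]
  sim_seeds <- seeds[n_datasets + seq_len(n_datasets)]
  rows <- vector("list", n_datasets)

  for (i in seq_len(n_datasets)) {
    true <- .with_seed(draw_seeds[i], function() {
      if (task == "recall") {
        list(mu_m = .runif_range(rng$mu_m), rho = .runif_range(rng$rho),
             P_exp = .runif_range(rng$P_exp), M_conf = .runif_range(rng$M_conf))
      } else {
        list(P_exp = .runif_range(rng$P_exp), rho = .runif_range(rng$rho),
             M_conf = stats::setNames(
               c(.runif_range(rng$M_conf), .runif_range(rng$M_conf),
                 .runif_range(rng$M_conf), .runif_range(rng$M_conf)),
               .M_CONF_CELLS),
             d_prime = .runif_range(rng$d_prime),
             criterion = .runif_range(rng$criterion))
      }
    })
    cfg <- sim_config(n_trials, scale, seed = sim_seeds[i])
    if (task == "recall") {
      pp <- recall_params(true$mu_m, true$rho, P_exp = true$P_exp,
                          M_conf = true$M_conf)
      tt <- simulate_recall(pp, cfg)
      # degenerate datasets keep mu_m/rho in the fit (scattered estimates);
      # they are excluded afterwards for the corrected correlations
      fit <- fit_bim(tt, options = modifyList(list(drop_degenerate = FALSE),
                                              fit_options))
      rows[[i]] <- data.frame(
        true_mu_m = true$mu_m, true_rho = true$rho,
        true_P_exp = true$P_exp, true_M_conf = true$M_conf,
        fit_mu_m = fit$estimates$mu_m %||% NA_real_,
        fit_rho = fit$estimates$rho %||% NA_real_,
        fit_P_exp = fit$estimates$P_exp, fit_M_conf = fit$estimates$M_conf,
        degenerate = length(unique(tt$outcome)) == 1L)
    } else {
      pp <- recognition_params(true$d_prime, true$criterion, true$rho,
                               P_exp = true$P_exp, M_conf = true$M_conf)
      tt <- simulate_recognition(pp, cfg)
      fit <- fit_bim(tt, options = fit_options)
      mfit <- fit$estimates$M_conf
      rows[[i]] <- data.frame(
        true_P_exp = true$P_exp, true_rho = true$rho,
        true_d_prime = true$d_prime, true_criterion = true$criterion,
        true_M_s1_r1 = true$M_conf[["s1_r1"]], true_M_s1_r2 = true$M_conf[["s1_r2"]],
        true_M_s2_r1 = true$M_conf[["s2_r1"]], true_M_s2_r2 = true$M_conf[["s2_r2"]],
        fit_P_exp = fit$estimates$P_exp, fit_rho = fit$estimates$rho,
        fit_M_s1_r1 = mfit[["s1_r1"]], fit_M_s1_r2 = mfit[["s1_r2"]],
        fit_M_s2_r1 = mfit[["s2_r1"]], fit_M_s2_r2 = mfit[["s2_r2"]],
        n_empty = length(fit$empty_cells),
        empty_cells = paste(fit$empty_cells, collapse = ";"))
    }
    if (progress && i %% 100L == 0L) cat(".")
  }
  if (progress) cat("\n")
  draws <- do.call(rbind, rows)

  if (task == "recall") {
    cors <- c(P_exp = .safe_cor(draws$true_P_exp, draws$fit_P_exp),
              M_conf = .safe_cor(draws$true_M_conf, draws$fit_M_conf),
              mu_m = .safe_cor(draws$true_mu_m, draws$fit_mu_m),
              rho = .safe_cor(draws$true_rho, draws$fit_rho))
    keep <- !draws$degenerate
    cors_ex <- c(mu_m = .safe_cor(draws$true_mu_m[keep], draws$fit_mu_m[keep]),
                 rho = .safe_cor(draws$true_rho[keep], draws$fit_rho[keep]))
    n_ex <- sum(draws$degenerate)
  } else {
    cors <- c(P_exp = .safe_cor(draws$true_P_exp, draws$fit_P_exp),
              rho = .safe_cor(draws$true_rho, draws$fit_rho))
    keep <- draws$n_empty == 0L
    cors_ex <- c(
      M_s1_r1 = .safe_cor(draws$true_M_s1_r1[keep], draws$fit_M_s1_r1[keep]),
      M_s1_r2 = .safe_cor(draws$true_M_s1_r2[keep], draws$fit_M_s1_r2[keep]),
      M_s2_r1 = .safe_cor(draws$true_M_s2_r1[keep], draws$fit_M_s2_r1[keep]),
      M_s2_r2 = .safe_cor(draws$true_M_s2_r2[keep], draws$fit_M_s2_r2[keep]))
    n_ex <- sum(!keep)
  }
  structure(list(task = task, scale = .scale_string(scale),
                 n_trials = n_trials, n_datasets = n_datasets,
                 correlations = cors, correlations_excluded = cors_ex,
                 n_excluded = n_ex, draws = draws),
            class = "bim_recovery_report")
}

#' @export
print.bim_recovery_report <- function(x, ...) {
  cat(sprintf("parameter recovery: %s, %s, %d trials x %d datasets\n",
              x$task, x$scale, x$n_trials, x$n_datasets))
  print(round(x$correlations, 3))
  cat(sprintf("after exclusion (%d datasets removed):\n", x$n_excluded))
  print(round(x$correlations_excluded, 3))
  invisible(x)
}

#' Cross-correlation study against reference models
#'
#' Samples model parameter sets, simulates discrete-scale datasets, fits
#' this package's model alongside the reference models, and reports the
#' Spearman correlation matrix between fitted model parameters and
#' reference metrics. Recall: restricted SDRM, gamma, AUROC. Recognition:
#' meta-d' (padded), gamma, AUROC. Entries with |r| > 0.5 are flagged.
#'
#' @param task `"recall"` or `"recognition"`.
#' @param n_datasets Number of simulated datasets.
#' @param n_trials Trials per dataset (per stimulus for recognition).
#' @param n_bins Rating-scale points (default 7).
#' @param seed Master seed.
#' @param fit_options,ref_options Options for the model fits.
#' @param progress Print a dot every 50 datasets.
#' @return Object of class `bim_xcorr_report` with `matrix` (Spearman),
#'   `flags` (|r| > .5), and the per-dataset `draws`.
#' @export
cross_correlation_study <- function(task = "recall", n_datasets = 1000L,
                                    n_trials = 500L, n_bins = 7L, seed = 1L,
                                    fit_options = list(), ref_options = list(),
                                    progress = FALSE) {
  task <- match.arg(task, c("recall", "recognition"))
  scale <- sprintf("discrete:%d", n_bins)
  rng <- .default_ranges
  seeds <- .derive_seeds(seed, 2L * n_datasets)
  rows <- vector("list", n_datasets)

  for (i in seq_len(n_datasets)) {
    true <- .with_seed(seeds[i], function() {
      if (task == "recall") {
        list(mu_m = .runif_range(rng$mu_m), rho = .runif_range(rng$rho),
             P_exp = .runif_range(rng$P_exp), M_conf = .runif_range(rng$M_conf))
      } else {
        list(P_exp = .runif_range(rng$P_exp), rho = .runif_range(rng$rho),
             M_conf = stats::setNames(
               c(.runif_range(rng$M_conf), .runif_range(rng$M_conf),
                 .runif_range(rng$M_conf), .runif_range(rng$M_conf)),
               .M_CONF_CELLS),
             d_prime = .runif_range(rng$d_prime),
             criterion = .runif_range(rng$criterion))
      }
    })
    cfg <- sim_config(n_trials, scale, seed = seeds[n_datasets + i])
    met <- function(tt) {
      g <- tryCatch(gamma_stat(tt), bim_degenerate = function(e) NA_real_)
      a <- tryCatch(auroc2(tt), bim_degenerate = function(e) NA_real_)
      c(gamma = g, auroc = a)
    }
    if (task == "recall") {
      pp <- recall_params(true$mu_m, true$rho, P_exp = true$P_exp,
                          M_conf = true$M_conf)
      tt <- simulate_recall(pp, cfg)
      fit <- fit_bim(tt, options = fit_options)
      sd_fit <- sdrm_fit(tt, n = n_bins, options = ref_options)
      m <- met(tt)
      rows[[i]] <- data.frame(
        P_exp = fit$estimates$P_exp, M_conf = fit$estimates$M_conf,
        mu_m = fit$estimates$mu_m %||% NA_real_,
        rho = fit$estimates$rho %||% NA_real_,
        gamma = m[["gamma"]], auroc = m[["auroc"]],
        sdrm_rho = sd_fit$estimates$rho,
        sdrm_M_crit = sd_fit$estimates$M_criteria,
        sdrm_SD_crit = sd_fit$estimates$SD_criteria,
        sdrm_C_M = sd_fit$estimates$C_M)
    } else {
      pp <- recognition_params(true$d_prime, true$criterion, true$rho,
                               P_exp = true$P_exp, M_conf = true$M_conf)
      tt <- simulate_recognition(pp, cfg)
      fit <- fit_bim(tt, options = fit_options)
      md <- metad_fit(count_table_recognition(tt, n_bins), options = ref_options)
      m <- met(tt)
      mf <- fit$estimates$M_conf
      rows[[i]] <- data.frame(
        P_exp = fit$estimates$P_exp,
        M_s1_r1 = mf[["s1_r1"]], M_s1_r2 = mf[["s1_r2"]],
        M_s2_r1 = mf[["s2_r1"]], M_s2_r2 = mf[["s2_r2"]],
        gamma = m[["gamma"]], auroc = m[["auroc"]],
        meta_d = md$meta_d,
        M_CrS1 = md$M_CrS1, SD_CrS1 = md$SD_CrS1,
        M_CrS2 = md$M_CrS2, SD_CrS2 = md$SD_CrS2)
    }
    if (progress && i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  draws <- do.call(rbind, rows)

  if (task == "recall") {
    model_cols <- c("P_exp", "M_conf", "mu_m", "rho")
    ref_cols <- c("gamma", "auroc", "sdrm_rho", "sdrm_M_crit",
                  "sdrm_SD_crit", "sdrm_C_M")
  } else {
    model_cols <- c("P_exp", "M_s1_r1", "M_s1_r2", "M_s2_r1", "M_s2_r2")
    ref_cols <- c("gamma", "auroc", "meta_d", "M_CrS1", "SD_CrS1",
                  "M_CrS2", "SD_CrS2")
  }
  mat <- sapply(model_cols, function(mc)
    sapply(ref_cols, function(rc)
      .safe_cor(draws[[mc]], draws[[rc]], method = "spearman")))
  structure(list(task = task, n_datasets = n_datasets, n_trials = n_trials,
                 n_bins = n_bins, matrix = t(mat),
                 flags = abs(t(mat)) > 0.5, draws = draws),
            class = "bim_xcorr_report")
}

#' @export
print.bim_xcorr_report <- function(x, ...) {
  cat(sprintf("cross-correlation study: %s, %d datasets x %d trials, %d-point scale\n",
              x$task, x$n_datasets, x$n_trials, x$n_bins))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Leave-one-out cross-validated log-likelihood
#'
#' For each trial, refits the model to the remaining trials (warm-started
#' at the full-data estimate, single start) and evaluates the held-out
#' trial's log-likelihood; returns the sum. `model = "SDRM2"` requires
#' `trials` to be a list of the two condition tables.
#'
#' @param trials Trial table (or list of two tables for `"SDRM2"`).
#' @param model `"BIM"`, `"SDRM1"`, or `"SDRM2"`.
#' @param options Fit options (the warm start replaces multistart).
#' @return Scalar cross-validated log-likelihood.
#' @export
loo_cv_loglik <- function(trials, model = c("BIM", "SDRM1", "SDRM2"),
                          options = list()) {
  model <- match.arg(model)
  if (model == "SDRM2") {
    if (!is.list(trials) || is.data.frame(trials) || length(trials) != 2L)
      .stopf("SDRM2 cross-validation needs a list of two condition tables")
    return(.loo_sdrm2(trials[[1]], trials[[2]], options))
  }
  tt <- trials
  if (nrow(tt) < 2L) .stopf("need at least 2 trials")
  n_scale <- .parse_scale(tt$scale[1])
  cv <- 0
  if (model == "BIM") {
    full <- fit_bim(tt, options = options)
    warm <- modifyList(options, list(n_starts = 1L, init = full$estimates))
    for (i in seq_len(nrow(tt))) {
      fit <- fit_bim(tt[-i, , drop = FALSE], options = warm)
      held <- tt[i, , drop = FALSE]
      p <- fit$estimates
      if (length(fit$dropped_params)) {
        # confidence-only model: use unconditional bin/report probability
        cv <- cv + .loglik_degenerate_holdout(held, p, n_scale)
      } else {
        pr <- recall_params(p$mu_m, p$rho, P_exp = p$P_exp, M_conf = p$M_conf)
        cv <- cv + if (n_scale$type == "continuous")
          loglik_recall_continuous(held, pr)
        else loglik_recall_discrete(held, pr, n_scale$n)
      }
    }
  } else {
    full <- sdrm_fit(tt, options = options)
    for (i in seq_len(nrow(tt))) {
      warm <- modifyList(options, list(n_starts = 1L))
      fit <- .sdrm_refit_warm(tt[-i, , drop = FALSE], full, warm)
      held <- tt[i, , drop = FALSE]
      cv <- cv + sdrm_loglik(held, sdrm_params(fit$estimates$C_M,
                                               fit$estimates$rho,
                                               fit$estimates$criteria))
    }
  }
  cv
}

# Held-out log-likelihood under the degenerate (confidence-only) recall
# model: performance term is dropped exactly as in fitting.
.loglik_degenerate_holdout <- function(held, p, n_scale) {
  if (n_scale$type == "continuous") {
    nat <- .nat_recall(0, 0, p$P_exp, p$M_conf, drop_performance = TRUE)
    .cont_loglik_nat(held$confidence, rep(0L, nrow(held)), nat)$loglik
  } else {
    edges <- .z_edges_up(n_scale$n, p$P_exp, p$M_conf)
    pr <- pnorm(edges[-1]) - pnorm(edges[-(n_scale$n + 1L)])
    sum(log(pmax(pr[as.integer(held$confidence)], 1e-300)))
  }
}

.sdrm_refit_warm <- function(tt, full, options) {
  n <- length(full$estimates$criteria) + 1L
  # warm start: seed optimiser at the full-data solution via init theta
  opt <- .fit_defaults(modifyList(options, list(n_starts = 1L)))
  counts <- matrix(0, 2L, n)
  idx <- cbind(tt$outcome + 1L, as.integer(tt$confidence))
  for (i in seq_len(nrow(idx))) counts[idx[i, 1], idx[i, 2]] <-
      counts[idx[i, 1], idx[i, 2]] + 1
  crit <- full$estimates$criteria
  theta0 <- c(full$estimates$C_M, atanh(.clamp(full$estimates$rho, -0.993, 0.993)),
              crit[1], log(pmax(diff(crit), 1e-4)))
  lower <- c(-5, -.ATANH_BOUND, -6, rep(-7, n - 2L))
  upper <- c(5, .ATANH_BOUND, 6, rep(2, n - 2L))
  obj <- function(th) {
    cr <- .sdrm_unpack_criteria(th[-(1:2)])
    cells <- .sdrm_cells(th[1], tanh(th[2]), cr)
    list(value = -sum(counts * log(pmax(cells, 1e-300))), grad = NULL)
  }
  best <- .mle_multistart(obj, list(theta0), lower, upper, opt$maxit,
                          opt$factr, has_grad = FALSE)
  cr <- .sdrm_unpack_criteria(best$par[-(1:2)])
  list(estimates = list(C_M = best$par[1], rho = tanh(best$par[2]),
                        criteria = cr))
}

.loo_sdrm2 <- function(ta, tb, options) {
  n <- .parse_scale(ta$scale[1])$n
  full <- sdrm2_fit(ta, tb, n, options)
  cv <- 0
  single <- modifyList(options, list(n_starts = 1L))
  eval_held <- function(held, est, cond) {
    crit <- if (cond == 1L) est$criteria_a else est$criteria_b
    rho <- if (cond == 1L) est$rho_a else est$rho_b
    cm <- if (cond == 1L) est$C_M_a else est$C_M_b
    sdrm_loglik(held, sdrm_params(cm, rho, crit))
  }
  for (cond in 1:2) {
    tt <- if (cond == 1L) ta else tb
    for (i in seq_len(nrow(tt))) {
      a2 <- if (cond == 1L) tt[-i, , drop = FALSE] else ta
      b2 <- if (cond == 1L) tb else tt[-i, , drop = FALSE]
      fit <- sdrm2_fit(a2, b2, n, single)
      cv <- cv + eval_held(tt[i, , drop = FALSE], fit$estimates, cond)
    }
  }
  cv
}

#' Blockwise refitting for belief-updating detection
#'
#' Splits the trials into contiguous, order-preserving blocks (the last
#' block absorbs any remainder) and fits the restricted model to each
#' block. A decreasing fitted P_exp together with a drifting M_conf across
#' blocks is the signature of belief updating that the restricted model
#' cannot represent directly.
#'
#' @param trials Trial table carrying trial order.
#' @param n_blocks Number of blocks (default 4).
#' @param options Fit options.
#' @return List with `fits` (per-block `bim_fit`s) and `summary`
#'   (data.frame of block, n, P_exp, M_conf).
#' @export
blockwise_refit <- function(trials, n_blocks = 4L, options = list()) {
  n <- nrow(trials)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L || n_blocks > n) .stopf("invalid n_blocks")
  size <- n %/% n_blocks
  fits <- vector("list", n_blocks)
  summ <- data.frame(block = seq_len(n_blocks), n = NA_integer_,
                     P_exp = NA_real_, M_conf = NA_real_)
  for (b in seq_len(n_blocks)) {
    from <- (b - 1L) * size + 1L
    to <- if (b == n_blocks) n else b * size
    blk <- trials[from:to, , drop = FALSE]
    fits[[b]] <- fit_bim(blk, options = options)
    summ$n[b] <- nrow(blk)
    summ$P_exp[b] <- fits[[b]]$estimates$P_exp
    summ$M_conf[b] <- fits[[b]]$estimates$M_conf
  }
  list(fits = fits, summary = summ)
}
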