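# Seeded trial-level simulators.
#
# Each simulator draws (strength deviation w, experience deviation z) from
# a standard bivariate normal with correlation rho, computes predicted
# confidence in closed form, and applies the reporting model: continuous
# scales add N(0, 0.025^2) noise and clamp to [0, 1]; discrete scales bin
# the noiseless posterior probability into n equal-width intervals
# (bin i = [(i-1)/n, i/n), top bin closed).

.new_trial_table <- function(n, task, condition, scale) {
  data.frame(trial = seq_len(n),
             task = rep(task, n),
             condition = rep(condition, n),
             stimulus = rep(NA_character_, n),
             response = rep(NA_character_, n),
             outcome = rep(NA_integer_, n),
             confidence = rep(NA_real_, n),
             scale = rep(.scale_string(scale), n),
             stringsAsFactors = FALSE)
}

.bin_unit_interval <- function(p, n) {
  pmin(floor(p * n) + 1L, n)
}

# Draw (w, z) standard bivariate normal with correlation rho; column-wise.
.draw_wz <- function(n, rho) {
  w <- rnorm(n)
  z <- rho * w + sqrt(1 - rho^2) * rnorm(n)
  list(w = w, z = z)
}

.report_confidence <- function(p, scale, sigma_noise) {
  if (scale$type == "continuous") {
    .clamp(p + rnorm(length(p), 0, sigma_noise), 0, 1)
  } else {
    as.numeric(.bin_unit_interval(p, scale$n))
  }
}

#' Simulate a recall task
#'
#' @param params A [recall_params()] object (fit or generative style).
#' @param config A [sim_config()].
#' @return A trial table (`data.frame`) with columns `trial`, `task`,
#'   `condition`, `stimulus`, `response`, `outcome`, `confidence`, `scale`.
#' @examples
#' p <- recall_params(mu_m = 0.2, rho = 0.5, P_exp = 0.5, M_conf = 0.6)
#' head(simulate_recall(p, sim_config(20, seed = 42)))
#' @export
simulate_recall <- function(params, config) {
  stopifnot(inherits(params, "bim_recall_params"),
            inherits(config, "bim_sim_config"))
  n <- config$n_trials
  scale <- config$scale
  .with_seed(config$seed, function() {
    wz <- .draw_wz(n, params$rho)
    outcome <- as.integer(params$mu_m + wz$w > 0)
    p <- if (params$style == "generative") {
      predicted_confidence_recall(params$mu_e + wz$z, params$mu_b, params$sigma_l)
    } else {
      a <- canonical_cell_shift(params$M_conf, params$P_exp)
      b <- .canonical_slope(params$P_exp)
      pnorm(a + b * wz$z)
    }
    tt <- .new_trial_table(n, "recall", config$condition, scale)
    tt$outcome <- outcome
    tt$confidence <- .report_confidence(p, scale, params$sigma_noise)
    tt
  })
}

#' Simulate a recognition task
#'
#' Simulates `config$n_trials` trials for each stimulus type (S1 then S2).
#' Strength means are -d'/2 and +d'/2; the response is S2 whenever strength
#' exceeds the type I criterion; confidence comes from the response's cell
#' (canonical shifts for fit-style parameters, the Bayes-derived
#' response-mirrored forms for generative parameters).
#'
#' @param params A [recognition_params()] object.
#' @param config A [sim_config()]; `n_trials` counts trials per stimulus.
#' @return A trial table with `stimulus`, `response` filled in and
#'   `outcome = 1` when the response matches the stimulus.
#' @export
simulate_recognition <- function(params, config) {
  stopifnot(inherits(params, "bim_recognition_params"),
            inherits(config, "bim_sim_config"))
  n_per <- config$n_trials
  scale <- config$scale
  .with_seed(config$seed, function() {
    stim <- rep(c("S1", "S2"), each = n_per)
    mu_s <- ifelse(stim == "S1", -params$d_prime / 2, params$d_prime / 2)
    wz <- .draw_wz(2L * n_per, params$rho)
    resp <- ifelse(mu_s + wz$w > params$criterion, "S2", "S1")
    p <- numeric(2L * n_per)
    if (params$style == "fit") {
      b <- .canonical_slope(params$P_exp)
      cellname <- paste0(tolower(stim), "_", tolower(sub("S", "r", resp)))
      a <- canonical_cell_shift(params$M_conf[cellname], params$P_exp)
      sgn <- ifelse(resp == "S2", 1, -1)
      p <- pnorm(a + sgn * b * wz$z)
    } else {
      e <- mu_s_e <- ifelse(stim == "S1", params$mu_e_s1, params$mu_e_s2)
      e <- mu_s_e + wz$z
      is2 <- resp == "S2"
      p[is2] <- predicted_confidence_recognition(e[is2], "S2", params$mu_b_r2,
                                                 params$sigma_l, params$criterion)
      p[!is2] <- predicted_confidence_recognition(e[!is2], "S1", params$mu_b_r1,
                                                  params$sigma_l, params$criterion)
    }
    tt <- .new_trial_table(2L * n_per, "recognition", config$condition, scale)
    tt$stimulus <- stim
    tt$response <- resp
    tt$outcome <- as.integer(stim == resp)
    tt$confidence <- .report_confidence(p, scale, params$sigma_noise)
    tt
  })
}

#' Simulate sequential belief updating
#'
#' Extended-model simulator: on each trial an experience `e ~ N(mu_e, 1)`
#' is drawn, confidence is the generalised posterior probability
#' `P(m-hat > 0 | e)` under the *current* belief `N(mu_b_t, sigma_b_t^2)`
#' and confidence likelihood SD `sigma_l`, and the belief is then updated
#' by a second conjugate inference with likelihood SD `sigma_lb`. The
#' belief SD shrinks deterministically; smaller `sigma_lb` means faster
#' updating.
#'
#' @param init A [belief_state()] giving the pre-task belief and `sigma_lb`.
#' @param mu_e Mean of the processing-experience distribution.
#' @param sigma_l Confidence-likelihood SD (> 0).
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param sigma_noise Reporting-noise SD applied to the continuous report.
#' @return List with `trials` (a continuous-scale recall-style trial table;
#'   outcomes are generated with mu_m = mu_e and the same correlation
#'   structure absent, i.e. outcome = 1 iff a fresh strength draw clears 0)
#'   and `trajectory` (data.frame of per-trial pre/post belief states).
#' @export
simulate_belief_updating <- function(init, mu_e, sigma_l, n_trials,
                                     seed = 1L, sigma_noise = 0.025) {
  stopifnot(inherits(init, "bim_belief_state"))
  if (sigma_l <= 0) .stopf("sigma_l must be positive")
  n <- as.integer(n_trials)
  .with_seed(seed, function() {
    e <- mu_e + rnorm(n)
    noise <- rnorm(n, 0, sigma_noise)
    state <- init
    conf <- numeric(n)
    traj <- data.frame(trial = seq_len(n), mu_b_pre = NA_real_,
                       sigma_b_pre = NA_real_, e = e, confidence = NA_real_,
                       mu_b_post = NA_real_, sigma_b_post = NA_real_)
    for (t in seq_len(n)) {
      traj$mu_b_pre[t] <- state$mu_b_t
      traj$sigma_b_pre[t] <- state$sigma_b_t
      post <- posterior_strength(e[t], state$mu_b_t, sigma_l, state$sigma_b_t)
      conf[t] <- pnorm(post$mean / sqrt(post$variance))
      state <- update_belief(state, e[t])
      traj$mu_b_post[t] <- state$mu_b_t
      traj$sigma_b_post[t] <- state$sigma_b_t
    }
    traj$confidence <- conf
    tt <- .new_trial_table(n, "recall", NA_character_, list(type = "continuous"))
    # outcome: strength draw shares the experience deviation scale-free;
    # performance is incidental here, confidence dynamics are the point.
    tt$outcome <- as.integer(mu_e + rnorm(n) > 0)
    tt$confidence <- .clamp(conf + noise, 0, 1)
    list(trials = tt, trajectory = traj)
  })
}
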