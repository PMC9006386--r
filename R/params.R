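# Parameter-set constructors.
#
# Each task has two parameterisations:
#  * "fit": the identifiable set actually estimated from data
#    (recall: mu_m, rho, P_exp, M_conf; recognition: P_exp, rho, four
#    M_conf cells plus plugged-in SDT d'/C);
#  * "generative": the underlying latent means (mu_e, mu_b, sigma_l),
#    useful for simulation experiments where the non-identifiable means
#    are meaningful.

.M_CONF_CELLS <- c("s1_r1", "s1_r2", "s2_r1", "s2_r2")

#' Recall-task parameter set
#'
#' Supply either the identifiable fit-style set (`P_exp`, `M_conf`) or the
#' generative set (`mu_e`, `mu_b`, `sigma_l`). All latent distributions
#' have SD 1; the reporting-noise SD is fixed at 0.025.
#'
#' @param mu_m Mean of objective memory strength (z units).
#' @param rho Strength-experience correlation, |rho| < 1.
#' @param P_exp,M_conf Fit-style parameters, each strictly inside (0, 1).
#' @param mu_e,mu_b,sigma_l Generative parameters (sigma_l > 0).
#' @param sigma_noise Reporting-noise SD (fixed default 0.025).
#' @return Object of class `bim_recall_params`.
#' @export
recall_params <- function(mu_m, rho, P_exp = NULL, M_conf = NULL,
                          mu_e = NULL, mu_b = NULL, sigma_l = NULL,
                          sigma_noise = 0.025) {
  if (!is.finite(mu_m)) .stopf("mu_m must be finite")
  if (!is.finite(rho) || abs(rho) >= 1) .stopf("|rho| must be < 1")
  fit_style <- !is.null(P_exp) || !is.null(M_conf)
  if (fit_style) {
    if (is.null(P_exp) || is.null(M_conf))
      .stopf("fit-style recall parameters need both P_exp and M_conf")
    if (!.is_prob(P_exp) || !.is_prob(M_conf))
      .stopf("P_exp and M_conf must lie strictly inside (0, 1)")
    out <- list(style = "fit", mu_m = mu_m, rho = rho,
                P_exp = P_exp, M_conf = M_conf, sigma_noise = sigma_noise)
  } else {
    if (is.null(mu_e) || is.null(mu_b) || is.null(sigma_l))
      .stopf("generative recall parameters need mu_e, mu_b and sigma_l")
    if (sigma_l <= 0) .stopf("sigma_l must be positive")
    out <- list(style = "generative", mu_m = mu_m, rho = rho,
                mu_e = mu_e, mu_b = mu_b, sigma_l = sigma_l,
                sigma_noise = sigma_noise)
    out$P_exp <- experience_weight(sigma_l)
    out$M_conf <- mean_confidence_recall(mu_e, mu_b, out$P_exp)
  }
  structure(out, class = "bim_recall_params")
}

#' Recognition-task parameter set
#'
#' Fit style: `P_exp`, `rho` and the four cell means `M_conf` (named
#' `s1_r1`, `s1_r2`, `s2_r1`, `s2_r2`), plus type I SDT parameters.
#' Generative style: `sigma_l`, per-stimulus experience means and
#' per-response belief means. Stimulus strength means are -d'/2 and +d'/2.
#'
#' @param d_prime,criterion Type I SDT parameters.
#' @param rho Within-stimulus strength-experience correlation.
#' @param P_exp Experience weight (fit style).
#' @param M_conf Length-4 vector of cell mean confidences (fit style),
#'   ordered/named as `s1_r1`, `s1_r2`, `s2_r1`, `s2_r2`.
#' @param sigma_l Likelihood SD (generative style).
#' @param mu_e_s1,mu_e_s2 Experience means per stimulus (generative).
#' @param mu_b_r1,mu_b_r2 Belief means per response (generative).
#' @param sigma_noise Reporting-noise SD (fixed default 0.025).
#' @return Object of class `bim_recognition_params`.
#' @export
recognition_params <- function(d_prime, criterion, rho,
                               P_exp = NULL, M_conf = NULL,
                               sigma_l = NULL,
                               mu_e_s1 = NULL, mu_e_s2 = NULL,
                               mu_b_r1 = NULL, mu_b_r2 = NULL,
                               sigma_noise = 0.025) {
  if (!is.finite(d_prime) || !is.finite(criterion))
    .stopf("d_prime and criterion must be finite")
  if (!is.finite(rho) || abs(rho) >= 1) .stopf("|rho| must be < 1")
  fit_style <- !is.null(P_exp) || !is.null(M_conf)
  if (fit_style) {
    if (is.null(P_exp) || is.null(M_conf) || length(M_conf) != 4L)
      .stopf("fit-style recognition parameters need P_exp and 4 M_conf cells")
    if (!.is_prob(P_exp) || !.is_prob(M_conf))
      .stopf("P_exp and all M_conf must lie strictly inside (0, 1)")
    if (is.null(names(M_conf))) names(M_conf) <- .M_CONF_CELLS
    M_conf <- M_conf[.M_CONF_CELLS]
    if (any(is.na(M_conf))) .stopf("M_conf must be named s1_r1, s1_r2, s2_r1, s2_r2")
    out <- list(style = "fit", d_prime = d_prime, criterion = criterion,
                rho = rho, P_exp = P_exp, M_conf = M_conf,
                sigma_noise = sigma_noise)
  } else {
    if (is.null(sigma_l) || is.null(mu_e_s1) || is.null(mu_e_s2) ||
        is.null(mu_b_r1) || is.null(mu_b_r2))
      .stopf("generative recognition parameters need sigma_l, mu_e_s*, mu_b_r*")
    if (sigma_l <= 0) .stopf("sigma_l must be positive")
    P_exp <- experience_weight(sigma_l)
    M_conf <- c(
      s1_r1 = mean_confidence_recognition(mu_e_s1, mu_b_r1, P_exp, criterion, "S1", "S1"),
      s1_r2 = mean_confidence_recognition(mu_e_s1, mu_b_r2, P_exp, criterion, "S1", "S2"),
      s2_r1 = mean_confidence_recognition(mu_e_s2, mu_b_r1, P_exp, criterion, "S2", "S1"),
      s2_r2 = mean_confidence_recognition(mu_e_s2, mu_b_r2, P_exp, criterion, "S2", "S2"))
    out <- list(style = "generative", d_prime = d_prime, criterion = criterion,
                rho = rho, sigma_l = sigma_l, P_exp = P_exp,
                mu_e_s1 = mu_e_s1, mu_e_s2 = mu_e_s2,
                mu_b_r1 = mu_b_r1, mu_b_r2 = mu_b_r2,
                M_conf = M_conf, sigma_noise = sigma_noise)
  }
  structure(out, class = "bim_recognition_params")
}

#' Simulation configuration
#'
#' @param n_trials Number of trials (recall) or trials per stimulus
#'   (recognition).
#' @param scale `"continuous"` or `"discrete:<n>"`.
#' @param seed Integer seed; identical configurations reproduce identical
#'   trial tables.
#' @param condition Optional condition label carried into the trial table.
#' @return Object of class `bim_sim_config`.
#' @export
sim_config <- function(n_trials, scale = "continuous", seed = 1L,
                       condition = NA_character_) {
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) .stopf("n_trials must be >= 1")
  structure(list(n_trials = n_trials, scale = .parse_scale(scale),
                 seed = as.integer(seed), condition = condition),
            class = "bim_sim_config")
}
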