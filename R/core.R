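# Closed-form model mathematics.
#
# The observer never sees objective memory strength m; on each trial they
# receive a processing experience e drawn (correlated rho) alongside m, and
# infer the latent strength by conjugate normal Bayesian updating of a
# prior belief N(mu_b, sigma_b^2) with likelihood N(m-hat, sigma_l^2).
# Confidence is the posterior probability that the inferred strength clears
# the decision criterion (0 for recall; the type I criterion C for
# recognition). All latent distributions have SD 1 for identifiability.

#' Relative weight of processing experience
#'
#' The proportion with which trial-wise processing experience (as opposed
#' to prior belief) contributes to the posterior mean of inferred memory
#' strength: `P_exp = 1 / (1 + sigma_l^2)`. The complement is the belief
#' weight `P_belief = sigma_l^2 / (1 + sigma_l^2)`.
#'
#' @param sigma_l SD of the likelihood linking strength to experience (> 0).
#' @return Experience weight in (0, 1).
#' @examples
#' experience_weight(1)   # experience and belief weighted equally
#' experience_weight(2)   # 0.2
#' @export
experience_weight <- function(sigma_l) {
  if (!is.numeric(sigma_l) || any(!is.finite(sigma_l)) || any(sigma_l <= 0))
    .stopf("sigma_l must be a positive finite number")
  1 / (1 + sigma_l^2)
}

#' Posterior distribution of inferred memory strength
#'
#' Conjugate normal update of the belief prior `N(mu_b, sigma_b^2)` with a
#' single experience sample `e` under likelihood SD `sigma_l`. With
#' `sigma_b = 1` this is the basic model's posterior; other values are used
#' only by the belief-updating simulator.
#'
#' @param e Processing experience (vectorised).
#' @param mu_b Prior belief mean.
#' @param sigma_l Likelihood SD (> 0).
#' @param sigma_b Prior SD (> 0, default 1).
#' @return List with elements `mean` and `variance`.
#' @export
posterior_strength <- function(e, mu_b, sigma_l, sigma_b = 1) {
  if (sigma_l <= 0 || sigma_b <= 0) .stopf("sigma_l and sigma_b must be positive")
  v_b <- sigma_b^2
  v_l <- sigma_l^2
  list(mean = (v_b * e + v_l * mu_b) / (v_b + v_l),
       variance = v_b * v_l / (v_b + v_l))
}

#' Predicted confidence in a recall task
#'
#' Posterior probability that inferred strength exceeds the recall
#' criterion 0 given experience `e`:
#' `Phi((e + sigma_l^2 mu_b) / (sigma_l sqrt(1 + sigma_l^2)))`.
#'
#' @inheritParams posterior_strength
#' @return Probability (vectorised over `e`).
#' @export
predicted_confidence_recall <- function(e, mu_b, sigma_l) {
  if (sigma_l <= 0) .stopf("sigma_l must be positive")
  pnorm((e + sigma_l^2 * mu_b) / (sigma_l * sqrt(1 + sigma_l^2)))
}

#' Mean of the confidence distribution in a recall task
#'
#' Marginal mean of predicted confidence over `e ~ N(mu_e, 1)`:
#' `Phi((mu_e P_exp + mu_b P_belief) / sqrt(1 - P_exp P_belief))`.
#'
#' @param mu_e Mean of the processing-experience distribution.
#' @param mu_b Mean of the prior-belief distribution.
#' @param P_exp Experience weight, strictly inside (0, 1).
#' @return Probability.
#' @export
mean_confidence_recall <- function(mu_e, mu_b, P_exp) {
  if (!.is_prob(P_exp)) .stopf("P_exp must lie strictly inside (0, 1)")
  P_b <- 1 - P_exp
  pnorm((mu_e * P_exp + mu_b * P_b) / sqrt(1 - P_exp * P_b))
}

#' Fixed criteria on the unit confidence scale
#'
#' An n-point rating scale divides the 0-1 posterior-probability scale into
#' n equal-width bins, so the n-1 criteria sit at i/n.
#'
#' @param n Number of scale points (>= 2).
#' @return Numeric vector of length `n - 1`.
#' @examples
#' confidence_criteria_unit(5)  # 0.2 0.4 0.6 0.8
#' @export
confidence_criteria_unit <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) .stopf("n must be an integer >= 2")
  seq_len(n - 1L) / n
}

#' Confidence criteria mapped onto the experience distribution
#'
#' Inverts the predicted-confidence transform so that the fixed unit-scale
#' criteria become criteria on processing experience:
#' `C_e(i) = sigma_l sqrt(1 + sigma_l^2) Phi^-1(i/n) - sigma_l^2 mu_b`.
#' Feeding the result back through [predicted_confidence_recall()] recovers
#' i/n exactly.
#'
#' @inheritParams confidence_criteria_unit
#' @inheritParams posterior_strength
#' @return Numeric vector of length `n - 1`, strictly increasing.
#' @export
criteria_on_experience <- function(n, mu_b, sigma_l) {
  if (sigma_l <= 0) .stopf("sigma_l must be positive")
  cc <- confidence_criteria_unit(n)
  sigma_l * sqrt(1 + sigma_l^2) * qnorm(cc) - sigma_l^2 * mu_b
}

#' Type I signal-detection parameters from hit and false-alarm rates
#'
#' `d' = Phi^-1(HR) - Phi^-1(FAR)`, `C = -(Phi^-1(HR) + Phi^-1(FAR)) / 2`.
#' Rates must already be corrected away from 0 and 1 (the fitting code uses
#' the 1/(2N) replacement rule).
#'
#' @param HR Hit rate in (0, 1).
#' @param FAR False-alarm rate in (0, 1).
#' @return List with elements `d_prime` and `criterion`.
#' @export
sdt_from_rates <- function(HR, FAR) {
  if (!.is_prob(HR) || !.is_prob(FAR))
    .stopf("HR and FAR must lie strictly inside (0, 1); correct 0/1 rates first")
  zH <- qnorm(HR)
  zF <- qnorm(FAR)
  list(d_prime = zH - zF, criterion = -(zH + zF) / 2)
}

#' Predicted confidence in a recognition task
#'
#' Posterior probability that the type I response was correct, given
#' experience `e` and the response-specific belief mean. For S2 responses
#' this is `Phi((e P_exp + mu_b P_belief - C) / sqrt(P_belief))`; S1
#' responses mirror the experience axis (`e` enters negatively, the
#' criterion positively). With `criterion = 0` and an S2 response the
#' recall form is recovered.
#'
#' @param e Processing experience (vectorised).
#' @param response `"S1"` or `"S2"`.
#' @param mu_b_resp Belief mean attached to the given response.
#' @param sigma_l Likelihood SD (> 0).
#' @param criterion Type I criterion C.
#' @return Probability.
#' @export
predicted_confidence_recognition <- function(e, response, mu_b_resp, sigma_l,
                                             criterion = 0) {
  if (sigma_l <= 0) .stopf("sigma_l must be positive")
  response <- match.arg(response, c("S1", "S2"))
  P_exp <- experience_weight(sigma_l)
  P_b <- 1 - P_exp
  if (response == "S2")
    pnorm((e * P_exp + mu_b_resp * P_b - criterion) / sqrt(P_b))
  else
    pnorm((-e * P_exp + mu_b_resp * P_b + criterion) / sqrt(P_b))
}

#' Cell mean of the recognition confidence distribution
#'
#' Marginal (response-unconditioned) mean of
#' [predicted_confidence_recognition()] over `e ~ N(mu_e_stim, 1)` for a
#' given stimulus x response cell.
#'
#' @param mu_e_stim Experience mean of the stimulus shown.
#' @param mu_b_resp Belief mean attached to the response given.
#' @param P_exp Experience weight in (0, 1).
#' @param criterion Type I criterion C.
#' @param stimulus,response `"S1"` or `"S2"`.
#' @return Probability.
#' @export
mean_confidence_recognition <- function(mu_e_stim, mu_b_resp, P_exp,
                                        criterion = 0,
                                        stimulus = "S2", response = "S2") {
  if (!.is_prob(P_exp)) .stopf("P_exp must lie strictly inside (0, 1)")
  stimulus <- match.arg(stimulus, c("S1", "S2"))
  response <- match.arg(response, c("S1", "S2"))
  P_b <- 1 - P_exp
  den <- sqrt(1 - P_exp * P_b)
  if (response == "S2")
    pnorm((mu_e_stim * P_exp + mu_b_resp * P_b - criterion) / den)
  else
    pnorm((-mu_e_stim * P_exp + mu_b_resp * P_b + criterion) / den)
}

#' Canonical cell shift for the identifiable parameterisation
#'
#' The means mu_e and mu_b are not identifiable; the likelihood is
#' parameterised by the cell's mean confidence M_conf instead. Writing
#' `A = Phi^-1(M_conf)`, trial-level predicted confidence becomes
#' `Phi(shift + z * P_exp / sqrt(P_belief))` with `z` the standardised
#' experience deviation and `shift = A sqrt((1 - P_exp P_belief) /
#' P_belief)` the value returned here. Its marginal mean over
#' `z ~ N(0, 1)` is exactly `M_conf`.
#'
#' @param M_conf Cell mean confidence, strictly inside (0, 1).
#' @param P_exp Experience weight, strictly inside (0, 1).
#' @return The probit-scale shift.
#' @export
canonical_cell_shift <- function(M_conf, P_exp) {
  if (!.is_prob(M_conf)) .stopf("M_conf must lie strictly inside (0, 1)")
  if (!.is_prob(P_exp)) .stopf("P_exp must lie strictly inside (0, 1)")
  P_b <- 1 - P_exp
  qnorm(M_conf) * sqrt((1 - P_exp * P_b) / P_b)
}

# Canonical slope on z for trial-level predicted confidence.
.canonical_slope <- function(P_exp) {
  P_exp / sqrt(1 - P_exp)
}

#' Belief state for sequential updating
#'
#' Bundles the current belief distribution `N(mu_b_t, sigma_b_t^2)` with the
#' SD `sigma_lb` of the likelihood used for belief updating (typically much
#' larger than the confidence likelihood SD `sigma_l`, reflecting slow
#' belief revision).
#'
#' @param mu_b_t Current belief mean.
#' @param sigma_b_t Current belief SD (> 0).
#' @param sigma_lb Belief-update likelihood SD (> 0).
#' @return Object of class `bim_belief_state`.
#' @export
belief_state <- function(mu_b_t = 0, sigma_b_t = 1, sigma_lb = 10) {
  if (sigma_b_t <= 0 || sigma_lb <= 0)
    .stopf("sigma_b_t and sigma_lb must be positive")
  structure(list(mu_b_t = mu_b_t, sigma_b_t = sigma_b_t, sigma_lb = sigma_lb),
            class = "bim_belief_state")
}

#' One conjugate belief update
#'
#' Updates the belief distribution with one experience sample under the
#' belief-update likelihood `N(m-hat, sigma_lb^2)`:
#' mean `(sigma_lb^2 mu_b + sigma_b^2 e) / (sigma_lb^2 + sigma_b^2)`,
#' variance `sigma_b^2 sigma_lb^2 / (sigma_b^2 + sigma_lb^2)`. The belief SD
#' shrinks deterministically with every update.
#'
#' @param state A [belief_state()].
#' @param e Processing experience observed on this trial.
#' @return Updated `bim_belief_state`.
#' @export
update_belief <- function(state, e) {
  stopifnot(inherits(state, "bim_belief_state"))
  v_b <- state$sigma_b_t^2
  v_l <- state$sigma_lb^2
  belief_state(mu_b_t = (v_l * state$mu_b_t + v_b * e) / (v_l + v_b),
               sigma_b_t = sqrt(v_b * v_l / (v_b + v_l)),
               sigma_lb = state$sigma_lb)
}
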