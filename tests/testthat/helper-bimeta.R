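# Shared test fixtures (built in code; no stored data).

make_recall_trials <- function(outcome, confidence, scale = "continuous") {
  n <- length(outcome)
  data.frame(trial = seq_len(n), task = "recall", condition = NA_character_,
             stimulus = NA_character_, response = NA_character_,
             outcome = as.integer(outcome), confidence = confidence,
             scale = scale, stringsAsFactors = FALSE)
}

make_recognition_trials <- function(stimulus, response, confidence,
                                    scale = "discrete:4") {
  n <- length(stimulus)
  data.frame(trial = seq_len(n), task = "recognition",
             condition = NA_character_, stimulus = stimulus,
             response = response,
             outcome = as.integer(stimulus == response),
             confidence = confidence, scale = scale, stringsAsFactors = FALSE)
}

# Uniform draw helpers for property-style loops.
rand_recall_par <- function() {
  list(mu_m = runif(1, -2, 2), rho = runif(1, -0.9, 0.9),
       P_exp = runif(1, 0.1, 0.9), M_conf = runif(1, 0.1, 0.9))
}

# Single-trial continuous likelihood value (density at reported r, outcome y).
cont_L1 <- function(r, y, mu_m, rho, P_exp, M_conf) {
  nat <- bimeta:::.nat_recall(mu_m, rho, P_exp, M_conf)
  vapply(seq_along(r), function(i)
    exp(bimeta:::.cont_loglik_nat(r[i], y[i], nat)$loglik), numeric(1))
}
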