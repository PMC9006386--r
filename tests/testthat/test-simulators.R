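test_that("seed determinism and basic contracts", {
  p <- recall_params(0.2, 0.4, P_exp = 0.6, M_conf = 0.55)
  a <- simulate_recall(p, sim_config(50, "continuous", 123))
  b <- simulate_recall(p, sim_config(50, "continuous", 123))
  expect_identical(a, b)
  c <- simulate_recall(p, sim_config(50, "continuous", 124))
  expect_false(identical(a, c))
  expect_true(all(a$confidence >= 0 & a$confidence <= 1))
  d <- simulate_recall(p, sim_config(50, "discrete:5", 123))
  expect_true(all(d$confidence %in% 1:5))
  # simulator call does not disturb the caller's RNG stream
  set.seed(99); x1 <- rnorm(1)
  set.seed(99); invisible(simulate_recall(p, sim_config(5, seed = 1)))
  expect_identical(rnorm(1), x1)
})

test_that("recall marginals follow the model", {
  # extreme strength: all recalled
  p <- recall_params(5, 0, P_exp = 0.5, M_conf = 0.5)
  tt <- simulate_recall(p, sim_config(200, "continuous", 1))
  expect_true(all(tt$outcome == 1))
  # recalled fraction -> Phi(mu_m)
  for (mu in c(-0.8, 0, 1.1)) {
    p <- recall_params(mu, 0.3, P_exp = 0.5, M_conf = 0.5)
    tt <- simulate_recall(p, sim_config(1e5, "continuous", 42))
    se <- sqrt(pnorm(mu) * (1 - pnorm(mu)) / 1e5)
    expect_lt(abs(mean(tt$outcome) - pnorm(mu)), 3 * se)
  }
  # rho = 0: recalled and unrecalled trials share the confidence mean
  p <- recall_params(0, 0, P_exp = 0.6, M_conf = 0.6)
  tt <- simulate_recall(p, sim_config(1e5, "continuous", 7))
  m1 <- tt$confidence[tt$outcome == 1]
  m0 <- tt$confidence[tt$outcome == 0]
  se <- sqrt(var(m1) / length(m1) + var(m0) / length(m0))
  expect_lt(abs(mean(m1) - mean(m0)), 3 * se)
  # mean confidence matches the closed form when clamping is negligible
  expect_lt(abs(mean(tt$confidence) - 0.6), 3 * sd(tt$confidence) / sqrt(1e5))
})

test_that("recognition simulator follows SDT and the confidence model", {
  p0 <- recognition_params(0, 0, 0.4, P_exp = 0.5,
                           M_conf = c(0.5, 0.5, 0.5, 0.5))
  tt <- simulate_recognition(p0, sim_config(2e4, "continuous", 3))
  expect_lt(abs(mean(tt$response == "S2") - 0.5), 3 * sqrt(0.25 / 4e4))
  p3 <- recognition_params(3, 0, 0.4, P_exp = 0.5,
                           M_conf = c(0.6, 0.4, 0.4, 0.6))
  t3 <- simulate_recognition(p3, sim_config(2e4, "continuous", 3))
  acc <- pnorm(1.5)
  expect_lt(abs(mean(t3$outcome) - acc), 3 * sqrt(acc * (1 - acc) / 4e4))
  expect_true(all(t3$outcome == (t3$stimulus == t3$response)))
  # high rho raises confidence for correct AND incorrect trials
  base <- recognition_params(1, 0, 0, P_exp = 0.6,
                             M_conf = c(0.55, 0.45, 0.45, 0.55))
  hi <- recognition_params(1, 0, 0.85, P_exp = 0.6,
                           M_conf = c(0.55, 0.45, 0.45, 0.55))
  tb <- simulate_recognition(base, sim_config(3e4, "continuous", 5))
  th <- simulate_recognition(hi, sim_config(3e4, "continuous", 5))
  expect_gt(mean(th$confidence[th$outcome == 1]),
            mean(tb$confidence[tb$outcome == 1]) + 0.01)
  expect_gt(mean(th$confidence[th$outcome == 0]),
            mean(tb$confidence[tb$outcome == 0]) + 0.01)
})

test_that("discrete bin frequencies match the analytic cell probabilities", {
  # simulator <-> likelihood cross-oracle
  set.seed(31)
  for (k in 1:4) {
    pars <- rand_recall_par()
    p <- recall_params(pars$mu_m, pars$rho, P_exp = pars$P_exp,
                       M_conf = pars$M_conf)
    tt <- simulate_recall(p, sim_config(2e5, "discrete:7", 100 + k))
    cells <- bimeta:::.recall_cells(7, pars$mu_m, pars$rho, pars$P_exp,
                                    pars$M_conf)
    emp <- t(vapply(0:1, function(y) vapply(1:7, function(b)
      mean(tt$outcome == y & tt$confidence == b), numeric(1)), numeric(7)))
    se <- sqrt(pmax(cells * (1 - cells), 1e-12) / 2e5)
    expect_lt(max(abs(emp - cells) / pmax(se, 1e-5)), 3.8)
  }
  # recognition, one parameter set per stimulus table
  p2 <- recognition_params(1.1, -0.2, 0.4, P_exp = 0.55,
                           M_conf = c(0.65, 0.4, 0.35, 0.7))
  t2 <- simulate_recognition(p2, sim_config(1e5, "discrete:7", 9))
  cl <- bimeta:::.recog_cells(7, 0.55, 0.4, as.list(p2$M_conf), 1.1, -0.2)
  for (stim in c("S1", "S2")) {
    m <- cl[[tolower(stim)]]
    sel <- t2$stimulus == stim
    emp <- t(vapply(c("S1", "S2"), function(r) vapply(1:7, function(b)
      mean(t2$response[sel] == r & t2$confidence[sel] == b), numeric(1)),
      numeric(7)))
    se <- sqrt(pmax(m * (1 - m), 1e-12) / 1e5)
    expect_lt(max(abs(emp - m) / pmax(se, 1e-5)), 3.8)
  }
})

test_that("belief-updating simulator shows the expected dynamics", {
  # huge sigma_lb: belief trajectory is frozen
  frozen <- simulate_belief_updating(belief_state(0, 1, 1e6), 0.5, 1, 50,
                                     seed = 2)
  expect_lt(max(abs(frozen$trajectory$mu_b_post)), 1e-3)
  expect_gt(min(frozen$trajectory$sigma_b_post), 1 - 1e-3)
  # sigma_b decreases deterministically, faster for smaller sigma_lb
  s10 <- simulate_belief_updating(belief_state(0, 1, 10), 0.5, 1, 100, seed = 3)
  s20 <- simulate_belief_updating(belief_state(0, 1, 20), 0.5, 1, 100, seed = 3)
  expect_true(all(diff(s10$trajectory$sigma_b_post) < 0))
  expect_lt(s10$trajectory$sigma_b_post[100], s20$trajectory$sigma_b_post[100])
  # mu_b drifts up in expectation when mu_e > mu_b0 (average over runs)
  finals <- vapply(1:60, function(s)
    simulate_belief_updating(belief_state(0, 1, 10), 0.5, 1, 100,
                             seed = 1000 + s)$trajectory$mu_b_post[100],
    numeric(1))
  expect_gt(mean(finals), 0.1)
})
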