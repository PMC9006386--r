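test_that("experience weight and its complement", {
  expect_equal(experience_weight(1), 0.5)
  expect_equal(experience_weight(2), 0.2)
  expect_error(experience_weight(0), "positive")
  expect_error(experience_weight(-1), "positive")
  # P_exp + P_belief = 1 across sigma_l
  sl <- exp(seq(-3, 3, length.out = 25))
  expect_equal(experience_weight(sl) + sl^2 / (1 + sl^2), rep(1, 25))
  # sigma_l -> 0+ limit
  expect_gt(experience_weight(1e-8), 1 - 1e-12)
})

test_that("posterior over inferred strength is the conjugate update", {
  p <- posterior_strength(1, 0, 1, 1)
  expect_equal(p$mean, 0.5)
  expect_equal(p$variance, 0.5)
  # prior and data agree
  expect_equal(posterior_strength(0.3, 0.3, 2)$mean, 0.3)
  # weight on e equals the experience weight when sigma_b = 1
  for (sl in c(0.3, 1, 2.5)) {
    w <- experience_weight(sl)
    p <- posterior_strength(1, 0, sl)
    expect_equal(p$mean, w * 1 + (1 - w) * 0)
    expect_lt(p$variance, min(sl^2, 1))
  }
  # huge sigma_l: posterior collapses to the prior
  expect_lt(abs(posterior_strength(5, 0.2, 1e4)$mean - 0.2), 1e-6)
})

test_that("predicted recall confidence", {
  expect_equal(predicted_confidence_recall(0, 0, 1), 0.5)
  expect_equal(predicted_confidence_recall(sqrt(2), 0, 1), pnorm(1))
  expect_equal(predicted_confidence_recall(-sqrt(2), 0, 1), pnorm(-1))
  e <- seq(-3, 3, length.out = 50)
  expect_true(all(diff(predicted_confidence_recall(e, 0.4, 0.7)) > 0))
  # generalized belief-state confidence reduces to the closed form at
  # sigma_b = 1, threshold 0
  for (k in 1:10) {
    e <- rnorm(1); mu_b <- rnorm(1); sl <- exp(rnorm(1) / 2)
    p <- posterior_strength(e, mu_b, sl, 1)
    expect_equal(pnorm(p$mean / sqrt(p$variance)),
                 predicted_confidence_recall(e, mu_b, sl), tolerance = 1e-13)
  }
})

test_that("mean recall confidence matches closed form and MC oracle", {
  expect_equal(mean_confidence_recall(0, 0, 0.5), 0.5)
  expect_equal(mean_confidence_recall(1, 0, 0.5), pnorm(0.5 / sqrt(0.75)))
  expect_error(mean_confidence_recall(0, 0, 1), "inside")
  set.seed(41)
  for (k in 1:3) {
    mu_e <- runif(1, -1, 1); mu_b <- runif(1, -1, 1); P <- runif(1, 0.1, 0.9)
    sl <- sqrt((1 - P) / P)
    e <- rnorm(1e6, mu_e, 1)
    mc <- mean(predicted_confidence_recall(e, mu_b, sl))
    se <- sd(predicted_confidence_recall(e, mu_b, sl)) / 1e3
    expect_lt(abs(mc - mean_confidence_recall(mu_e, mu_b, P)), 3 * se)
  }
})

test_that("unit-scale criteria and the experience-scale mapping", {
  expect_equal(confidence_criteria_unit(5), c(0.2, 0.4, 0.6, 0.8))
  expect_equal(confidence_criteria_unit(2), 0.5)
  expect_equal(confidence_criteria_unit(7), (1:6) / 7)
  expect_error(confidence_criteria_unit(1), ">= 2")
  expect_equal(criteria_on_experience(2, 0, 1.3), 0)
  # shifting mu_b moves criteria down linearly with slope -sigma_l^2
  c1 <- criteria_on_experience(5, 0, 1.5)
  c2 <- criteria_on_experience(5, 1, 1.5)
  expect_equal(c2 - c1, rep(-1.5^2, 4))
  # round trip is exact to machine precision
  set.seed(7)
  for (k in 1:20) {
    n <- sample(2:9, 1); mu_b <- rnorm(1); sl <- exp(rnorm(1) / 2)
    ce <- criteria_on_experience(n, mu_b, sl)
    expect_equal(predicted_confidence_recall(ce, mu_b, sl),
                 seq_len(n - 1) / n, tolerance = 1e-14)
  }
})

test_that("SDT parameters from rates", {
  expect_equal(sdt_from_rates(0.6, 0.6)$d_prime, 0)
  s <- sdt_from_rates(pnorm(1), pnorm(-1))
  expect_equal(s$d_prime, 2)
  expect_equal(s$criterion, 0)
  s2 <- sdt_from_rates(pnorm(0.5), 0.5)
  expect_equal(s2$d_prime, 0.5)
  expect_equal(s2$criterion, -0.25)
  expect_error(sdt_from_rates(1, 0.5), "inside")
  expect_error(sdt_from_rates(0.5, 0), "inside")
})

test_that("recognition confidence forms", {
  # criterion 0, S2 response reduces to the recall form
  for (k in 1:5) {
    e <- rnorm(1); mu_b <- rnorm(1); sl <- exp(rnorm(1) / 3)
    expect_equal(predicted_confidence_recognition(e, "S2", mu_b, sl, 0),
                 predicted_confidence_recall(e, mu_b, sl))
    # mirror symmetry with equal belief means
    expect_equal(predicted_confidence_recognition(e, "S1", mu_b, sl, 0),
                 predicted_confidence_recognition(-e, "S2", mu_b, sl, 0))
  }
  expect_equal(mean_confidence_recognition(0, 0, 0.5, 0, "S1", "S1"), 0.5)
  # swapping stimulus sign and response label leaves the value invariant
  expect_equal(
    mean_confidence_recognition(0.7, 0.2, 0.6, 0, "S2", "S2"),
    mean_confidence_recognition(-0.7, 0.2, 0.6, 0, "S1", "S1"))
  # marginal-mean identity against MC over e
  set.seed(13)
  mu_e <- 0.4; mu_b <- -0.2; P <- 0.6; C <- 0.3
  sl <- sqrt((1 - P) / P)
  e <- rnorm(1e6, mu_e, 1)
  for (resp in c("S1", "S2")) {
    v <- predicted_confidence_recognition(e, resp, mu_b, sl, C)
    expect_lt(abs(mean(v) -
                    mean_confidence_recognition(mu_e, mu_b, P, C, "S2", resp)),
              3 * sd(v) / 1e3)
  }
})

test_that("canonical cell shift reproduces M_conf as a marginal mean", {
  expect_equal(canonical_cell_shift(0.5, 0.3), 0)
  set.seed(21)
  z <- rnorm(1e6)
  for (k in 1:20) {
    M <- runif(1, 0.05, 0.95); P <- runif(1, 0.05, 0.95)
    a <- canonical_cell_shift(M, P)
    b <- P / sqrt(1 - P)
    # analytic marginal: E Phi(a + b z) = Phi(a / sqrt(1 + b^2))
    expect_equal(pnorm(a / sqrt(1 + b^2)), M, tolerance = 1e-12)
    if (k <= 3) {
      v <- pnorm(a + b * z)
      expect_lt(abs(mean(v) - M), 3 * sd(v) / 1e3)
    }
  }
  # P_exp limits: variance maximal near 1, degenerate near 0
  z5 <- rnorm(5e3)
  v_hi <- var(pnorm(canonical_cell_shift(0.6, 0.95) + 0.95 / sqrt(0.05) * z5))
  v_lo <- var(pnorm(canonical_cell_shift(0.6, 0.05) + 0.05 / sqrt(0.95) * z5))
  expect_gt(v_hi, 10 * v_lo)
  expect_error(canonical_cell_shift(0, 0.5), "inside")
})

test_that("belief updating is the conjugate normal-normal rule", {
  st <- belief_state(0, 1, 10)
  up <- update_belief(st, 1)
  expect_equal(up$mu_b_t, 1 / 101)
  expect_equal(up$sigma_b_t^2, 100 / 101)
  # e at the current mean: mean unchanged, SD shrinks
  up2 <- update_belief(st, 0)
  expect_equal(up2$mu_b_t, 0)
  expect_lt(up2$sigma_b_t, st$sigma_b_t)
  # enormous sigma_lb: state essentially unchanged
  up3 <- update_belief(belief_state(0.3, 0.8, 1e6), 5)
  expect_lt(abs(up3$mu_b_t - 0.3), 1e-8)
  expect_lt(abs(up3$sigma_b_t - 0.8), 1e-8)
})
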