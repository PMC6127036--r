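test_that("the parametric initial prior is built and normalised correctly", {
  expect_equal(make_prior(1, 1), rep(1 / 6, 6))
  expect_equal(make_prior(0, 0), c(0, 0, 0.5, 0.5, 0, 0))
  expect_equal(make_prior(2, 4), c(4, 2, 1, 1, 2, 4) / 14)
  expect_error(make_prior(-1, 1), "nonnegative")
})

test_that("expected base rate and belief read out p(B) correctly", {
  expect_equal(expected_base_rate(rep(1 / 6, 6)), 0.5)
  expect_equal(expected_base_rate(c(0, 0, 0, 0, 1, 0)), 0.8)
  tri <- c(0, 1, 2, 3, 4, 5) / 15
  expect_equal(expected_base_rate(tri), 11 / 15)
  expect_equal(belief_rightward(tri), 0.8) # (3+4+5)/15
  expect_equal(belief_rightward(rep(1 / 6, 6)), 0.5)
  expect_equal(belief_rightward(c(0, 1, 0, 0, 0, 0)), 0)
  expect_identical(prior_direction_R, expected_base_rate)
})

test_that("direction posterior combines prior and counterfactual", {
  expect_lt(abs(direction_posterior(0.7, 0.57) - 0.75), 0.01)
  expect_equal(direction_posterior(0.5, 0.5), 0.5)
  expect_equal(direction_posterior(0.7, 0.5), 0.7)
  expect_error(direction_posterior(1, 0), "0/0")
})

test_that("the update evidence nu_r follows each rule", {
  expect_equal(compute_nu("bayesian", "R", pu_R = 0.62), 0.62)
  expect_equal(compute_nu("choice_only", "L"), 0)
  expect_equal(compute_nu("choice_only", "R"), 1)
  expect_equal(compute_nu("choice_confidence", "L", conf = 0.8), 0.2)
  set.seed(20)
  for (i in 1:200) {
    ch <- sample(c("L", "R"), 1)
    cf <- runif(1, 0.5, 1)
    pu <- runif(1)
    pr <- runif(1, 0.1, 0.9)
    expect_equal(compute_nu("mixture", ch, cf, pu, pr, beta_mix = 1),
                 compute_nu("bayesian", ch, cf, pu, pr))
    expect_equal(compute_nu("mixture", ch, cf, pu, pr, beta_mix = 0),
                 compute_nu("choice_confidence", ch, cf, pu, pr))
  }
  expect_error(compute_nu("mixture", "R", 0.7, 0.6, 0.5), "beta_mix")
  expect_error(compute_nu("empirical", "R", 0.7, 0.6, 0.5), "empirical_betas")
})

test_that("the p(B) update is the linear-in-B multiplicative rule", {
  pB <- c(0.125, 0.125, 0.25, 0.25, 0.125, 0.125) # exactly normalised
  expect_identical(update_base_rate(pB, 0.5), pB) # no-op, bit-identical
  u <- update_base_rate(rep(1 / 6, 6), 1)
  expect_equal(u, c(0, 1, 2, 3, 4, 5) / 15)
  expect_equal(update_base_rate(rep(1 / 6, 6), 0), rev(u))
  expect_error(update_base_rate(c(1, 0, 0, 0, 0, 0), 1), "degenerate")
})

test_that("sequential updating equals the one-shot batch posterior", {
  set.seed(21)
  for (rep in 1:20) {
    p0 <- make_prior(runif(1, 0, 3), runif(1, 0, 3))
    nus <- runif(12)
    seq_p <- p0
    for (nu in nus) seq_p <- update_base_rate(seq_p, nu)
    batch <- p0
    for (nu in nus) {
      batch <- batch * (BASE_RATES * nu + (1 - BASE_RATES) * (1 - nu))
    }
    batch <- batch / sum(batch)
    expect_lt(max(abs(seq_p - batch)), 1e-10)
  }
})

test_that("Bayesian updating is a martingale under its own predictive", {
  maps <- default_maps()
  pB <- update_base_rate(make_prior(1, 0.5), 0.8)
  EB <- expected_base_rate(pB)
  set.seed(22)
  n <- 4e4
  # predictive: direction ~ E[B], coherence uniform, duration from the task
  sgn <- ifelse(runif(n) < EB, 1, -1)
  mag <- sample(COHERENCES, n, replace = TRUE)
  ap <- accumulator_params(kappa = 14, bound_A = 1.2)
  sim <- simulate_trial_evidence(ap, sgn * mag, sample_duration(n), n = n)
  pu <- vapply(seq_len(n), function(i) {
    if (sim$bound_hit[i]) {
      k <- min(max(round(sim$te[i] / maps$dt), 1), length(maps$pu_top))
      if (sim$e[i] > 0) maps$pu_top[k] else maps$pu_bot[k]
    } else {
      k <- min(max(round(sim$te[i] / maps$dt), 1), ncol(maps$pu))
      j <- min(max(round((sim$e[i] + 1.2) / maps$de), 1), nrow(maps$pu))
      maps$pu[j, k]
    }
  }, numeric(1))
  upd <- vapply(pu, function(u) update_base_rate(pB, u), numeric(6))
  avg <- rowMeans(upd)
  mc_se <- apply(upd, 1, sd) / sqrt(n)
  expect_true(all(abs(avg - pB) < 4 * mc_se + 1e-3))
})

test_that("lag filters behave at their limits and in between", {
  expect_equal(lag_report(0.9, 0.5, 0), 0.9)
  expect_equal(lag_report(1, 0.5, 0.5), 0.75)
  expect_lt(abs(lag_report(0.9, 0.5, 1 - 1e-9) - 0.5), 1e-8)
  p1 <- make_prior(1, 1)
  p2 <- update_base_rate(p1, 0.9)
  expect_equal(lag_update_pB(p1, p2, 0), p2)
  expect_equal(lag_update_pB(p1, p2, 0.5), (p1 + p2) / 2)
  set.seed(23)
  for (i in 1:20) {
    a <- runif(1)
    pa <- make_prior(runif(1, 0, 2), runif(1, 0, 2))
    pb <- update_base_rate(pa, runif(1))
    expect_equal(sum(lag_update_pB(pa, pb, a)), 1)
  }
})

test_that("observer simulation is reproducible and needs matching maps", {
  des <- generate_experiment(5, seed = 30)
  p <- default_params()
  s1 <- simulate_observer(des, p, default_maps(), seed = 7)
  s2 <- simulate_observer(des, p, default_maps(), seed = 7)
  expect_identical(s1, s2)
  expect_error(
    simulate_observer(des, observer_params(kappa = 10), default_maps()),
    "different kappa")
})

test_that("accuracy approaches ceiling in fully biased easy blocks", {
  des <- do.call(rbind, lapply(1:30, function(b) {
    data.frame(subject_id = "s1", block_id = b, trial_index = 1:25,
               base_rate = 1, coherence_signed = 0.512,
               duration_s = 0.6, direction = "R")
  }))
  sim <- simulate_observer(des, default_params(), default_maps(), seed = 8)
  late <- sim$trial_index > 15
  expect_gt(mean(sim$choice[late] == "R"), 0.99)
})

test_that("confidence grows with motion strength under a neutral prior", {
  des <- single_trial_design(6000, seed = 31)
  p <- observer_params(kappa = 14, bound_A = 1.2, omega1 = 1, omega2 = 1)
  sim <- simulate_observer(des, p, default_maps(), seed = 9)
  correct <- sim$choice == sim$direction
  m <- tapply(sim$confidence_raw[correct],
              abs(sim$coherence_signed)[correct], mean)
  expect_true(all(diff(m) > 0))
})

test_that("end-of-block belief is ordered by base rate", {
  sim <- make_obs_data(240, seed = 32)
  last <- !duplicated(sim$block_id, fromLast = TRUE)
  m <- tapply(sim$belief_report[last], sim$base_rate[last], mean)
  expect_true(all(diff(m) > 0))
})
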