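test_that("confidence binarisation labels the lowest 30% as low", {
  conf <- seq(0.51, 0.96, by = 0.05) # 10 distinct values
  cat10 <- binarize_confidence(conf)
  expect_equal(sum(cat10 == "low"), 3)
  expect_equal(cat10[order(conf)][1:3], rep("low", 3))
  expect_warning(allhi <- binarize_confidence(rep(0.8, 12)), "identical")
  expect_true(all(allhi == "high"))
  expect_error(binarize_confidence(c(0.6, 0.7)), "at least 10")
  # the quantile is per call (per subject), not pooled
  lo_subj <- binarize_confidence(seq(0.5, 0.59, by = 0.01))
  hi_subj <- binarize_confidence(seq(0.9, 0.99, by = 0.01))
  expect_equal(mean(lo_subj == "low"), mean(hi_subj == "low"))
})

test_that("the confidence transformation is a rank-preserving requantile", {
  set.seed(40)
  raw <- runif(200, 0.5, 1)
  sim <- rbeta(200, 5, 2) / 2 + 0.5
  tr <- transform_confidence(raw, sim)
  expect_equal(cor(raw, tr, method = "spearman"), 1)
  expect_equal(sort(tr), sort(sim)) # identical distributions
  # ties collapse to the mean of their simulated band, weakly monotone
  raw_t <- c(0.6, 0.6, 0.7, 0.8, 0.8, 0.9)
  sim_t <- c(0.51, 0.55, 0.61, 0.72, 0.80, 0.95)
  tr_t <- transform_confidence(raw_t, sim_t)
  expect_equal(tr_t[1], tr_t[2])
  expect_equal(tr_t[1], mean(c(0.51, 0.55)))
  expect_true(all(diff(tr_t[order(raw_t)]) >= 0))
  expect_error(transform_confidence(raw, sim[-1]), "size mismatch")
})

test_that("counterfactual inversion is the exact inverse of the posterior", {
  set.seed(41)
  x <- runif(1000, 0.001, 0.999)
  p <- runif(1000, 0.01, 0.99)
  back <- invert_confidence_to_counterfactual(direction_posterior(x, p), p,
                                              eps = 1e-12)
  expect_lt(max(abs(back - x)), 1e-9)
  expect_equal(invert_confidence_to_counterfactual(0.57, 0.57), 0.5)
  # the worked example run backwards
  expect_lt(abs(invert_confidence_to_counterfactual(0.7557, 0.57) - 0.70),
            0.01)
  # endpoint reports are clipped, not infinite
  expect_true(is.finite(invert_confidence_to_counterfactual(1, 0.5)))
})

test_that("the four outcome masses are a probability distribution", {
  maps <- default_maps()
  set.seed(42)
  for (i in 1:20) {
    pB <- update_base_rate(make_prior(runif(1, 0, 3), runif(1, 0, 3)),
                           runif(1))
    m <- trial_joint_likelihood(sample(c(-1, 1), 1) * sample(COHERENCES, 1),
                                runif(1, 0.1, 0.9), pB,
                                runif(1, 0.55, 0.95), maps)
    expect_true(all(m >= 0))
    expect_lt(abs(sum(m) - 1), 1e-8)
  }
  # as phi drops to 0.5 the low-confidence region empties
  mlo <- trial_joint_likelihood(0.128, 0.6, make_prior(1, 1), 0.5001, maps)
  expect_lt(mlo[["R_low"]] + mlo[["L_low"]], 0.01)
})

test_that("outcome masses match observed frequencies from simulation", {
  maps <- default_maps()
  pB0 <- make_prior(1, 0.5)
  m <- trial_joint_likelihood(0.128, 0.5, pB0, 0.8, maps)
  des <- data.frame(subject_id = "s", block_id = seq_len(3e4),
                    trial_index = 1L, base_rate = 0.6,
                    coherence_signed = 0.128, duration_s = 0.5)
  sim <- simulate_observer(des, default_params(), maps, seed = 43)
  f <- c(mean(sim$choice == "R" & sim$confidence_category == "high"),
         mean(sim$choice == "R" & sim$confidence_category == "low"),
         mean(sim$choice == "L" & sim$confidence_category == "high"),
         mean(sim$choice == "L" & sim$confidence_category == "low"))
  expect_true(all(abs(f - m) < 3 * sqrt(m * (1 - m) / 3e4) + 1e-4))
})

test_that("the dataset log-likelihood is additive and reduces correctly", {
  maps <- fitting_maps()
  p <- default_params()
  sim <- make_obs_data(12, seed = 44, maps = default_maps())
  ll1 <- dataset_loglik(sim, p, maps)
  doubled <- rbind(sim, transform(sim, block_id = block_id + 1000L))
  ll2 <- dataset_loglik(doubled, p, maps)
  expect_equal(ll2$loglik, 2 * ll1$loglik)
  # forced nu_r = 0.5 keeps p(B) at p0; per-trial masses equal the
  # neutral-prior masses computed independently per trial
  p00 <- observer_params(kappa = 14, bound_A = 1.2, phi = 0.8,
                         omega1 = 0, omega2 = 0)
  llc <- dataset_loglik(sim, p00, maps,
                        conf_trans = rep(0.5, nrow(sim)), eps_clip = 1e-12)
  pB0 <- make_prior(0, 0)
  ref <- vapply(seq_len(nrow(sim)), function(i) {
    m <- trial_joint_likelihood(sim$coherence_signed[i], sim$duration_s[i],
                                pB0, 0.8, maps)
    idx <- paste0(sim$choice[i], "_",
                  ifelse(sim$confidence_category[i] == "high", "high",
                         "low"))
    log(m[[idx]])
  }, numeric(1))
  expect_lt(max(abs(llc$per_trial - ref)), 1e-10)
})

test_that("the generating parameters dominate perturbed ones in likelihood", {
  sim <- make_obs_data(80, seed = 45)
  ll <- function(kappa) {
    mp <- build_likelihood_maps(accumulator_params(kappa, 1.2,
                                                   dt_map = 2e-3,
                                                   n_bins = 255L))
    dataset_loglik(sim, observer_params(kappa = kappa), mp)$loglik
  }
  expect_gt(ll(14), ll(14 * 1.25))
  expect_gt(ll(14), ll(14 * 0.75))
})

test_that("fitted likelihood is stable under halving the grid resolution", {
  sim <- make_obs_data(60, seed = 46)
  prof <- function(dt, nb) {
    ks <- seq(11, 18, by = 0.5)
    v <- vapply(ks, function(k) {
      mp <- build_likelihood_maps(accumulator_params(k, 1.2, dt_map = dt,
                                                     n_bins = nb))
      dataset_loglik(sim, observer_params(kappa = k), mp)$loglik
    }, numeric(1))
    # continuous argmax by quadratic interpolation around the grid max
    i <- which.max(v)
    i <- min(max(i, 2), length(v) - 1)
    ks[i] + 0.5 * 0.5 * (v[i - 1] - v[i + 1]) /
      (v[i - 1] - 2 * v[i] + v[i + 1])
  }
  k_fine <- prof(2e-3, 255L)
  k_coarse <- prof(4e-3, 127L)
  expect_lt(abs(k_fine - k_coarse) / k_fine, 0.02)
})

test_that("the mixture weight profiles to the Bayesian end on Bayesian data", {
  sim <- make_obs_data(60, seed = 47)
  maps <- fitting_maps()
  betas <- seq(0, 1, by = 0.1)
  ll <- vapply(betas, function(b) {
    p <- observer_params(kappa = 14, bound_A = 1.2, phi = 0.8, omega1 = 1,
                         omega2 = 0.5, model = "mixture", beta_mix = b)
    dataset_loglik(sim, p, maps)$loglik
  }, numeric(1))
  expect_gte(betas[which.max(ll)], 0.9)
})

test_that("fitting is deterministic for a fixed seed and dataset", {
  sim <- make_obs_data(8, seed = 48)
  f1 <- fit_observer(sim, "bayesian", n_starts = 2, seed = 5, maxit = 25)
  f2 <- fit_observer(sim, "bayesian", n_starts = 2, seed = 5, maxit = 25)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$logLik, f2$logLik)
  expect_equal(f1$n_params, 5)
  expect_equal(f1$AIC, 2 * 5 - 2 * f1$logLik)
  expect_equal(f1$BIC, 5 * log(nrow(sim)) - 2 * f1$logLik)
})

test_that("model comparison reports deltas against the best model", {
  sim <- make_obs_data(8, seed = 49)
  f1 <- fit_observer(sim, "bayesian", n_starts = 1, seed = 5, maxit = 20)
  f2 <- fit_observer(sim, "choice_only", n_starts = 1, seed = 5, maxit = 20)
  cmp <- compare_models(f1, f2)
  expect_equal(nrow(cmp), 2)
  expect_equal(cmp$dLogLik[1], 0)
  expect_true(all(cmp$dLogLik >= 0))
  # equal parameter counts: logLik ordering equals AIC/BIC ordering
  expect_equal(order(-cmp$logLik), order(cmp$AIC))
  other <- make_obs_data(9, seed = 50)
  f3 <- fit_observer(other, "bayesian", n_starts = 1, seed = 5, maxit = 20)
  expect_error(compare_models(f1, f3), "same dataset")
  # AIC against hand arithmetic
  expect_equal(compare_models(f1, f1)$AIC[1], 2 * 5 - 2 * f1$logLik)
})

test_that("the report-lag constant is recovered from lagged sequences", {
  sim <- make_obs_data(40, seed = 51)
  b <- sim$belief # no-lag belief sequence
  lagged <- apply_lag_for_test(b, 0.6, sim$block_id)
  est <- fit_lag_alpha(lagged, b, sim$block_id)
  expect_lt(abs(est$alpha - 0.6), 0.1)
  # reports identical to predictions: alpha is exactly zero
  est0 <- fit_lag_alpha(b, b, sim$block_id)
  expect_identical(est0$alpha, 0)
  expect_identical(est0$fitted, b)
  # flat reports at 0.5 push alpha to the upper boundary
  estf <- fit_lag_alpha(rep(0.5, length(b)), b, sim$block_id)
  expect_gt(estf$alpha, 0.95)
})
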