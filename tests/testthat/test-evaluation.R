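test_that("belief prediction reduces to a single simulation at n_sim = 1", {
  sim <- make_obs_data(6, seed = 60)
  fit <- fixed_fit(sim)
  pred <- predict_beliefs(fit, n_sim = 1, seed = 77)
  mapsf <- fitting_maps()
  set.seed(77)
  ref <- simulate_observer(sim, default_params(), mapsf)
  expect_identical(pred$mean_trajectory, ref$belief_report)
  is_last <- !duplicated(sim$block_id, fromLast = TRUE)
  expect_identical(unname(pred$end_mean), ref$belief_report[is_last])
})

test_that("predicted belief starts neutral and separates by base rate", {
  sim <- make_obs_data(60, seed = 61)
  fit <- fixed_fit(sim)
  pred <- predict_beliefs(fit, n_sim = 30, seed = 78)
  first <- !duplicated(sim$block_id)
  # mean belief after the first trial is near 0.5 under the symmetric prior
  expect_lt(abs(mean(pred$mean_trajectory[first]) - 0.5), 0.05)
  is_last <- !duplicated(sim$block_id, fromLast = TRUE)
  br <- sim$base_rate[is_last]
  if (any(br == 1) && any(br == 0.6)) {
    expect_gt(mean(pred$end_mean[br == 1]), mean(pred$end_mean[br == 0.6]))
  }
})

test_that("end-of-block MSE behaves as a proper alignment-checked error", {
  sim <- make_obs_data(40, seed = 62)
  is_last <- !duplicated(sim$block_id, fromLast = TRUE)
  reports <- sim$belief_report[is_last]
  expect_equal(end_of_block_mse(reports, reports), 0)
  expect_error(end_of_block_mse(reports[-1], reports), "alignment")
  # destroying the block pairing (label permutation) increases the error
  set.seed(63)
  perm <- sample(length(reports))
  expect_gt(end_of_block_mse(reports[perm], reports),
            end_of_block_mse(reports, reports))
})

test_that("paired belief-MSE comparison favours the generating model", {
  sim <- make_obs_data(60, seed = 64)
  fits <- list(fixed_fit(sim, "bayesian"),
               fixed_fit(sim, "choice_only"))
  cmp <- compare_belief_mse(fits, sim, n_rep = 40, seed = 65)
  expect_equal(dim(cmp$mse), c(40L, 2L))
  # antisymmetry of the pairwise comparison
  expect_equal(cmp$p_lower["bayesian", "choice_only"] +
                 cmp$p_lower["choice_only", "bayesian"] +
                 mean(cmp$mse[, 1] == cmp$mse[, 2]), 1)
  # the generating (bayesian) model predicts its own beliefs better
  expect_gt(cmp$p_lower["bayesian", "choice_only"], 0.5)
})

test_that("choice-bias regression recovers a known logistic model", {
  set.seed(66)
  des <- generate_experiment(120, seed = 66)
  # generate choices from a known logistic choice-bias model tied to B
  b1 <- 8; b2 <- 10
  bias <- (des$base_rate - 0.5) * 2
  eta <- b1 * des$duration_s * des$coherence_signed +
    b2 * des$coherence_signed + bias
  des$choice <- ifelse(runif(nrow(des)) < plogis(eta), "R", "L")
  reg <- run_regression("choice_bias", des)
  ct <- reg$coefficients
  bias_terms <- ct[grep("^bias_B", ct$term), ]
  truth <- (as.numeric(sub("bias_B", "", bias_terms$term)) - 0.5) * 2
  expect_true(all(abs(bias_terms$estimate - truth) < 2.5 * bias_terms$se))
  expect_true(all(diff(bias_terms$estimate) > 0)) # monotone in base rate
  expect_lt(reg$lrt$p, 1e-6)
})

test_that("choice-bias LRT holds its size when the base rate is inert", {
  set.seed(67)
  n_sig <- 0
  for (r in 1:10) {
    des <- generate_experiment(40, seed = 670 + r)
    eta <- 8 * des$duration_s * des$coherence_signed +
      10 * des$coherence_signed
    des$choice <- ifelse(runif(nrow(des)) < plogis(eta), "R", "L")
    reg <- run_regression("choice_bias", des)
    if (reg$lrt$p < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 2)
})

test_that("bayesian-observer data show the printed regression signatures", {
  sim <- make_obs_data(150, seed = 68)
  # near-perfect separation at the strongest coherences is expected here
  reg_bias <- suppressWarnings(run_regression("choice_bias", sim))
  bias <- reg_bias$coefficients[grep("^bias_B", reg_bias$coefficients$term), ]
  expect_true(all(diff(bias$estimate) > 0))
  expect_lt(reg_bias$lrt$p, 1e-4)
  # confidence rises with |c| and with the base rate toward the choice
  reg_conf <- run_regression("confidence_strength", sim)
  ct <- reg_conf$coefficients
  expect_gt(ct$estimate[ct$term == "absc"], 0)
  expect_gt(ct$estimate[ct$term == "Bsr"], 0)
  expect_lt(ct$p[ct$term == "Bsr"], 0.01)
})

test_that("accuracy and confidence courses build and strengthen with trials", {
  sim <- make_obs_data(150, seed = 69)
  reg_acc <- run_regression("accuracy_course", sim, max_trial = 25)
  b6 <- reg_acc$coefficients[grep("^Bs_trial", reg_acc$coefficients$term), ]
  ord <- order(as.integer(sub("Bs_trial", "", b6$term)))
  b6 <- b6[ord, ]
  early <- mean(b6$estimate[1:3])
  late <- mean(b6$estimate[10:15])
  expect_gt(late, early)
  reg_hc <- run_regression("highconf_course", sim, max_trial = 25)
  b9 <- reg_hc$coefficients[grep("^Bsr_trial", reg_hc$coefficients$term), ]
  ord <- order(as.integer(sub("Bsr_trial", "", b9$term)))
  b9 <- b9[ord, ]
  expect_gt(mean(b9$estimate[10:15]), mean(b9$estimate[1:3]))
})

test_that("delta-belief regression is invariant to mirror reflection", {
  sim <- make_obs_data(80, seed = 70)
  mirror <- sim
  mirror$choice <- ifelse(sim$choice == "R", "L", "R")
  mirror$direction <- ifelse(sim$direction == "R", "L", "R")
  mirror$coherence_signed <- -sim$coherence_signed
  mirror$belief_report <- 1 - sim$belief_report
  mirror$base_rate <- 1 - sim$base_rate
  r1 <- run_regression("delta_belief", sim)
  r2 <- run_regression("delta_belief", mirror)
  expect_equal(r1$coefficients$estimate, r2$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("belief-consistent choices strengthen with base-rate extremity", {
  sim <- make_obs_data(400, seed = 71)
  reg <- run_regression("belief_consistency", sim)
  ct <- reg$coefficients
  expect_gt(ct$estimate[ct$term == "Bs"], 0)
  tiny <- make_obs_data(5, seed = 72)
  tiny$belief_report <- 0.5 # never near-certain: nothing is eligible
  expect_error(run_regression("belief_consistency", tiny), "insufficient")
})

test_that("zero-coherence diagnostics separate lagged from no-lag reports", {
  sim0 <- make_obs_data(400, seed = 73)
  d0 <- zero_coherence_diagnostics(sim0)
  # no-lag Bayesian observer: flat profile near zero
  expect_true(all(abs(d0$by_belief$mean_change) <
                    4 * d0$by_belief$se + 0.005))
  pl <- default_params(alpha_lag = 0.6)
  siml <- make_obs_data(400, seed = 73, params = pl)
  dl <- zero_coherence_diagnostics(siml)
  # lagged reports keep drifting toward the previously held belief
  slope0 <- coef(lm(mean_change ~ belief_mid, d0$by_belief))[2]
  slopel <- coef(lm(mean_change ~ belief_mid, dl$by_belief))[2]
  expect_gt(slopel, slope0 + 0.02)
  expect_gt(slopel, 0)
  expect_error(zero_coherence_diagnostics(make_obs_data(5, seed = 74)),
               "insufficient")
})

test_that("counterfactual diagnostic crosses zero at pu = 0.5 without lag", {
  sim <- make_obs_data(250, seed = 75, keep_latent = TRUE)
  fit <- fixed_fit(sim)
  d <- zero_coherence_diagnostics(sim, fit = fit)
  expect_true(!is.null(d$by_counterfactual))
  for (ch in c("L", "R")) {
    cc <- d$by_counterfactual[d$by_counterfactual$choice == ch, ]
    near <- abs(cc$pu - 0.5) < 0.02
    if (any(near)) expect_lt(abs(mean(cc$change_smoothed[near])), 0.05)
  }
})
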