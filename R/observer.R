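#' Observer parameters
#'
#' The five core parameters shared by all update rules -- `kappa` and
#' `bound_A` (accumulator), `phi` (criterion on probability correct that
#' separates high from low confidence), and `omega1`, `omega2` (initial
#' prior over base rates) -- plus the rule-specific extras: `beta_mix` for
#' the mixture rule, `empirical_betas` (5 coefficients) for the empirical
#' rule, and the two optional first-order lags, `alpha_lag` on the belief
#' report only and `alpha_lag_pB` on the p(B) update itself.
#'
#' @param kappa,bound_A accumulator parameters (see [accumulator_params()]).
#' @param phi confidence criterion in `(0.5, 1]`.
#' @param omega1 prior weight on base rates 0.2 and 0.8 (>= 0).
#' @param omega2 prior weight on base rates 0 and 1 (>= 0).
#' @param model update rule.
#' @param beta_mix mixture weight on the counterfactual term, `[0, 1]`.
#' @param empirical_betas five coefficients of the empirical logistic rule.
#' @param alpha_lag lag on the belief report, `[0, 1)`.
#' @param alpha_lag_pB lag on the p(B) update (non-Bayesian variant).
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(kappa = 14, bound_A = 1.2, phi = 0.8,
                            omega1 = 1, omega2 = 0.5,
                            model = c("bayesian", "choice_only",
                                      "choice_confidence", "empirical",
                                      "mixture"),
                            beta_mix = NULL, empirical_betas = NULL,
                            alpha_lag = 0, alpha_lag_pB = 0) {
  model <- match.arg(model)
  stopifnot(kappa > 0, bound_A > 0, phi > 0.5, phi <= 1,
            omega1 >= 0, omega2 >= 0,
            alpha_lag >= 0, alpha_lag < 1, alpha_lag_pB >= 0,
            alpha_lag_pB < 1)
  if (model == "mixture") {
    if (is.null(beta_mix)) stop("mixture model requires beta_mix")
    stopifnot(beta_mix >= 0, beta_mix <= 1)
  }
  if (model == "empirical") {
    if (is.null(empirical_betas) || length(empirical_betas) != 5) {
      stop("empirical model requires 5 empirical_betas")
    }
  }
  structure(list(kappa = kappa, bound_A = bound_A, phi = phi,
                 omega1 = omega1, omega2 = omega2, model = model,
                 beta_mix = beta_mix, empirical_betas = empirical_betas,
                 alpha_lag = alpha_lag, alpha_lag_pB = alpha_lag_pB),
            class = "observer_params")
}

model_code <- function(model) {
  match(model, c("bayesian", "choice_only", "choice_confidence",
                 "empirical", "mixture")) - 1L
}

validate_pB <- function(pB) {
  stopifnot(length(pB) == 6, all(pB >= 0))
  if (abs(sum(pB) - 1) > 1e-12) stop("p(B) must sum to 1")
  invisible(pB)
}

#' Initial prior over the six base rates
#'
#' Unnormalised weights `(omega2, omega1, 1, 1, omega1, omega2)` over the
#' base rates `(0, 0.2, 0.4, 0.6, 0.8, 1)`, normalised; symmetric about 0.5
#' by construction. The weight of the two values closest to 0.5 is fixed at
#' 1, so the distribution has two free parameters.
#'
#' @param omega1,omega2 nonnegative weights.
#' @return numeric vector of six probabilities.
#' @export
make_prior <- function(omega1, omega2) {
  if (omega1 < 0 || omega2 < 0) stop("prior weights must be nonnegative")
  w <- c(omega2, omega1, 1, 1, omega1, omega2)
  w / sum(w)
}

#' Expectation of the base rate
#'
#' `E[B]` under `p(B)`; because `p(R | B) = B`, this is also the prior
#' probability of rightward motion on the next trial.
#'
#' @param pB probability vector over the six base rates.
#' @return scalar in `[0, 1]`.
#' @export
expected_base_rate <- function(pB) {
  validate_pB(pB)
  sum(BASE_RATES * pB)
}

#' @rdname expected_base_rate
#' @export
prior_direction_R <- expected_base_rate

#' Direction posterior under the evolving prior
#'
#' Combines the counterfactual posterior for rightward, `pu`, with the
#' expected base rate: `E[B] pu / (E[B] pu + (1 - E[B]) (1 - pu))`.
#'
#' @param pu_R counterfactual posterior probability of rightward.
#' @param expected_B expectation of the base rate.
#' @return posterior probability of rightward motion.
#' @export
direction_posterior <- function(pu_R, expected_B) {
  stopifnot(all(pu_R >= 0 & pu_R <= 1), all(expected_B >= 0 & expected_B <= 1))
  num <- expected_B * pu_R
  den <- num + (1 - expected_B) * (1 - pu_R)
  if (any(den == 0)) stop("undefined direction posterior (0/0)")
  num / den
}

#' Per-trial update evidence under each rule
#'
#' Returns `nu_r` (the rightward update evidence in `[0, 1]`; `nu_l = 1 -
#' nu_r`): the counterfactual posterior for the bayesian rule; the choice
#' indicator for choice-only; the reported posterior for rightward for
#' choice-confidence; a five-parameter logistic in confidence and
#' chosen-side prior expectation for the empirical rule; and the
#' `beta`-weighted mixture of the bayesian and choice-confidence values.
#'
#' @param model update rule name.
#' @param choice "R" or "L" (or logical rightward), vectorised.
#' @param conf confidence in the chosen side (transformed scale), `(0, 1)`.
#' @param pu_R counterfactual posterior for rightward.
#' @param prior_R prior expectation that motion is rightward (`E[B]`).
#' @param beta_mix mixture weight (mixture rule only).
#' @param empirical_betas five coefficients (empirical rule only).
#' @return numeric vector of `nu_r` values.
#' @export
compute_nu <- function(model, choice, conf = NULL, pu_R = NULL,
                       prior_R = NULL, beta_mix = NULL,
                       empirical_betas = NULL) {
  is_r <- if (is.character(choice)) choice == "R" else as.logical(choice)
  rep_posterior_R <- function() {
    if (is.null(conf)) stop("this rule requires conf")
    ifelse(is_r, conf, 1 - conf)
  }
  switch(model,
    bayesian = {
      if (is.null(pu_R)) stop("bayesian rule requires pu_R")
      pu_R + 0 * is_r
    },
    choice_only = as.numeric(is_r),
    choice_confidence = rep_posterior_R(),
    empirical = {
      if (is.null(empirical_betas) || length(empirical_betas) != 5) {
        stop("empirical rule requires 5 empirical_betas")
      }
      if (is.null(conf) || is.null(prior_R)) {
        stop("empirical rule requires conf and prior_R")
      }
      pd <- ifelse(is_r, prior_R, 1 - prior_R)
      b <- empirical_betas
      nd <- plogis(b[1] + b[2] * conf + b[3] * pd + b[4] * conf * pd +
                     b[5] * conf^2 * pd)
      ifelse(is_r, nd, 1 - nd)
    },
    mixture = {
      if (is.null(beta_mix)) stop("mixture rule requires beta_mix")
      if (is.null(conf) || is.null(pu_R)) {
        stop("mixture rule requires conf and pu_R")
      }
      beta_mix * pu_R + (1 - beta_mix) * rep_posterior_R()
    },
    stop("unknown model: ", model)
  )
}

#' Update the distribution over base rates
#'
#' Pointwise multiplies `p(B)` by the linear-in-B evidence term
#' `B nu_r + (1 - B) (1 - nu_r)` and renormalises. The posterior becomes
#' the prior for the next trial.
#'
#' @param pB probability vector over the six base rates.
#' @param nu_r rightward update evidence in `[0, 1]`.
#' @return updated probability vector.
#' @export
update_base_rate <- function(pB, nu_r) {
  validate_pB(pB)
  stopifnot(nu_r >= 0, nu_r <= 1)
  w <- pB * (BASE_RATES * nu_r + (1 - BASE_RATES) * (1 - nu_r))
  s <- sum(w)
  if (s <= 0) stop("degenerate base-rate update (all-zero posterior)")
  w / s
}

#' Belief that the block is biased rightward
#'
#' The posterior mass of `p(B)` above 0.5 (the support contains no 0.5).
#'
#' @param pB probability vector over the six base rates.
#' @return scalar belief in `[0, 1]`.
#' @export
belief_rightward <- function(pB) {
  validate_pB(pB)
  sum(pB[BASE_RATES > 0.5])
}

#' First-order lag on the belief report
#'
#' `f_i = f_{i-1} + (b_i - f_{i-1}) (1 - alpha)`; the internal `p(B)` is
#' untouched. With `alpha = 0` the report equals the underlying belief; as
#' `alpha -> 1` the report stays at its starting value of 0.5.
#'
#' @param b_i belief that would be reported without lag.
#' @param f_prev previous report (0.5 at the start of a block).
#' @param alpha lag constant in `[0, 1)`.
#' @return the lagged report.
#' @export
lag_report <- function(b_i, f_prev, alpha) {
  stopifnot(alpha >= 0, alpha < 1)
  if (alpha == 0) return(b_i) # exactly the no-lag report
  f_prev + (b_i - f_prev) * (1 - alpha)
}

# apply the report lag along a belief sequence, restarting at 0.5 at each
# block boundary
apply_lag <- function(b, alpha, block = rep(1L, length(b))) {
  f <- numeric(length(b))
  f_prev <- 0.5
  cur <- NA
  for (i in seq_along(b)) {
    if (!identical(block[i], cur)) {
      cur <- block[i]
      f_prev <- 0.5
    }
    f_prev <- lag_report(b[i], f_prev, alpha)
    f[i] <- f_prev
  }
  f
}

#' First-order lag on the p(B) update itself
#'
#' The non-Bayesian lag variant: the carried distribution is an affine
#' combination of the previous distribution and the fully updated one, so it
#' remains normalised.
#'
#' @param pB_prev distribution carried from the previous trial.
#' @param pB_new fully updated distribution for the current trial.
#' @param alpha lag constant in `[0, 1)`.
#' @return the lagged distribution.
#' @export
lag_update_pB <- function(pB_prev, pB_new, alpha) {
  validate_pB(pB_prev)
  validate_pB(pB_new)
  stopifnot(alpha >= 0, alpha < 1)
  pB_prev + (pB_new - pB_prev) * (1 - alpha)
}

#' Simulate observer behaviour on a stimulus design
#'
#' For each trial: simulate the accumulator, look up counterfactual
#' confidence from the maps, combine it with the current `E[B]` to choose
#' and assign confidence (the model posterior for the chosen side), update
#' `p(B)` under the observer's update rule, and emit the (optionally
#' lagged) belief report. `p(B)` resets to the initial prior and the belief
#' marker to 0.5 at every block boundary.
#'
#' @param design stimulus trial table (see [generate_experiment()]).
#' @param params an [observer_params()] object.
#' @param maps [build_likelihood_maps()] output with matching `kappa` and
#'   `bound_A`.
#' @param seed optional integer seed.
#' @param keep_latent keep the latent `e`, `te`, `pu`, `EB` columns?
#' @return the design with behaviour columns `choice`, `confidence_raw`,
#'   `confidence_category` (binarised at `phi`), `belief`, `belief_report`.
#' @export
simulate_observer <- function(design, params, maps, seed = NULL,
                              keep_latent = FALSE) {
  stopifnot(inherits(params, "observer_params"),
            inherits(maps, "likelihood_maps"))
  if (abs(maps$kappa - params$kappa) > 1e-12 ||
      abs(maps$bound_A - params$bound_A) > 1e-12) {
    stop("likelihood maps were built for different kappa/bound_A than params")
  }
  check_stimulus_columns(design)
  if (!is.null(seed)) set.seed(seed)
  prior0 <- make_prior(params$omega1, params$omega2)
  eb <- params$empirical_betas %||% numeric(5)
  res <- cpp_observer_sim(
    as.integer(factor(design$block_id, levels = unique(design$block_id))),
    params$kappa * design$coherence_signed, design$duration_s,
    params$bound_A, 5e-4, maps$pu, maps$pu_top, maps$pu_bot, maps$de,
    maps$dt, prior0, BASE_RATES, model_code(params$model),
    params$beta_mix %||% 1, eb, params$alpha_lag, params$alpha_lag_pB
  )
  out <- design
  out$choice <- ifelse(res$choice_r == 1L, "R", "L")
  out$confidence_raw <- res$confidence
  out$confidence_category <- ifelse(res$confidence >= params$phi,
                                    "high", "low")
  out$belief <- res$belief
  out$belief_report <- res$belief_report
  if (keep_latent) {
    out$e <- res$e
    out$te <- res$te
    out$bound_hit <- as.logical(res$bound_hit)
    out$pu <- res$pu
    out$EB_prior <- res$EB
  }
  class(out) <- c("trial_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
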