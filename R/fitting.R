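#' Binarise confidence reports for one subject
#'
#' The lowest 30% of a subject's confidence reports are labelled low
#' confidence; the threshold is the per-subject 30th percentile (type-1
#' quantile) and ties at the threshold fall in "low". If every report is
#' identical the binarisation is degenerate: all reports are labelled
#' "high" with a warning.
#'
#' @param conf numeric vector of raw confidence reports for one subject.
#' @param prop_low proportion labelled low (0.3 in the protocol).
#' @return character vector of "low"/"high".
#' @export
binarize_confidence <- function(conf, prop_low = 0.3) {
  if (length(conf) < 10) stop("need at least 10 trials to binarise confidence")
  if (length(unique(conf)) == 1L) {
    warning("all confidence reports identical; labelling all as high")
    return(rep("high", length(conf)))
  }
  thr <- quantile(conf, prop_low, type = 1, names = FALSE)
  ifelse(conf <= thr, "low", "high")
}

#' Rank-preserving transformation of confidence reports
#'
#' Maps the raw reports onto the model's simulated probability-correct
#' values by rank: the behavioural trial with the k-th smallest confidence
#' receives the k-th smallest simulated value, so the transformed
#' distribution equals the simulated one and the high/low categories are
#' unchanged. Tied raw reports receive the mean of their simulated band
#' (weakly monotone).
#'
#' @param conf_raw raw reports.
#' @param conf_sim simulated probability-correct values, same length.
#' @return transformed confidence vector.
#' @export
transform_confidence <- function(conf_raw, conf_sim) {
  if (length(conf_raw) != length(conf_sim)) {
    stop("size mismatch: ", length(conf_sim), " simulated values for ",
         length(conf_raw), " reports")
  }
  out <- numeric(length(conf_raw))
  out[order(conf_raw)] <- sort(conf_sim)
  ave(out, conf_raw, FUN = mean)
}

#' Invert reported confidence to counterfactual confidence
#'
#' The exact inverse of [direction_posterior()]: given the reported
#' posterior for rightward and the prior expectation of rightward, recover
#' the counterfactual posterior through the odds identity
#' `odds(pu) = odds(conf_R) * (1 - prior_R) / prior_R`. Reports at the
#' scale endpoints are clipped to `[eps, 1 - eps]` first.
#'
#' @param conf_R reported posterior probability of rightward.
#' @param prior_R prior expectation of rightward (`E[B]`), in (0, 1).
#' @param eps clipping width for endpoint reports.
#' @return counterfactual posterior for rightward.
#' @export
invert_confidence_to_counterfactual <- function(conf_R, prior_R,
                                                eps = 1e-4) {
  stopifnot(all(prior_R > 0 & prior_R < 1))
  conf_R <- pmin(pmax(conf_R, eps), 1 - eps)
  odds <- (conf_R / (1 - conf_R)) * ((1 - prior_R) / prior_R)
  odds / (1 + odds)
}

# map a trial's duration onto the propagation time grid (0-based index)
time_index <- function(T, dt, nt) {
  pmin(pmax(as.integer(round(T / dt)), 1L), nt) - 1L
}

prepare_loglik_inputs <- function(data, maps) {
  mag <- match(round(abs(data$coherence_signed), 6),
               round(maps$coherences, 6))
  if (anyNA(mag)) stop("coherence magnitude not in the maps' coherence set")
  nt <- length(maps$t_grid)
  list(
    block = as.integer(factor(paste(data$subject_id, data$block_id),
                              levels = unique(paste(data$subject_id,
                                                    data$block_id)))),
    mag_idx = mag - 1L,
    sgn = as.integer(sign(data$coherence_signed)),
    kidx = time_index(data$duration_s, maps$dt, nt),
    choice_r = as.integer(data$choice == "R"),
    conf_high = as.integer(data$confidence_category == "high")
  )
}

#' Joint likelihood of the four choice-confidence outcomes for one trial
#'
#' Integrates `p(e, te | c, T)` over the regions of the evidence-time plane
#' where the biased-prior posterior for the chosen side falls in
#' `(0.5, phi)` (low confidence) or `[phi, 1]` (high). The four outcome
#' masses sum to 1.
#'
#' @param coherence_signed signed coherence of the trial.
#' @param duration_s stimulus duration in seconds.
#' @param pB current distribution over base rates.
#' @param phi confidence criterion.
#' @param maps a [build_likelihood_maps()] object.
#' @return named numeric vector `R_high`, `R_low`, `L_high`, `L_low`.
#' @export
trial_joint_likelihood <- function(coherence_signed, duration_s, pB, phi,
                                   maps) {
  stopifnot(inherits(maps, "likelihood_maps"), phi > 0.5, phi < 1)
  EB <- expected_base_rate(pB)
  mag <- match(round(abs(coherence_signed), 6), round(maps$coherences, 6))
  if (is.na(mag)) stop("coherence magnitude not in the maps' coherence set")
  k <- time_index(duration_s, maps$dt, length(maps$t_grid))
  cpp_outcome_masses(maps$D, maps$ftop, maps$fbot, mag - 1L,
                     as.integer(sign(coherence_signed)), k, maps$pu,
                     maps$pu_top, maps$pu_bot, maps$bound_A, maps$de,
                     maps$dt, EB, phi)
}

#' Dataset log-likelihood under an update rule
#'
#' Per block, starts from the parametric initial prior, adds the log mass of
#' each observed (choice, confidence-category) outcome, and propagates
#' `p(B)` using the update evidence computed from the subject's observed
#' choice and transformed confidence (counterfactual inversion for the
#' bayesian and mixture rules, the reported posterior for
#' choice-confidence, the choice indicator for choice-only).
#'
#' @param data behavioural trial table, ordered by block and trial.
#' @param params an [observer_params()] object.
#' @param maps likelihood maps matching `params`.
#' @param conf_trans transformed confidence (defaults to raw reports).
#' @param eps_clip clipping for the counterfactual inversion.
#' @param log_floor floor for zero-mass outcomes (diagnostic-counted).
#' @return list with `loglik`, `per_trial`, `n_floor`, `EB`, `nu_r`.
#' @export
dataset_loglik <- function(data, params, maps, conf_trans = NULL,
                           eps_clip = 1e-4, log_floor = log(1e-10),
                           .inp = NULL) {
  stopifnot(inherits(params, "observer_params"))
  inp <- .inp %||% prepare_loglik_inputs(data, maps)
  if (is.null(conf_trans)) conf_trans <- data$confidence_raw
  prior0 <- make_prior(params$omega1, params$omega2)
  cpp_dataset_loglik(inp$block, inp$mag_idx, inp$sgn, inp$kidx,
                     inp$choice_r, inp$conf_high, conf_trans, maps$D,
                     maps$ftop, maps$fbot, maps$pu, maps$pu_top,
                     maps$pu_bot, maps$bound_A, maps$de, maps$dt,
                     params$phi, prior0, BASE_RATES,
                     model_code(params$model), params$beta_mix %||% 1,
                     params$empirical_betas %||% numeric(5), eps_clip,
                     log_floor, params$alpha_lag_pB)
}

default_bounds <- function(model, lag_update = FALSE) {
  b <- list(kappa = c(1, 60), bound_A = c(0.3, 5), phi = c(0.505, 0.999),
            omega1 = c(0, 20), omega2 = c(0, 20))
  if (model == "mixture") b$beta_mix <- c(0, 1)
  if (model == "empirical") {
    for (i in 1:5) b[[paste0("e_beta", i - 1)]] <- c(-20, 20)
  }
  if (lag_update) b$alpha_lag_pB <- c(0, 0.99)
  b
}

params_from_vector <- function(p, model, lag_update = FALSE) {
  extra <- list()
  i <- 6
  if (model == "mixture") {
    extra$beta_mix <- p[i]; i <- i + 1
  }
  if (model == "empirical") {
    extra$empirical_betas <- p[i:(i + 4)]; i <- i + 5
  }
  if (lag_update) extra$alpha_lag_pB <- p[i]
  do.call(observer_params,
          c(list(kappa = p[1], bound_A = p[2], phi = p[3], omega1 = p[4],
                 omega2 = p[5], model = model), extra))
}

#' Fit an observer model by maximum likelihood
#'
#' Fits the five shared parameters (`kappa`, `bound_A`, `phi`, `omega1`,
#' `omega2`), plus any rule-specific extras, to one subject's choices and
#' binarised confidence by bounded derivative-free optimisation
#' (Nelder-Mead on logit-rescaled parameters) from Latin-hypercube starting
#' points. The rank-preserving confidence transformation is refreshed from
#' a model simulation at each restart's starting point and again at its
#' optimum; if the refresh moves the log-likelihood by `ll_tol` or more the
#' restart is re-optimised once under the new transformation.
#'
#' @param data behavioural trial table for a single subject.
#' @param model update rule to fit.
#' @param n_starts number of optimisation restarts (the protocol uses 30).
#' @param seed integer seed controlling starts and transformation refreshes.
#' @param bounds named list of parameter bounds (defaults documented in
#'   [observer_params()] terms: kappa 1-60, bound 0.3-5, phi 0.505-0.999,
#'   omegas 0-20).
#' @param grid fitting-resolution propagation grid: `n_bins` evidence bins
#'   and time step `dt` in seconds.
#' @param maxit Nelder-Mead iteration cap per restart (before the
#'   quasi-Newton polish).
#' @param transform refresh the confidence transformation during fitting?
#'   With `FALSE` the raw reports are used throughout.
#' @param lag_update also fit a first-order lag on the p(B) update
#'   (the non-Bayesian lag variant)?
#' @param start optional numeric vector (or matrix, one start per row) of
#'   additional starting values on the natural parameter scale; counted
#'   toward `n_starts`.
#' @param include_zero_both treat 0% coherence as compatible with both
#'   directions in the counterfactual map?
#' @param ll_tol stopping tolerance for the transformation refresh.
#' @return an object of class `observer_fit`.
#' @export
fit_observer <- function(data, model = c("bayesian", "choice_only",
                                         "choice_confidence", "empirical",
                                         "mixture"),
                         n_starts = 30, seed = 1, bounds = NULL,
                         grid = list(n_bins = 255L, dt = 2e-3), maxit = 200,
                         transform = TRUE, lag_update = FALSE, start = NULL,
                         include_zero_both = TRUE, ll_tol = 0.01) {
  model <- match.arg(model)
  cl <- match.call()
  if (length(unique(data$subject_id)) != 1L) {
    stop("fit_observer fits one subject at a time; split the data first")
  }
  data <- data[order(data$block_id, data$trial_index), , drop = FALSE]
  if (is.null(data$confidence_category)) {
    data$confidence_category <- binarize_confidence(data$confidence_raw)
  }
  bl <- default_bounds(model, lag_update)
  if (!is.null(bounds)) bl <- modifyList(bl, bounds)
  lo <- vapply(bl, `[`, numeric(1), 1)
  hi <- vapply(bl, `[`, numeric(1), 2)
  npar <- length(lo)
  to_x <- function(p) qlogis(pmin(pmax((p - lo) / (hi - lo), 1e-8),
                                  1 - 1e-8))
  to_p <- function(x) lo + (hi - lo) * plogis(x)
  t_max <- 0.9

  build_fit_maps <- function(p) {
    ap <- accumulator_params(kappa = p[1], bound_A = p[2],
                             dt_map = grid$dt, n_bins = grid$n_bins,
                             t_max = t_max)
    build_likelihood_maps(ap, include_zero_both = include_zero_both)
  }
  # trial indexing into the maps is fixed by the grid, not by (kappa, A);
  # precompute it once for the whole optimisation
  inp <- prepare_loglik_inputs(data, build_fit_maps(c(10, 1)))
  negll <- function(x, conf_trans) {
    p <- to_p(x)
    maps <- build_fit_maps(p)
    obj <- dataset_loglik(data, params_from_vector(p, model, lag_update),
                          maps, conf_trans, .inp = inp)
    -obj$loglik
  }
  # short Nelder-Mead to leave the start's neighbourhood robustly, then a
  # quasi-Newton polish (numerical gradients) on the unconstrained scale;
  # restarts remain responsible for escaping genuine local optima
  run_opt <- function(x0, conf_trans) {
    o1 <- optim(x0, negll, conf_trans = conf_trans,
                method = "Nelder-Mead", control = list(maxit = maxit))
    o2 <- nlminb(o1$par, negll, conf_trans = conf_trans,
                 control = list(eval.max = 500, iter.max = 200))
    list(par = o2$par, value = o2$objective,
         convergence = o2$convergence)
  }
  refresh_transform <- function(p, sim_seed) {
    if (!transform) return(data$confidence_raw)
    maps <- build_fit_maps(p)
    sim <- simulate_observer(data, params_from_vector(p, model, lag_update),
                             maps, seed = sim_seed)
    transform_confidence(data$confidence_raw, sim$confidence_raw)
  }

  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, npar)
  starts <- sweep(sweep(starts, 2, hi - lo, `*`), 2, lo, `+`)
  if (!is.null(start)) {
    sm <- if (is.matrix(start)) start else matrix(start, nrow = 1)
    if (ncol(sm) != npar) stop("start has wrong length for model ", model)
    starts[seq_len(min(nrow(sm), n_starts)), ] <-
      sm[seq_len(min(nrow(sm), n_starts)), , drop = FALSE]
  }

  best <- NULL
  start_values <- numeric(n_starts)
  start_conv <- integer(n_starts)
  for (s in seq_len(n_starts)) {
    p0 <- starts[s, ]
    ct <- refresh_transform(p0, sim_seed = seed + 1000L * s)
    opt <- run_opt(to_x(p0), ct)
    # refresh the transformation at the incumbent optimum
    ct2 <- refresh_transform(to_p(opt$par), sim_seed = seed + 1000L * s + 1L)
    v2 <- negll(opt$par, ct2)
    n_refresh <- 1L
    if (transform && abs(v2 - opt$value) >= ll_tol) {
      opt <- run_opt(opt$par, ct2)
      v2 <- opt$value
      n_refresh <- 2L
    }
    start_values[s] <- -v2
    start_conv[s] <- opt$convergence
    if (is.null(best) || v2 < best$value) {
      best <- list(par = opt$par, value = v2, conf_trans = ct2,
                   start = s, n_refresh = n_refresh)
    }
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("optimisation failure: no start converged to a finite ",
         "log-likelihood (", n_starts, " starts)")
  }
  p_hat <- to_p(best$par)
  names(p_hat) <- names(bl)
  maps_hat <- build_fit_maps(p_hat)
  final <- dataset_loglik(data, params_from_vector(p_hat, model, lag_update),
                          maps_hat, best$conf_trans, .inp = inp)
  n <- nrow(data)
  k <- npar
  structure(list(
    model = model, coefficients = p_hat, logLik = final$loglik,
    per_trial = final$per_trial, n_params = k, n_trials = n,
    AIC = 2 * k - 2 * final$loglik, BIC = k * log(n) - 2 * final$loglik,
    data = data, conf_transformed = best$conf_trans,
    EB = final$EB, nu_r = final$nu_r, lag_update = lag_update,
    grid = grid, bounds = bl, include_zero_both = include_zero_both,
    seed = seed,
    diagnostics = list(n_starts = n_starts, start_values = start_values,
                       convergence = start_conv, best_start = best$start,
                       n_floor = final$n_floor,
                       transform_refreshes = best$n_refresh),
    call = cl
  ), class = "observer_fit")
}

#' Compare fitted models on one dataset
#'
#' @param ... `observer_fit` objects (or a single list of them).
#' @return data.frame with log-likelihood, parameter counts, AIC, BIC and
#'   deltas relative to the maximum-likelihood model.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "observer_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "observer_fit")))
  key <- function(f) {
    paste(nrow(f$data), sum(f$data$coherence_signed),
          sum(f$data$choice == "R"))
  }
  keys <- vapply(fits, key, character(1))
  if (length(unique(keys)) != 1L) {
    stop("model comparison requires fits to the same dataset")
  }
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  k <- vapply(fits, function(f) f$n_params, numeric(1))
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  bic <- vapply(fits, function(f) f$BIC, numeric(1))
  out <- data.frame(
    model = vapply(fits, function(f) f$model, character(1)),
    logLik = ll, n_params = k, AIC = aic, BIC = bic,
    dLogLik = max(ll) - ll, dAIC = aic - min(aic), dBIC = bic - min(bic)
  )
  out[order(-out$logLik), ]
}

#' Fit the report-lag time constant
#'
#' Finds the `alpha` in `[0, 1)` minimising the mean squared error between
#' the lag-filtered no-lag belief predictions and the reported beliefs;
#' the filter restarts at 0.5 at each block boundary.
#'
#' @param reports reported beliefs.
#' @param predictions no-lag belief predictions, same length.
#' @param block block labels (a single block when omitted).
#' @return list with `alpha`, `mse`, and the filtered predictions.
#' @export
fit_lag_alpha <- function(reports, predictions,
                          block = rep(1L, length(reports))) {
  stopifnot(length(reports) == length(predictions))
  mse <- function(a) mean((apply_lag(predictions, a, block) - reports)^2)
  opt <- optimize(mse, c(0, 0.999))
  cand <- c(0, opt$minimum, 0.999)
  vals <- vapply(cand, mse, numeric(1))
  a <- cand[which.min(vals)]
  list(alpha = a, mse = min(vals),
       fitted = apply_lag(predictions, a, block))
}
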