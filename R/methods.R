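#' @export
print.observer_fit <- function(x, ...) {
  cat("Observer model fit (", x$model,
      if (x$lag_update) ", lag on p(B) update" else "", ")\n", sep = "")
  cat(sprintf("  %d trials, %d parameters, logLik = %.2f (AIC %.1f, BIC %.1f)\n",
              x$n_trials, x$n_params, x$logLik, x$AIC, x$BIC))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.observer_fit <- function(object, ...) {
  d <- object$diagnostics
  structure(list(fit = object,
                 start_spread = range(d$start_values),
                 n_converged = sum(d$convergence == 0),
                 n_floor = d$n_floor), class = "summary.observer_fit")
}

#' @export
print.summary.observer_fit <- function(x, ...) {
  print(x$fit)
  d <- x$fit$diagnostics
  cat(sprintf("  %d/%d starts converged (best: start %d); restart logLik range [%.2f, %.2f]\n",
              x$n_converged, d$n_starts, d$best_start,
              x$start_spread[1], x$start_spread[2]))
  if (x$n_floor > 0) {
    cat("  ", x$n_floor, "trial(s) hit the log-likelihood floor\n")
  }
  invisible(x)
}

#' @export
coef.observer_fit <- function(object, ...) object$coefficients

#' @export
logLik.observer_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_params,
            nobs = object$n_trials, class = "logLik")
}

#' Predict belief trajectories (method for fitted observers)
#'
#' @param object an `observer_fit`.
#' @param design stimulus table; defaults to the fitted data.
#' @param n_sim number of simulations of the full experiment.
#' @param seed integer seed.
#' @param ... passed to [predict_beliefs()].
#' @export
predict.observer_fit <- function(object, design = NULL, n_sim = 200,
                                 seed = NULL, ...) {
  predict_beliefs(object, design = design, n_sim = n_sim, seed = seed, ...)
}

#' Simulate behaviour from a fitted observer
#'
#' @param object an `observer_fit`.
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @param design stimulus table; defaults to the fitted data's stimuli.
#' @param ... passed to [simulate_observer()].
#' @return a trial table, or a list of them when `nsim > 1`.
#' @export
simulate.observer_fit <- function(object, nsim = 1, seed = NULL,
                                  design = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(design)) design <- object$data
  params <- params_from_vector(unname(object$coefficients), object$model,
                               object$lag_update)
  ap <- accumulator_params(kappa = params$kappa, bound_A = params$bound_A,
                           dt_map = object$grid$dt,
                           n_bins = object$grid$n_bins)
  maps <- build_likelihood_maps(ap,
                                include_zero_both = object$include_zero_both)
  sims <- lapply(seq_len(nsim), function(i) {
    simulate_observer(design, params, maps, ...)
  })
  if (nsim == 1) sims[[1]] else sims
}

#' Residuals of the belief predictions
#'
#' Reported minus mean-predicted belief at the end of each block (requires
#' belief reports in the fitted data).
#'
#' @param object an `observer_fit`.
#' @param n_sim simulations used for the prediction.
#' @param seed integer seed.
#' @param ... unused.
#' @export
residuals.observer_fit <- function(object, n_sim = 50, seed = NULL, ...) {
  if (is.null(object$data$belief_report)) {
    stop("fitted data carries no belief reports")
  }
  pred <- predict_beliefs(object, n_sim = n_sim, seed = seed)
  is_last <- !duplicated(object$data$block_id, fromLast = TRUE)
  object$data$belief_report[is_last] - pred$end_mean
}

#' Plot mean belief trajectories by base rate
#'
#' Mean reported belief as a function of trial number within the block for
#' each base rate, from data (solid) and, optionally, from model
#' predictions (dashed).
#'
#' @param x an `observer_fit` or a trial table.
#' @param predictions optional `belief_prediction` to overlay.
#' @param max_trial largest trial number displayed.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.observer_fit <- function(x, predictions = NULL, max_trial = 30, ...) {
  plot_belief_course(x$data, predictions, max_trial, ...)
}

#' @rdname plot.observer_fit
#' @export
plot.trial_table <- function(x, predictions = NULL, max_trial = 30, ...) {
  plot_belief_course(x, predictions, max_trial, ...)
}

plot_belief_course <- function(data, predictions = NULL, max_trial = 30,
                               ...) {
  if (is.null(data$belief_report)) stop("no belief reports to plot")
  keep <- data$trial_index <= max_trial
  m <- tapply(data$belief_report[keep],
              list(data$trial_index[keep], data$base_rate[keep]), mean)
  matplot(as.numeric(rownames(m)), m, type = "l", lty = 1,
          xlab = "trial number in block", ylab = "mean belief (rightward)",
          ylim = c(0, 1), ...)
  abline(h = 0.5, col = "grey", lty = 3)
  if (!is.null(predictions)) {
    pd <- predictions$design
    keep_p <- pd$trial_index <= max_trial
    mp <- tapply(predictions$mean_trajectory[keep_p],
                 list(pd$trial_index[keep_p], pd$base_rate[keep_p]), mean)
    matplot(as.numeric(rownames(mp)), mp, type = "l", lty = 2, add = TRUE)
  }
  legend("bottomright", legend = colnames(m), lty = 1, col = seq_len(ncol(m)),
         title = "base rate", cex = 0.7, bty = "n")
  invisible(m)
}

#' @export
print.belief_prediction <- function(x, ...) {
  cat("Belief predictions from", x$n_sim, "simulations of",
      length(x$block_id), "blocks\n")
  cat(sprintf("  mean end-of-block belief: %.3f (range %.3f-%.3f)\n",
              mean(x$end_mean), min(x$end_mean), max(x$end_mean)))
  invisible(x)
}
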