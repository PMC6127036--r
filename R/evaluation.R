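#' Predict belief trajectories from a fitted model
#'
#' Simulates the fitted observer repeatedly on an identical stimulus
#' sequence (the protocol uses 200 simulations of the full experiment) and
#' summarises the belief reports per trial and at the end of each block.
#'
#' @param fit an `observer_fit`.
#' @param design stimulus trial table; defaults to the fitted data's
#'   stimuli.
#' @param n_sim number of simulations.
#' @param seed integer seed.
#' @param maps optional precomputed likelihood maps at the fitted
#'   parameters (rebuilt on the fitting grid otherwise).
#' @return object of class `belief_prediction`: per-trial mean trajectory,
#'   the end-of-block belief for every simulation, and their block means.
#' @export
predict_beliefs <- function(fit, design = NULL, n_sim = 200, seed = NULL,
                            maps = NULL) {
  stopifnot(inherits(fit, "observer_fit"))
  if (is.null(design)) design <- fit$data
  params <- params_from_vector(unname(fit$coefficients), fit$model,
                               fit$lag_update)
  if (is.null(maps)) {
    ap <- accumulator_params(kappa = params$kappa, bound_A = params$bound_A,
                             dt_map = fit$grid$dt, n_bins = fit$grid$n_bins)
    maps <- build_likelihood_maps(ap,
                                  include_zero_both = fit$include_zero_both)
  }
  if (!is.null(seed)) set.seed(seed)
  is_last <- !duplicated(design$block_id, fromLast = TRUE)
  blocks <- design$block_id[is_last]
  traj <- matrix(0, nrow(design), n_sim)
  for (s in seq_len(n_sim)) {
    sim <- simulate_observer(design, params, maps)
    traj[, s] <- sim$belief_report
  }
  structure(list(
    mean_trajectory = rowMeans(traj),
    end_matrix = traj[is_last, , drop = FALSE],
    end_mean = rowMeans(traj[is_last, , drop = FALSE]),
    block_id = blocks, design = design, n_sim = n_sim,
    trajectories = traj
  ), class = "belief_prediction")
}

#' Mean squared error of end-of-block belief predictions
#'
#' @param predictions a `belief_prediction` or a numeric vector of
#'   predicted end-of-block beliefs.
#' @param reports reported end-of-block beliefs, one per block, in the same
#'   block order.
#' @return scalar MSE over blocks.
#' @export
end_of_block_mse <- function(predictions, reports) {
  pred <- if (inherits(predictions, "belief_prediction")) {
    predictions$end_mean
  } else {
    predictions
  }
  if (length(pred) != length(reports)) {
    stop("alignment error: ", length(pred), " predicted blocks for ",
         length(reports), " reports")
  }
  mean((pred - reports)^2)
}

#' Paired end-of-block MSE comparison between fitted models
#'
#' Each repetition simulates every model once on the identical stimulus
#' sequence and computes its end-of-block MSE against the reported beliefs;
#' the empirical p-value for a pair is the proportion of repetitions in
#' which one model's MSE is below the other's.
#'
#' @param fits list of `observer_fit` objects (same dataset).
#' @param data behavioural table carrying the stimuli and the reported
#'   beliefs (`belief_report`).
#' @param n_rep number of paired repetitions.
#' @param seed integer seed.
#' @return object of class `belief_mse_comparison` with the per-repetition
#'   MSE matrix, mean MSE per model, and pairwise comparison proportions.
#' @export
compare_belief_mse <- function(fits, data, n_rep = 200, seed = NULL) {
  stopifnot(is.list(fits), length(fits) >= 2)
  if (!is.null(seed)) set.seed(seed)
  is_last <- !duplicated(data$block_id, fromLast = TRUE)
  reports <- data$belief_report[is_last]
  models <- vapply(fits, function(f) f$model, character(1))
  prep <- lapply(fits, function(f) {
    params <- params_from_vector(unname(f$coefficients), f$model,
                                 f$lag_update)
    ap <- accumulator_params(kappa = params$kappa,
                             bound_A = params$bound_A,
                             dt_map = f$grid$dt, n_bins = f$grid$n_bins)
    list(params = params,
         maps = build_likelihood_maps(ap,
                 include_zero_both = f$include_zero_both))
  })
  mse <- matrix(0, n_rep, length(fits), dimnames = list(NULL, models))
  for (r in seq_len(n_rep)) {
    for (m in seq_along(fits)) {
      sim <- simulate_observer(data, prep[[m]]$params, prep[[m]]$maps)
      mse[r, m] <- mean((sim$belief_report[is_last] - reports)^2)
    }
  }
  nm <- length(fits)
  p_lower <- matrix(NA_real_, nm, nm, dimnames = list(models, models))
  for (i in seq_len(nm)) {
    for (j in seq_len(nm)) {
      if (i != j) p_lower[i, j] <- mean(mse[, i] < mse[, j])
    }
  }
  structure(list(mse = mse, mean_mse = colMeans(mse), p_lower = p_lower,
                 n_rep = n_rep),
            class = "belief_mse_comparison")
}

#' @export
print.belief_mse_comparison <- function(x, ...) {
  cat("Paired end-of-block belief MSE over", x$n_rep, "repetitions\n")
  print(round(x$mean_mse, 5))
  cat("P(row model MSE < column model MSE):\n")
  print(round(x$p_lower, 3))
  invisible(x)
}

# ---- regression analyses ---------------------------------------------------

trial_correct <- function(data) {
  if (is.null(data$direction)) {
    stop("regression requires a 'direction' column (nominal direction)")
  }
  data$choice == data$direction
}

# previous-trial value within block (NA on the first trial of a block)
lag_within_block <- function(x, block) {
  out <- c(NA, x[-length(x)])
  out[!duplicated(block)] <- NA
  out
}

subject_dummies <- function(subj, omit_last = TRUE) {
  s <- factor(subj)
  lev <- levels(s)
  keep <- if (omit_last && length(lev) > 1) lev[-length(lev)] else lev
  m <- sapply(keep, function(l) as.numeric(s == l))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(keep))
  colnames(m) <- paste0("subj_", keep)
  m
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(X)
}

coef_table <- function(fit) {
  s <- summary(fit)$coefficients
  data.frame(term = sub("^X", "", rownames(s)), estimate = s[, 1],
             se = s[, 2], stat = s[, 3],
             p = s[, 4], row.names = NULL)
}

fit_glm_matrix <- function(y, X, family) {
  check_full_rank(X)
  if (identical(family, "linear")) {
    lm(y ~ 0 + X)
  } else {
    glm(y ~ 0 + X, family = binomial())
  }
}

#' Run one of the six regression analyses
#'
#' Builds the printed design matrix for the requested analysis and fits it
#' by standard maximum likelihood (logistic or linear). Redundant indicator
#' levels are omitted as printed; remaining rank deficiency is an error
#' naming the collinear columns.
#'
#' * `choice_bias`: rightward choice on duration-by-coherence plus
#'   per-base-rate coherence slopes and intercepts (the bias coefficients),
#'   with a likelihood-ratio test of all base-rate intercepts being zero.
#' * `confidence_strength`: confidence (correct trials) on motion strength,
#'   base rate relative to choice, and chosen side.
#' * `accuracy_course`: accuracy on motion strength, duration, and
#'   per-trial-number terms in the informativeness of the base rate.
#' * `highconf_course`: high-confidence probability, analogous course
#'   in base rate relative to choice.
#' * `delta_belief`: trial-to-trial belief change (sign-flipped for
#'   leftward choices; first trials change from 0.5), correct trials only.
#' * `belief_consistency`: probability of choosing with the reported belief
#'   on 0%-coherence trials following near-certain beliefs (< 0.05 or
#'   > 0.95).
#'
#' @param spec_id one of the six analysis identifiers above.
#' @param data behavioural trial table.
#' @param max_trial for the trial-course analyses, restrict to trial
#'   numbers up to this value; block lengths beyond ~35 trials are rare, so
#'   their indicator pairs can be collinear in small datasets.
#' @return object of class `priorlearn_regression` with the fitted model, a
#'   coefficient table, and (where defined) a likelihood-ratio test.
#' @export
run_regression <- function(spec_id = c("choice_bias", "confidence_strength",
                                       "accuracy_course",
                                       "highconf_course",
                                       "delta_belief",
                                       "belief_consistency"),
                           data, max_trial = NULL) {
  spec_id <- match.arg(spec_id)
  data <- data[order(data$subject_id, data$block_id, data$trial_index), ,
               drop = FALSE]
  if (!is.null(max_trial) &&
      spec_id %in% c("accuracy_course", "highconf_course")) {
    data <- data[data$trial_index <= max_trial, , drop = FALSE]
  }
  is_r <- data$choice == "R"
  coh <- data$coherence_signed
  absc <- abs(coh)
  Tdur <- data$duration_s
  lrt <- NULL

  if (spec_id == "choice_bias") {
    y <- as.numeric(is_r)
    Bf <- factor(data$base_rate)
    Xb <- NULL
    for (lev in levels(Bf)) {
      I <- as.numeric(Bf == lev)
      Xb <- cbind(Xb, I * coh, I)
      colnames(Xb)[ncol(Xb) - 1:0] <- paste0(c("c_B", "bias_B"), lev)
    }
    X0 <- cbind(Tc = Tdur * coh,
                Xb[, grep("^c_B", colnames(Xb)), drop = FALSE])
    Xs <- subject_dummies(data$subject_id)
    if (length(unique(data$subject_id)) > 1) {
      X0 <- cbind(X0, Xs)
    }
    X <- cbind(X0, Xb[, grep("^bias_B", colnames(Xb)), drop = FALSE])
    fit <- fit_glm_matrix(y, X, "logistic")
    null_fit <- fit_glm_matrix(y, X0, "logistic")
    dev <- deviance(null_fit) - deviance(fit)
    df <- ncol(X) - ncol(X0)
    lrt <- list(statistic = dev, df = df, p = pchisq(dev, df,
                                                     lower.tail = FALSE),
                null = "all base-rate bias coefficients zero")
  } else if (spec_id == "confidence_strength") {
    keep <- trial_correct(data)
    d <- data[keep, , drop = FALSE]
    Bsr <- ifelse(d$choice == "R", d$base_rate, 1 - d$base_rate)
    X <- cbind(absc = abs(d$coherence_signed), Bsr = Bsr,
               h = as.numeric(d$choice == "R"),
               subject_dummies(d$subject_id, omit_last = FALSE))
    fit <- fit_glm_matrix(d$confidence_raw, X, "linear")
  } else if (spec_id == "accuracy_course") {
    y <- as.numeric(trial_correct(data))
    Bs <- pmax(data$base_rate, 1 - data$base_rate)
    Nf <- factor(data$trial_index)
    Xn <- NULL
    for (lev in levels(Nf)) {
      I <- as.numeric(Nf == lev)
      Xn <- cbind(Xn, I, I * Bs)
      colnames(Xn)[ncol(Xn) - 1:0] <- paste0(c("trial", "Bs_trial"), lev)
    }
    X <- cbind(absc = absc, T = Tdur)
    if (length(unique(data$subject_id)) > 1) {
      X <- cbind(X, subject_dummies(data$subject_id))
      Xcs <- subject_dummies(data$subject_id, omit_last = FALSE) * absc
      colnames(Xcs) <- paste0("absc_", colnames(Xcs))
      X <- cbind(X, Xcs)
    }
    X <- cbind(X, Xn)
    fit <- fit_glm_matrix(y, X, "logistic")
  } else if (spec_id == "highconf_course") {
    y <- as.numeric(data$confidence_category == "high")
    a <- as.numeric(trial_correct(data))
    Bsr <- ifelse(is_r, data$base_rate, 1 - data$base_rate)
    Nf <- factor(data$trial_index)
    Xn <- NULL
    for (lev in levels(Nf)) {
      I <- as.numeric(Nf == lev)
      Xn <- cbind(Xn, I, I * Bsr)
      colnames(Xn)[ncol(Xn) - 1:0] <- paste0(c("trial", "Bsr_trial"), lev)
    }
    X <- cbind(absc = absc, T = Tdur, h = as.numeric(is_r), a = a)
    if (length(unique(data$subject_id)) > 1) {
      Xs <- subject_dummies(data$subject_id)
      Xcs <- Xs * absc
      colnames(Xcs) <- paste0("absc_", colnames(Xs))
      Xca <- subject_dummies(data$subject_id, omit_last = FALSE) * absc * a
      colnames(Xca) <- paste0("absc_a_", colnames(Xca))
      X <- cbind(X, Xs, Xcs, Xca)
    } else {
      X <- cbind(X, absc_a = absc * a)
    }
    X <- cbind(X, Xn)
    fit <- fit_glm_matrix(y, X, "logistic")
  } else if (spec_id == "delta_belief") {
    prev <- lag_within_block(data$belief_report,
                             paste(data$subject_id, data$block_id))
    prev[is.na(prev)] <- 0.5
    dbel <- data$belief_report - prev
    dbel <- ifelse(is_r, dbel, -dbel)
    beliefc <- ifelse(is_r, data$belief_report, 1 - data$belief_report)
    keep <- trial_correct(data)
    X <- cbind(absc = absc, T = Tdur, beliefc = beliefc,
               subject_dummies(data$subject_id,
                               omit_last = FALSE))[keep, , drop = FALSE]
    fit <- fit_glm_matrix(dbel[keep], X, "linear")
  } else { # belief_consistency
    key <- paste(data$subject_id, data$block_id)
    prev <- lag_within_block(data$belief_report, key)
    keep <- !is.na(prev) & absc == 0 & (prev < 0.05 | prev > 0.95)
    if (sum(keep) < 10) {
      stop("insufficient data: only ", sum(keep),
           " eligible 0%-coherence trials with near-certain prior belief")
    }
    consistent <- as.numeric((prev > 0.5) == is_r)
    Bs <- pmax(data$base_rate, 1 - data$base_rate)
    X <- cbind(Bs = Bs, T = Tdur,
               subject_dummies(data$subject_id,
                               omit_last = FALSE))[keep, , drop = FALSE]
    fit <- fit_glm_matrix(consistent[keep], X, "logistic")
  }
  structure(list(spec_id = spec_id, fit = fit, coefficients = coef_table(fit),
                 lrt = lrt, n = length(fit$residuals)),
            class = "priorlearn_regression")
}

#' @export
print.priorlearn_regression <- function(x, ...) {
  cat("Regression analysis:", x$spec_id, " (n =", x$n, ")\n")
  print(x$coefficients, digits = 4)
  if (!is.null(x$lrt)) {
    cat(sprintf("LRT (%s): chi2 = %.2f, df = %d, p = %.3g\n",
                x$lrt$null, x$lrt$statistic, x$lrt$df, x$lrt$p))
  }
  invisible(x)
}

#' Zero-coherence belief-change diagnostics
#'
#' Lag-sensitive summaries of the belief reports on 0%-coherence trials:
#' mean trial-to-trial belief change as a function of the currently held
#' belief (20 percentile bins); the same split by the sign of the previous
#' trial's coherence (5 percentile bins); and, when a fit is supplied,
#' belief change as a function of the counterfactual confidence inferred
#' from the model (split by choice, centred 100-trial moving average, all
#' trials). A no-lag Bayesian observer predicts a flat zero profile in the
#' first summary.
#'
#' @param data behavioural trial table.
#' @param fit optional `observer_fit` used to infer counterfactual
#'   confidence from the reported confidence.
#' @param n_bins number of percentile bins for the first summary.
#' @return list with components `by_belief`, `by_prev_coherence`, and
#'   (given a fit) `by_counterfactual`.
#' @export
zero_coherence_diagnostics <- function(data, fit = NULL, n_bins = 20) {
  key <- paste(data$subject_id, data$block_id)
  prev_belief <- lag_within_block(data$belief_report, key)
  prev_coh <- lag_within_block(data$coherence_signed, key)
  dbel <- data$belief_report - prev_belief
  zero <- !is.na(prev_belief) & abs(data$coherence_signed) == 0
  if (sum(zero) < 5 * n_bins) {
    stop("insufficient data: ", sum(zero), " usable 0%-coherence trials")
  }
  bin_summary <- function(x, y, k) {
    edges <- quantile(x, seq(0, 1, length.out = k + 1), type = 7)
    bin <- cut(x, unique(edges), include.lowest = TRUE, labels = FALSE)
    data.frame(
      bin = sort(unique(bin)),
      belief_mid = tapply(x, bin, mean),
      mean_change = tapply(y, bin, mean),
      se = tapply(y, bin, function(v) sd(v) / sqrt(length(v))),
      n = as.integer(table(bin)), row.names = NULL
    )
  }
  by_belief <- bin_summary(prev_belief[zero], dbel[zero], n_bins)
  by_prev <- do.call(rbind, lapply(c(-1, 0, 1), function(s) {
    sel <- zero & sign(prev_coh) == s
    if (sum(sel) < 10) return(NULL)
    cbind(prev_coherence_sign = s,
          bin_summary(prev_belief[sel], dbel[sel], 5))
  }))
  out <- list(by_belief = by_belief, by_prev_coherence = by_prev)
  if (!is.null(fit)) {
    maps <- NULL
    params <- params_from_vector(unname(fit$coefficients), fit$model,
                                 fit$lag_update)
    ap <- accumulator_params(kappa = params$kappa, bound_A = params$bound_A,
                             dt_map = fit$grid$dt, n_bins = fit$grid$n_bins)
    maps <- build_likelihood_maps(ap,
                                  include_zero_both = fit$include_zero_both)
    ll <- dataset_loglik(data, params, maps, fit$conf_transformed)
    pu_hat <- invert_confidence_to_counterfactual(
      ifelse(data$choice == "R", fit$conf_transformed,
             1 - fit$conf_transformed), ll$EB)
    prev_ok <- !is.na(prev_belief)
    mov_avg <- function(y, w = 100) {
      n <- length(y)
      half <- w %/% 2
      vapply(seq_len(n), function(i) {
        mean(y[max(1, i - half):min(n, i + half)])
      }, numeric(1))
    }
    out$by_counterfactual <- do.call(rbind, lapply(c("L", "R"),
      function(ch) {
        sel <- prev_ok & data$choice == ch
        x <- pu_hat[sel]
        y <- dbel[sel]
        o <- order(x)
        data.frame(choice = ch, pu = x[o], change_smoothed = mov_avg(y[o]))
      }))
  }
  out
}
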