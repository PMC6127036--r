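# shared fixtures, built once per test run

.maps_cache <- new.env(parent = emptyenv())

# default-condition likelihood maps (kappa 14, bound 1.2, full grid)
default_maps <- function() {
  if (is.null(.maps_cache$full)) {
    ap <- accumulator_params(kappa = 14, bound_A = 1.2)
    .maps_cache$full <- build_likelihood_maps(ap)
  }
  .maps_cache$full
}

# coarser fitting-resolution maps for the same condition
fitting_maps <- function(kappa = 14, bound_A = 1.2) {
  key <- paste0("fit_", kappa, "_", bound_A)
  if (is.null(.maps_cache[[key]])) {
    ap <- accumulator_params(kappa = kappa, bound_A = bound_A,
                             dt_map = 2e-3, n_bins = 255L)
    .maps_cache[[key]] <- build_likelihood_maps(ap)
  }
  .maps_cache[[key]]
}

default_params <- function(...) {
  observer_params(kappa = 14, bound_A = 1.2, phi = 0.8, omega1 = 1,
                  omega2 = 0.5, ...)
}

# simulate a full synthetic subject under the study conditions
make_obs_data <- function(n_blocks, seed, params = default_params(),
                          maps = default_maps(), subject_id = "s1", ...) {
  des <- generate_experiment(n_blocks, seed, subject_id = subject_id)
  simulate_observer(des, params, maps, seed = seed + 500L, ...)
}

# independent reimplementation of the report-lag filter (test oracle)
apply_lag_for_test <- function(b, alpha, block) {
  f <- numeric(length(b))
  fp <- 0.5
  cur <- NULL
  for (i in seq_along(b)) {
    if (!identical(block[i], cur)) {
      cur <- block[i]
      fp <- 0.5
    }
    fp <- fp + (b[i] - fp) * (1 - alpha)
    f[i] <- fp
  }
  f
}

# minimal fit-like object at known parameters (to exercise prediction and
# comparison machinery without an optimisation run)
fixed_fit <- function(data, model = "bayesian",
                      coefs = c(kappa = 14, bound_A = 1.2, phi = 0.8,
                                omega1 = 1, omega2 = 0.5)) {
  structure(list(model = model, coefficients = coefs, logLik = NA_real_,
                 n_params = length(coefs), n_trials = nrow(data),
                 data = data, conf_transformed = data$confidence_raw,
                 lag_update = FALSE,
                 grid = list(n_bins = 255L, dt = 2e-3),
                 include_zero_both = TRUE,
                 diagnostics = list(n_floor = 0)),
            class = "observer_fit")
}

# stimulus table of single-trial blocks (the prior never leaves p0)
single_trial_design <- function(n, coherences = COHERENCES, seed = 1) {
  set.seed(seed)
  mag <- sample(coherences, n, replace = TRUE)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  data.frame(subject_id = "s1", block_id = seq_len(n), trial_index = 1L,
             base_rate = 0.6, coherence_signed = sgn * mag,
             duration_s = sample_duration(n),
             direction = ifelse(sgn > 0, "R", "L"))
}
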