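#' Accumulator parameters
#'
#' Container for the bounded drift-diffusion accumulator. The drift on a
#' trial with signed coherence `c` is `kappa * c` per second; the diffusion
#' variance is fixed at 1 per second (not a parameter: any other value is
#' absorbed by rescaling `kappa` and `bound_A`). Absorbing bounds sit at
#' `+/- bound_A`.
#'
#' @param kappa signal-to-noise scale (> 0).
#' @param bound_A bound height in evidence units (> 0).
#' @param dt_sim Euler-Maruyama step for trial simulation, seconds.
#' @param dt_map time step for density propagation, seconds.
#' @param n_bins number of interior evidence bins across `(-A, A)`; must be
#'   odd so a grid node sits at 0.
#' @param t_max latest stimulus offset, seconds.
#' @return an object of class `accumulator_params`.
#' @export
accumulator_params <- function(kappa, bound_A, dt_sim = 5e-4, dt_map = 1e-3,
                               n_bins = 511L, t_max = 0.9) {
  stopifnot(kappa > 0, bound_A > 0, dt_sim > 0, dt_map > 0, t_max > 0)
  n_bins <- as.integer(n_bins)
  if (n_bins %% 2L == 0L) n_bins <- n_bins + 1L
  structure(list(kappa = kappa, bound_A = bound_A, dt_sim = dt_sim,
                 dt_map = dt_map, n_bins = n_bins, t_max = t_max),
            class = "accumulator_params")
}

#' Propagate the evidence density for one signed coherence
#'
#' Numerically solves the Fokker-Planck equation for the bounded accumulator
#' (Crank-Nicolson in time, exponentially fitted flux in evidence) and
#' returns the interior density at every time step together with the mass
#' absorbed at each bound per step. Interior mass plus cumulative absorbed
#' mass is 1 at every step up to rounding.
#'
#' @param params an [accumulator_params()] object.
#' @param c signed coherence in `[-1, 1]`.
#' @param t_max propagation horizon, seconds (defaults to `params$t_max`).
#' @param min_bins smallest admissible number of evidence bins.
#' @return list with `interior` (bins x steps density matrix), `ftop`,
#'   `fbot` (absorbed mass per step at `+A` / `-A`), `e_grid`, `t_grid`,
#'   `de`, `dt`.
#' @export
propagate_density <- function(params, c, t_max = params$t_max,
                              min_bins = 31L) {
  stopifnot(inherits(params, "accumulator_params"), abs(c) <= 1)
  if (params$n_bins < min_bins) {
    stop("evidence grid too coarse to resolve the bound: ", params$n_bins,
         " bins < minimum ", min_bins)
  }
  nt <- as.integer(round(t_max / params$dt_map))
  res <- cpp_fp_propagate(params$kappa * c, params$bound_A, params$n_bins,
                          params$dt_map, nt)
  res$e_grid <- seq(-params$bound_A + res$de, params$bound_A - res$de,
                    length.out = params$n_bins)
  res$t_grid <- seq_len(nt) * params$dt_map
  res
}

#' Build the per-coherence likelihood maps and the counterfactual posterior
#'
#' Propagates the density for each coherence magnitude (negative coherences
#' follow by mirror symmetry), forms the direction marginals
#' `p(e, te | d)` with `p(c | d)` uniform over the coherences compatible
#' with direction `d`, and computes the counterfactual posterior map
#' `pu(R | e, te)` on the grid, including its values at the two absorbing
#' bounds. Grid nodes that no coherence can reach (both marginals zero) are
#' marked `NA`; looking them up downstream is an error.
#'
#' @param params an [accumulator_params()] object.
#' @param coherences the set of coherence magnitudes (must include 0 first).
#' @param include_zero_both should 0% coherence count as compatible with
#'   both directions (default) or be excluded from the marginals?
#' @param t_max propagation horizon, seconds.
#' @return an object of class `likelihood_maps`.
#' @export
build_likelihood_maps <- function(params, coherences = COHERENCES,
                                  include_zero_both = TRUE,
                                  t_max = params$t_max) {
  stopifnot(inherits(params, "accumulator_params"))
  coherences <- sort(unique(abs(coherences)))
  nt <- as.integer(round(t_max / params$dt_map))
  ne <- params$n_bins
  m <- cpp_build_maps(params$kappa, params$bound_A, ne, params$dt_map, nt,
                      coherences, include_zero_both)
  structure(list(
    D = m$D, ftop = m$ftop, fbot = m$fbot, pu = m$pu, pu_top = m$pu_top,
    pu_bot = m$pu_bot, de = m$de, dt = params$dt_map,
    e_grid = seq(-params$bound_A + m$de, params$bound_A - m$de,
                 length.out = ne),
    t_grid = seq_len(nt) * params$dt_map,
    kappa = params$kappa, bound_A = params$bound_A,
    coherences = coherences, include_zero_both = include_zero_both
  ), class = "likelihood_maps")
}

#' Simulate terminal evidence for trials
#'
#' Euler-Maruyama simulation of the accumulator: increments are
#' `Normal(kappa * c * dt, dt)`; accumulation stops at the first bound
#' crossing (evidence clamped to `+/-A`, the crossing assigned to the end of
#' the step) or at stimulus offset `T`.
#'
#' @param params an [accumulator_params()] object.
#' @param c signed coherence (scalar or length-`n` vector).
#' @param T stimulus duration(s) in seconds.
#' @param n number of trials (recycled against `c` and `T`).
#' @return data.frame with columns `e`, `te`, `bound_hit`.
#' @export
simulate_trial_evidence <- function(params, c, T, n = max(length(c),
                                                          length(T))) {
  stopifnot(inherits(params, "accumulator_params"))
  mu <- rep_len(params$kappa * c, n)
  Td <- rep_len(T, n)
  res <- cpp_sim_evidence(mu, Td, params$bound_A, params$dt_sim)
  data.frame(e = res$e, te = res$te, bound_hit = as.logical(res$hit))
}

#' @export
print.likelihood_maps <- function(x, ...) {
  cat("Likelihood maps for bounded drift-diffusion\n")
  cat(sprintf("  kappa = %.4g, A = %.4g, %d evidence bins, dt = %g s, t up to %g s\n",
              x$kappa, x$bound_A, nrow(x$pu), x$dt, max(x$t_grid)))
  cat(sprintf("  coherence magnitudes: %s (0%% compatible with both: %s)\n",
              paste(x$coherences, collapse = ", "),
              if (x$include_zero_both) "yes" else "no"))
  invisible(x)
}
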