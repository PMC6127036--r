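# priorlearn

Tools for studying how a decision maker can learn a concealed prior
probability (a *base rate*) purely from their own perceptual decisions,
without any trial-by-trial feedback.

## The scientific problem

In a blocked random-dot-motion task, an observer judges on each trial
whether the net motion is rightward or leftward and reports confidence in
that judgment. Within a block of 15–42 trials one direction is more likely:
the base rate *B* — the probability that motion is rightward — is drawn from
{0, 0.2, 0.4, 0.6, 0.8, 1} and concealed from the observer. The observer
also reports, after every trial, a *belief*: the probability that the block
favours rightward. The puzzle is circular: choices should exploit the base
rate, but the base rate can only be estimated from those same (possibly
biased, never externally validated) choices.

The model implemented here resolves the circularity with *counterfactual
confidence*. Choice and confidence arise from bounded accumulation of noisy
momentary evidence: with signed coherence *c*, evidence accumulates with
drift `κc` and unit variance per second until it hits an absorbing bound at
`±A` or the stimulus ends, leaving a terminal state `(e, tₑ)`. Under a
neutral prior the posterior probability of rightward given that state,
`p_u(R | e, tₑ)`, follows from Fokker–Planck solutions of the bounded
diffusion, marginalised over coherence. The observer carries a distribution
`p(B)` over the six base rates and combines its expectation `E[B]` with the
counterfactual posterior to choose and to assign confidence:

    p(R | e, tₑ, E) = E[B] · p_u / (E[B] · p_u + (1 − E[B]) · (1 − p_u))

Crucially, `p(B)` itself is updated not with the reported (prior-laden)
confidence but with the counterfactual one:

    p(B | e, tₑ, E) ∝ (B ν_r + (1 − B) ν_l) · p(B | E),   ν_r = p_u(R | e, tₑ)

which avoids the self-reinforcing feedback a biased posterior would create.
The reported belief is `Σ_{B > 0.5} p(B)`. Rival update rules — choice-only
(`ν_r ∈ {0, 1}`), choice-confidence (`ν_r` = reported posterior), a flexible
empirical logistic rule, and a Bayesian/choice-confidence mixture — are
implemented behind the same interface, along with two first-order lag
variants (on the belief report only, or on the `p(B)` update itself).

Models are fitted per subject by maximum likelihood on choices and
binarised confidence (low = lowest 30% of reports; the criterion `φ`
separates high from low probability-correct), with a rank-preserving
transformation matching the reported confidence distribution to the
model's, and multi-start bounded derivative-free optimisation. Fitted
models then *predict* the belief reports — which were never fitted — and a
battery of regression and lag diagnostics evaluates those predictions.

## Worked example

```r
library(priorlearn)

# the worked posterior: counterfactual 0.7, expected base rate 0.57
direction_posterior(0.7, 0.57)
#> [1] 0.7556818

# simulate a synthetic subject under the study conditions
design <- generate_experiment(n_blocks = 150, seed = 7)
params <- observer_params(kappa = 14, bound_A = 1.2, phi = 0.8,
                          omega1 = 1, omega2 = 0.5)
maps   <- build_likelihood_maps(accumulator_params(14, 1.2))
data   <- simulate_observer(design, params, maps, seed = 1)
mean(data$choice == data$direction)
#> [1] 0.8509317

# mean end-of-block belief, by concealed base rate
last <- !duplicated(data$block_id, fromLast = TRUE)
round(tapply(data$belief_report[last], data$base_rate[last], mean), 3)
#>     0   0.2   0.4   0.6   0.8     1
#> 0.007 0.082 0.249 0.636 0.927 0.996

# fit the Bayesian observer back to its own behaviour (takes ~1 min)
fit <- fit_observer(data, "bayesian", n_starts = 5, seed = 11)
round(coef(fit), 3)
#>   kappa bound_A     phi  omega1  omega2
#>  14.201   1.238   0.798   1.151   0.421
```

The simulated observer reaches ~85% accuracy, its belief reports spread out
monotonically with the concealed base rate, and the generating accumulator
parameters are recovered to within a few percent.

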