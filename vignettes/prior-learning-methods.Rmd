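---
title: "Learning a concealed base rate from one's own decisions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning a concealed base rate from one's own decisions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorlearn)
```

## The inference problem

An observer discriminates the direction of random-dot motion in blocks of
15–42 trials. Within a block, the probability that motion is rightward —
the base rate $B$ — is fixed at one of $\{0, 0.2, 0.4, 0.6, 0.8, 1\}$ but
concealed; no feedback arrives until the block ends. A good observer should
use $B$ to bias choices and sharpen confidence, yet can only estimate $B$
from those same unvalidated choices. If the observer naively re-used the
confidence it reports (which already incorporates its current estimate of
$B$) to update that estimate, the prior would feed on itself: a slight
rightward bias would inflate rightward confidence, which would inflate the
bias, without any new information. The model implemented by this package
avoids the double counting by updating $p(B)$ with *counterfactual*
confidence: the posterior the observer would hold if both directions were
equally likely, which is simply the normalised likelihood of the evidence.

## The generative model

**Stimuli.** Block lengths are truncated-geometric ($p = 1/15$ on
15–42); base rates are uniform over the six values; the number of rightward
trials in a block of $n_{tr}$ trials is $\mathrm{round}(B\,n_{tr})$ in a
random order; the six coherence magnitudes $\{0, 3.2, 6.4, 12.8, 25.6,
51.2\}\%$ are repeated up to the first multiple of six *strictly larger*
than $n_{tr}$, shuffled, and truncated; durations are truncated-exponential
($\tau = 0.6$ s on $[0.1, 0.9]$ s). Two readings deserve note. First, the
strict reading of "larger than" means a 18-trial block draws from a pool of
24, so per-magnitude counts can differ by more than one exactly when
$n_{tr}$ is a multiple of six; for all other lengths the counts differ by
at most one. Second, 0%-coherence trials carry a nominal direction, because
the base-rate count is over all trials. Rounding of $B\,n_{tr}$ is
half-away-from-zero; no in-range combination actually produces a half, so
the convention is fixed only for safety.

**Accumulator.** Momentary evidence on a trial with signed coherence $c$ is
Gaussian with mean $\kappa c\,\Delta t$ and variance $\Delta t$; the
accumulated evidence $e$ terminates at absorbing bounds $\pm A$ or at
stimulus offset $T$, leaving the pair $(e, t_e)$. The diffusion variance is
fixed at 1/s — it is not a parameter, because any other value is absorbed
by rescaling $\kappa$ and $A$.

**Hierarchy.** The observer carries $p(B)$ over the six base rates,
initialised each block at a symmetric two-parameter prior with
unnormalised weights $(\omega_2, \omega_1, 1, 1, \omega_1, \omega_2)$. The
counterfactual posterior $p_u(R \mid e, t_e)$ is the likelihood ratio of
the terminal state under the two directions, marginalised over coherence
with $p(c \mid d)$ uniform over the compatible coherences. The direction
posterior multiplies $p_u$ by the prior expectation $E[B]$ and normalises;
the choice is its sign relative to $0.5$ and confidence is its value for
the chosen side. After each trial,
$p(B) \propto (B\,\nu_r + (1-B)\,\nu_l)\,p(B)$ with $\nu_r = p_u$ for the
Bayesian rule, and the reported belief is $\sum_{B > 0.5} p(B)$.

**Rival update rules.** `choice_only` sets $\nu_r$ to the choice indicator;
`choice_confidence` to the reported posterior for rightward; `mixture` to
$\beta p_u + (1-\beta)\,p(R \mid e, t_e, E)$; and `empirical` to a
five-parameter logistic in the chosen-side confidence and prior
expectation,
$\beta_0 + \beta_1\,\mathrm{conf} + \beta_2\,p_d + \beta_3\,
\mathrm{conf}\,p_d + \beta_4\,\mathrm{conf}^2 p_d$: an intercept, both
main effects, and two distinct nonlinear interactions, enough to express
the Bayesian rule's confidence-by-expectation interaction as well as both
degenerate rules. The empirical rule is exploratory; none of the package's
quantitative checks depend on its exact basis.

**Lags.** Two first-order filters with constant $\alpha$ are available: on
the *report* only ($f_i = f_{i-1} + (b_i - f_{i-1})(1-\alpha)$, internal
$p(B)$ untouched, marker reset to $0.5$ at block starts) and on the
*update* itself (the carried $p(B)$ is an affine combination of the
previous and fully updated distributions). $\alpha = 0$ reproduces the
no-lag model exactly — this is special-cased so the identity is bitwise,
not merely numerical.

## Numerical methods

**Fokker–Planck solver.** The joint density $p(e, t_e \mid c)$ is
propagated on a grid by a finite-volume scheme: Chang–Cooper exponential
flux weighting in evidence (exact for the steady-state exponential profile,
positivity-preserving at any drift) and Crank–Nicolson in time, with three
implicit-Euler startup steps to damp the delta initial condition. The mass
absorbed at each bound per step is recovered from the boundary column sums
of the discrete generator, which makes interior-plus-absorbed mass
conservation exact up to rounding (observed $< 10^{-11}$ over 900 steps).
Defaults: 511 interior evidence bins (odd, so a node sits at $e = 0$) and a
1 ms time step. These choices were validated against three independent
oracles: the gambler's-ruin closed form for absorption probabilities
(agreement $\sim 10^{-14}$, a consequence of the exponential fitting),
$10^5$-trial Monte-Carlo joint histograms (chi-square consistent), and the
unbounded-diffusion limit $p_u = \mathrm{logistic}(2\kappa|c|e)$.

**Trial simulation.** Euler–Maruyama with a 0.5 ms step and a
Brownian-bridge correction for within-step bound crossings (without the
correction the simulator systematically under-absorbs by $O(\sqrt{\Delta
t})$ and is detectably inconsistent with the propagated density). Bound
crossings are assigned to the end of their step; curtailed trials stop at
exactly $T$.

**Counterfactual map.** $p_u$ is stored on the propagation grid, with
dedicated values at the two absorbed columns. Grid nodes that no coherence
can reach (both direction marginals underflow to zero) are marked `NA`;
looking one up is an error rather than a silent $0.5$. Whether 0%
coherence is "compatible" with both directions in $p(c \mid d)$ is
genuinely ambiguous; we include it in both (switchable via
`include_zero_both`), which preserves the map's mirror symmetry either
way.

**Likelihood.** Each trial contributes the probability of its observed
(choice, high/low confidence) pair: the integral of $p(e, t_e \mid c, T)$
over the region where the biased-prior posterior for the chosen side falls
in $(0.5, \varphi)$ or $[\varphi, 1]$. Because the posterior is monotone in
$p_u$ at fixed $E[B]$, the regions reduce to thresholds on the stored map,
so each trial costs one pass over an evidence column and the absorbed-flux
history. Between trials $p(B)$ is propagated from the *observed* choice and
transformed confidence; for the Bayesian and mixture rules the
counterfactual value is recovered by the exact odds inversion
$\mathrm{odds}(p_u) = \mathrm{odds}(\mathrm{conf}_R)(1 - E[B])/E[B]$, with
reports clipped to $[10^{-4}, 1 - 10^{-4}]$ first (endpoint reports
otherwise have infinite odds; results are insensitive to the clip within a
few orders of magnitude). Zero-mass
outcomes are floored at $\log 10^{-10}$ and counted in the diagnostics.

**Fitting.** `fit_observer()` maximises the likelihood over
$(\kappa, A, \varphi, \omega_1, \omega_2)$ plus any rule-specific extras,
on logit-rescaled parameters within bounds
($\kappa \in [1, 60]$, $A \in [0.3, 5]$, $\varphi \in [0.505, 0.999]$,
$\omega \in [0, 20]$ — brackets for plausible psychophysical values,
exposed as configuration), restarted from Latin-hypercube points. Each
restart runs a short Nelder–Mead leg, which is robust to the objective's
grid-induced micro-kinks, followed by a quasi-Newton polish (`nlminb` with
numerical gradients) that converges an order of magnitude faster than a
simplex alone; the restarts, not the local method, are responsible for
escaping local optima. One such optimum is worth knowing about: a
large-bound ridge (the bound so high it is rarely hit) that fits
noticeably worse than the true basin but attracts a fraction of random
starts. The
rank-preserving confidence transformation (raw reports re-quantiled onto a
model simulation of the same stimuli; ties get their band mean) is
refreshed at each restart's starting point and again at its optimum, with
one re-optimisation if the refresh moves the log-likelihood by 0.01 or
more. Whether the propagation should condition on the transformation from
the current or the previous iterate is a genuinely open ordering question;
refreshing at the incumbent and re-optimising once converges to a fixed
point of the same alternation and is what we implement. The likelihood is
evaluated on a 255-bin / 2 ms grid during fitting (the maps are rebuilt at
every candidate $(\kappa, A)$); halving the resolution shifts the
likelihood's argmax in $\kappa$ by well under 2%, so the coarser grid is a
pure speed choice.

**Identified criterion.** With real reports the high/low split comes from
the per-subject 30th percentile (type-1 quantile, ties to "low"; a
degenerate all-identical vector yields all-"high" with a warning). In
simulation the category is generated directly by the criterion $\varphi$,
so that in recovery studies "the true $\varphi$" is well defined; the
30%-rule remains the data-driven path.

## Synthetic study conditions

The generator's defaults are the study conditions used throughout the
tests: $\kappa = 14$, $A = 1.2$, $\varphi = 0.8$, $\omega_1 = 1$,
$\omega_2 = 0.5$, no lag. $\kappa$ and $A$ were chosen once to give
mid-80s percent accuracy over the task's coherence mixture with a
realistic bound-crossing fraction; $\omega_2 < 1$ encodes the
under-weighting of extreme base rates that real observers exhibit;
$\varphi = 0.8$ sits near the upper-third of the simulated confidence
distribution, keeping both categories well populated. A synthetic subject
is 150 blocks (roughly 4,000 trials), matching the per-subject volume of a
full experiment.

What the generator emulates: the task's stimulus statistics, the
within-block accumulation of bias, lapse-free Bayesian (or rival) belief
updating, and continuous confidence/belief reports on their natural
scales. What it does not: motor noise on the reporting arcs, sequential
non-stationarities (fatigue, learning-to-learn across sessions), lapses,
and idiosyncratic confidence-scale distortions (the rank-preserving
transformation exists precisely because real scales are distorted; on
synthetic data it is nearly the identity). Passing recovery tests
therefore demonstrates internal consistency of estimator and generator,
not robustness to these artefacts.

## What the tests establish

- *Invariants*: $p(B)$ stays normalised over $10^5$ chained updates;
  $\nu_r = 1/2$ is a bitwise no-op; the counterfactual map satisfies
  $p_u(e) + p_u(-e) = 1$; the four outcome masses always sum to one; the
  confidence inversion is the exact inverse of the direction posterior.
- *Oracle equivalence*: solver vs. Monte Carlo, gambler's ruin, and the
  logistic limit, at the tolerances stated above.
- *Recovery*: from 150 synthetic blocks, $\kappa$ and $A$ are recovered
  within 15% and $\varphi$ within 0.05 (three seeds, five restarts). Model
  recovery uses three synthetic subjects per generator: the summed
  log-likelihood prefers the generating rule in both directions
  (Bayesian-generated and choice-only-generated data).
- *Belief dynamics*: end-of-block belief is monotone in the base rate;
  first-trial belief is neutral; on 0%-coherence trials the mean belief
  change is zero without lag and tracks the held belief with a report lag —
  the signature separating report lag from update lag.
- *Lag recovery*: the report-lag constant is identified within 0.1 from
  noiseless filtered sequences, and $\alpha = 0$ returns the no-lag
  predictions exactly.

Problem sizes in the tests (number of blocks, Monte-Carlo counts, restart
counts) are the package's own desk-scale choices: large enough that the
stochastic tolerances above are meaningful, small enough to run routinely.

## Known limitations

- Reaction times are not modelled (durations are experimenter-controlled);
  collapsing bounds and across-trial drift variability are out of scope.
- The per-trial likelihood treats the confidence *category*, not its exact
  analog value; analog comparisons enter only through the rank-preserving
  transformation.
- `fit_observer()` fits one subject at a time; there is no hierarchical
  pooling across subjects, and no bootstrap intervals on the fitted
  parameters.
- The empirical rule's logistic basis is one reasonable five-parameter
  choice among several; conclusions about the core rules do not rest on
  it.
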