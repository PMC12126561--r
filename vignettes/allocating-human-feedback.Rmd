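---
title: "Allocating scarce human feedback in chatbot-based smoking cessation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allocating scarce human feedback in chatbot-based smoking cessation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coachrl)
```

# The problem

A virtual coach assigns smokers and vapers short preparatory activities for
quitting, over up to five sessions. Between sessions a human coach can send a
feedback message, but human time is scarce: in a live deployment only about
a third of active users can be reached per day. `coachrl` implements the full
analysis chain for deciding *when* and *to whom* feedback should go:

1. a synthetic cohort generator emulating the micro-randomized study design,
2. interaction-sample construction, median imputation, and percentile state
   abstraction with greedy Q-difference feature selection,
3. estimation of a finite Markov decision process (MDP) and epsilon-optimal
   planning under feedback costs,
4. population simulations (four reference policies, a cost sweep),
5. an ethically extended MDP with multi-principle rewards tuned to a fixed
   daily feedback capacity, and
6. Bayesian random-intercept models for the short-term feedback effects.

# The synthetic cohort

Every downstream stage is exercised on synthetic data with the statistical
structure the analysis assumes, so the whole pipeline is testable without
access to the original study records.

Each person has a latent engagement intercept $u_i \sim N(0, \sigma_u)$
(default $\sigma_u = 1$ effort point). Sessions are attended until dropout,
which strikes independently after each session with probability 0.13
(chosen to match a decline from 679 active participants to roughly 504 by
the fifth session; the live-application scenario uses 0.15, a separate
configuration). Between consecutive attended sessions, feedback is assigned
independently with probability 0.20, mirroring the micro-randomized design.

Effort reported in session $t$ (for the activity assigned in session
$t-1$) is a rounded, clipped draw from

$$ e \sim N\!\big(\bar e + u_i + \beta_{dir}\,\mathbb{1}[\text{feedback in last gap}]
   + \beta_{del}\,\mathbb{1}[\text{any earlier feedback}]
   + \beta_{dose}\,\#\text{earlier messages},\ \sigma_e\big) $$

with defaults $\bar e = 5.74$, $\sigma_e = 2.75$, $\beta_{dir} = 0.08$,
$\beta_{del} = 0.39$, $\beta_{dose} = 0$ on the 0–10 scale; return
likelihood is analogous on its −5..5 scale with $\beta_{del} = 0.29$.
Rounding and clipping match the discrete bounded response scales; they
attenuate configured effects slightly (a percent-level effect at these
parameter values), which the parameter-recovery tests absorb within their
posterior uncertainty.

The five state features (importance, self-efficacy, feedback appreciation,
energy, activity difficulty) are discretized normals whose means load on
$u_i$, inducing the correlation between state and engagement that feature
selection needs. Two generator choices deserve emphasis:

* **A state-mediated feedback channel.** Feedback in the preceding gap
  shifts the next session's feature means (defaults +0.5 importance, +0.5
  self-efficacy, +1.0 appreciation). Without such a channel the feedback
  action would leave the state transition kernel untouched, every state's
  Q-gain would collapse to the tiny direct reward effect, and the cost-sweep
  and capacity analyses would be degenerate. The loadings and shifts are
  configuration, not estimates: the joint distribution of the raw features
  in the real study is unknown, and this is the simplest structure that
  supports the downstream analyses.
* **The delayed-effect boundary.** "Has received feedback" is defined as
  feedback in any gap *strictly before* the most recent one, in both the
  generator and the delayed-effect model, keeping the configured truth and
  the model covariate aligned for recovery experiments.

The questionnaire generator draws each respondent's 100-point allocation
over the 11 principle statements from a Dirichlet-multinomial with
configurable mean weights (defaults: the five aggregate group weights split
equally within groups), so sample mean proportions are unbiased for the
configured means.

What the generator does *not* emulate: activity content and difficulty
semantics, informative dropout (dropout is independent of state and
feedback), non-normal response styles (e.g., end-of-scale piling), and any
direct dependence of features on past effort. Passing tests therefore show
that the analysis machinery is correct under its own assumptions, not that
the substantive study findings generalize.

# Interaction samples and state abstraction

An interaction sample is a pair of consecutive attended sessions; it is
kept only when the second session reports effort, return likelihood, and
perceived importance. Remaining feature gaps are filled with the feature's
sample population median (pooled over both sessions of the pair).

Features are abstracted by percentiles: a median split for two levels
(values equal to the median go to the lower level) and tertile cuts
(33.3rd/66.7th percentiles, R type-7 quantiles, same tie rule) for three.
Cut points are computed once on the analysis sample's first-session values
and frozen, so simulated or future data are abstracted identically.

Base state features are selected greedily in the spirit of the G-algorithm:
at each step every remaining candidate is abstracted to the scheduled level
count (3, then 2, then 2), an MDP over (already selected x candidate) is
estimated and solved, and the candidate scores the maximum over actions and
candidate-level pairs of $|\Delta Q|$, averaged over the level combinations
of the already-selected features. The maximum-over-pairs with context
averaging is the package's choice of aggregation — the most sensitive of
the stable variants we considered; ties break by declaration order for
determinism. The selected 3 x 2 x 2 space has 12 states labeled by digit
strings such as `201`.

**Known limitation.** With cohorts of a few hundred people the Q-difference
scores of competing candidates are close to their estimation noise, and the
selected triple varies across generator seeds (session number and energy
sometimes displace appreciation). The packaged analysis uses the fixed
default seed; conclusions about *which* features matter should not be read
off a single synthetic run.

# The base MDP

States are the 12 abstracted states, actions are giving/not giving
feedback, and the discount factor is $\gamma = 0.85$. Effort maps to
reward through the piecewise-linear anchor map (mean effort to 0.5,
endpoints to 0 and 1); its inverse converts simulated rewards back to the
effort scale. The reward function is the per-(state, action) mean sample
reward, with empty cells falling back to the grand mean (flagged in support
counts). Transitions are estimated with an additive pseudo-count
$\lambda = 1$: on cohorts of this size, unsmoothed rows backed by a
handful of observations produce degenerate kernels, so a single
pseudo-count per successor keeps every row well-defined; $\lambda$ is
configuration and $\lambda = 0$ reproduces raw frequencies. The population mean effort is stored in the
model so all later inversions reuse the same constant.

Planning uses Gauss-Seidel value iteration sweeping states in sorted label
order, stopping when the sup-norm of successive value changes drops below
$\epsilon(1-\gamma)/\gamma$ with $\epsilon = 0.001$ (the sup-norm rather
than the span: the span criterion is blind to uniform value shifts and
degenerates on single-state models, and the sup-norm is never weaker).
Initialization is $V \equiv 0$; greedy ties break toward *not* giving
feedback, conserving the scarce resource. An exhaustive-enumeration oracle
(all $2^{|S|}$ deterministic policies, each evaluated by an exact linear
solve) verifies epsilon-optimality in the test suite; it is never the
production planner.

# Population simulations

The cohort is propagated as an exact distribution over states
(`mass' = mass x T`), eliminating Monte-Carlo noise; a seeded rollout mode
exists purely as a cross-check. Four reference policies are compared over
100 steps from the observed first-session distribution: the cost-free
optimal policy, always, never, and a theoretical half-half mixture. The
reported trajectory metric is always the *base* (cost-free) reward, also in
the cost sweep where planning used the cost-adjusted reward: the reward
drop at higher costs should reflect withheld feedback, not mechanical cost
subtraction. A configuration switch reports the adjusted reward instead.

# The ethically extended model

The base state is extended by a fixed priority level (3 values) and the
time since the last feedback (0, 1, 2+), giving 108 states. Both extra
features only enter the auxiliary rewards; base transitions factorize,
priority is static, and the time since feedback resets on feedback and
otherwise ratchets. Each auxiliary reward rescales its measure to [0, 1]
and is granted *only when feedback is allocated* — granted unconditionally
they would be policy-invariant constants:

* first-come-first-served: time since last feedback / 2,
* sickest-first: the shortfall of $R(s, a{=}0)$ rescaled over its observed
  range ("would engage least without feedback" is a verbal principle; the
  no-feedback reward is its natural model-level operationalization),
* priority: priority level / 2,
* autonomy: the appreciation level of the base state (0 or 1).

Weights over {prognosis, fcfs, sickest, priority, autonomy} default to the
aggregate questionnaire means (30.82/22.18/25.34/13.04/8.62%). Two-principle
policies renormalize the pair's weights by their ratio, an explicit package
choice since the source analysis does not state its split.

**Capacity tuning.** The live application holds 166 concurrent spots, up to
nine sessions, 15% dropout per session, vacated spots refilled from the
first-session distribution with uniform priorities. The steady state of
this turnover process is computed by exact expectation propagation over
(extended state, session age). The feedback cost is bisected so the
optimal policy's steady-state feedback fraction hits the 35% capacity
within 0.01. Two refinements keep this well-defined:

* Deterministic optimal policies change at discrete cost thresholds, so
  the achieved fraction is a step function. When no step lands within
  tolerance, the two epsilon-optimal policies bracketing the target are
  blended by randomizing the action in the states where they disagree —
  the standard constrained-MDP device (an optimal policy under a single
  linear constraint randomizes in at most a measure-zero set of states) —
  and the blend weight is bisected.
* Auxiliary rewards can make *withholding* feedback attractive even at
  zero cost: under the fcfs reward it pays to let the clock ratchet before
  allocating, capping the achievable fraction below the target. The
  bracket therefore extends to negative costs. The tuned cost is then read
  as the signed Lagrange multiplier of the capacity constraint — a
  subsidy when the constraint binds from below.

Subgroup shares are reported both from the deterministic steady state and
from a seeded agent-based simulation of the 166 spots (the two agree within
Monte-Carlo error; the agent log is what a deployed system would record).
Prognosis and sickest-first subgroups are occupancy-weighted tertiles of
the base Q-gain and of the no-feedback reward; fcfs and priority use their
three feature values; autonomy its two.

# Bayesian effect models

Direct, delayed, and dose effects of feedback on effort and return
likelihood are estimated with hierarchical normal models: outcome = grand
mean + person random intercept + fixed effect(s). The textbook-style
diffuse priors are made concrete as normal(0, 10) on the mean and slopes
and half-normal(0, 5) on both SDs; covariates are centered inside the
sampler (slopes are unaffected, mixing improves markedly). Sampling uses
JAGS with two chains and fixed per-chain seeds; split-R-hat above 1.01
triggers a warning rather than a silent estimate. Outcomes are modeled as
continuous normals despite being bounded integers — the conventional
simplification for Likert-style engagement scales.

Each fit is summarized by the posterior mean, the 95% highest-density
interval (narrowest window containing 95% of draws), $P(b > 0)$, and a
standardized effect $d = \hat b / \hat\sigma_{resid}$. The residual SD is
the denominator of choice here because it is the noise scale the
hierarchical model itself separates from between-person variation;
dividing by the raw outcome SD would conflate the two.

# Problem sizes and numerical choices

The packaged analysis and test suite run at the study scale: 679 persons
(about 2,000 interaction samples), 100-step trajectories, 200 simulated
live-application days, and 20-replicate recovery experiments at 1,000
persons with two MCMC chains of 1,000 retained draws each after short
warm-up — sizes at which every quantity reported by the scripts is stable
to well within the tolerances used to assess it. Degenerate inputs error
loudly (constant outcomes, all-missing features, unnormalized weights,
non-stochastic transition rows); constant features abstract to a single
level with a warning; empty estimation cells fall back to flagged
defaults rather than NaNs.

# Reproducing the analysis

The numbered scripts under `analysis/` run the stages in order on the
default seed and write their tables under `results/`; every computation
they perform is an exported, unit-tested package function, and
`run_pipeline()` executes the same chain programmatically from a single
YAML-serializable configuration.
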