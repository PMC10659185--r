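---
title: "Value-updating and boundary-updating accounts of corrective feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-updating and boundary-updating accounts of corrective feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmfeedback)
```

## The scientific question

In binary perceptual classification with trial-to-trial corrective
feedback, what does the decision-maker learn from being told "correct" or
"incorrect"?  Two families of answers make sharply different predictions.

Under a **value-updating** account, feedback is treated like reward:
the decision-maker maintains values $V_S, V_L$ for the *small* and *large*
options and reinforces the chosen one by a reward prediction error that is
scaled by decision confidence.  Under a **world-updating** account,
feedback is treated as evidence about the state of the world: combined with
the choice it reveals on which side of the class boundary the stimulus
truly fell, and the decision-maker updates a belief about that boundary.

The two accounts agree after weak sensory evidence (a *correct* "large"
choice biases the next choice toward "large" either way) but disagree after
strong evidence: value updating predicts the bias merely shrinks with
evidence strength, while boundary updating predicts it **reverses**,
because the remembered stimulus drags the boundary past the feedback
effect.  This stimulus-dependent bias reversal is the discriminating
signature the package reproduces and tests.

## Task simulator

The simulated experiment is a ring-size classification: stimulus levels
$S \in \{-2,-1,0,1,2\}$ (one ring-size step per unit), randomized within
every block of 5 trials, 170 trials per run, 30 runs per session.  Feedback
is stochastic: each trial draws a virtual criterion
$b \sim N(\mu_{True}, \sigma_{True}^2)$ with $\sigma_{True} = 1.28$; the
true class is *large* iff $S > b$ and feedback is *correct* iff the choice
matches it.  $\mu_{True}$ is 0 early in a run and switches to one of
$\{-0.4, 0, 0.4\}$ (10 runs each, shuffled order) at a trial drawn
uniformly from 40–50 — the source documents the switch window but not the
draw rule, so the uniform draw is this package's choice, configurable in
`make_run_schedule()`.

Two consequences of this design are worth keeping in mind when reading
tests.  First, blocked randomization makes successive stimuli
*anticorrelated*: $P(S_{t+1}{=}s \mid S_t{=}s) = 1/25$, not $1/5$, because a
level cannot repeat within a block.  Conditioned stimulus distributions and
episode-pair maps inherit this structure even for a memoryless observer;
the test suite asserts the blocked-design law rather than naive uniformity.
Second, nonveridical feedback at $|S| = 2$ is rare
($1-\Phi(2/1.28) \approx 0.06$ of those trials), so the corresponding
episode cells need long simulations before PSEs become estimable; cells
below a configurable trial minimum (default 50) are reported missing, never
imputed.

Agents are re-initialized at each run start (boundary belief to its
baseline prior, option values to $V_{init}$), mirroring the per-run
reference display of the experiment; both resets are package conventions
(the source is silent on them) and are symmetric across models.
Invalid/no-response trials are not simulated; trial tables carry a `valid`
flag for ingesting real data.

## The value-updating agent

Given a sensory measurement $m \sim N(S, \sigma_m^2)$, the belief state is
$p_L = \Phi((m - \mu_0)/\sigma_m)$.  Expected values are
$Q_L = p_L V_L$ and $Q_S = (1-p_L) V_S$; the choice is softmax,
$P(\text{large}) = 1/(1 + e^{-\beta(Q_L - Q_S)})$.  After feedback
($r = 1$ correct, $0$ incorrect — never $-1$) the chosen value updates by

$$\delta = r - p_C V_C, \qquad V_C \leftarrow V_C + \alpha\,\delta,$$

leaving the unchosen value untouched, with no temporal discounting and no
clipping (fitting bounds constrain the parameters instead).  Because
$p_C \le 1$, the sign of $\delta$ under *correct* feedback never reverses
while $Q_C < 1$: confidence modulates the *amount*, not the *direction*, of
reinforcement — the root of this model's inability to reverse feedback
biases.  Parameters: $\theta = \{\mu_0, \sigma_m, \alpha, \beta,
V_{init}\}$.

## The boundary-updating agent (BMBU)

The agent's learned generative model is $S \sim N(B, \sigma_S^2)$,
$m \sim N(S, \sigma_m^2)$, $m' \sim N(m, \sigma_{m'}^2)$, with class state
$CL = \text{large iff } S > B$.  Decisions use only the $p$-computation
against the current boundary belief mean $\hat B$:
$p_L = \Phi((m - \hat B)/\sigma_m)$, choosing *large* iff $p_L > 0.5$
(an exact tie — a measure-zero event — is broken by a fair coin).
Here $p(S \mid m)$ is taken as $N(m, \sigma_m^2)$, matching the belief-state
definition shared with the RL agent; folding the believed stimulus prior
into it is a defensible alternative the source leaves open.

After the episode, the class state is deduced from choice and feedback
(*large* iff the pair is (large, correct) or (small, incorrect)), and the
boundary likelihood marginalizes the unknown stimulus:

$$p(m', CL{=}\text{small} \mid b) =
  \Phi\!\left(\frac{b - w(b)}{\sqrt v}\right) N(m';\, b,\, \sigma_M^2 +
  \sigma_S^2),$$

with $\sigma_M^2 = \sigma_{m'}^2 + \sigma_m^2$,
$w(b) = (b\,\sigma_M^2 + m'\sigma_S^2)/(\sigma_M^2 + \sigma_S^2)$ and
$v = \sigma_M^2 \sigma_S^2 / (\sigma_M^2 + \sigma_S^2)$; the *large* state
carries the complementary CDF.  The two branches sum to the Gaussian
predictive $N(m'; b, \sigma_M^2 + \sigma_S^2)$ — an identity the tests
check to $10^{-10}$, alongside brute-force double quadrature of the
generative chain.

The posterior combines this likelihood with the Gaussian prior on a grid
and is summarized by its grid mean and variance — exactly the two moments
the next-trial prior consumes:

$$\hat B_t = \lambda \hat B^{post}_{t-1} + (1-\lambda)\mu_0, \qquad
  \sigma^2_{B_t} = \lambda \sigma^{2,post}_{t-1} + \sigma^2_{diffusion},
  \qquad \lambda = \frac{\sigma_0^2}{\sigma_0^2 + \sigma^{2,post}_{t-1}}.$$

The non-Gaussian posterior shape (a Gaussian times a Gaussian CDF, the
extended-skew-normal family) is not otherwise retained; closed-form
skew-normal moment algebra is used only inside test oracles, never as the
production path.  Parameters: $\theta = \{\mu_0, \sigma_m, \sigma_S,
\sigma_0, \sigma_{m'}, \sigma_{diffusion}\}$.

### Numerical choices

`posterior_update()` integrates on a grid spanning the union of the prior
mean $\pm 8$ prior SD and $m' \pm 8\sqrt{\sigma_S^2 + \sigma_M^2}$, with at
least 2001 points and trapezoidal normalization; if the normalizer
underflows the grid is widened once to $\pm 16$ SD before erroring.  Grid
moments match a $10^5$-point refinement to better than $10^{-4}$.  A prior
far narrower than the grid spacing cannot be resolved on the union grid
(its mass falls between points); the compiled path treats an exactly
degenerate prior ($\sigma^2 = 0$) as a fixed boundary.

The compiled simulation and fitting loop uses an algebraically equivalent
but tighter grid: the two Gaussian factors (prior and predictive) are
multiplied analytically and the grid covers their product $\pm 10$
posterior SDs, where the bounded CDF factor can only re-weight mass.  At
151 points this agrees with the reference construction to $10^{-13}$, and
at the 31-point fitting resolution to $10^{-8}$; an equivalence test pins
the two paths together.

## Reference models

The **Base** model fixes the boundary at 0 ($\theta = \{\sigma_m\}$); the
**Fixed** model at a free constant $\mu_0$ ($\theta = \{\mu_0,
\sigma_m\}$); both use the argmax readout on $p_L$, so their stochasticity
comes from the measurement alone, matching their 1- and 2-parameter counts.
The **Hybrid** model (9 parameters) decides by softmax over value-weighted
expected values computed against the BMBU boundary and, after feedback,
applies both the value update and the boundary update from the same
$(m, m', CL)$ — the two updates are independent given the episode, so their
relative order is immaterial.  Nesting relations (Base $\subset$ Fixed;
both learning models reduce to Fixed in their no-learning limits) are
verified by distribution-matching simulations.

## History-effect analysis

For any episode (stimulus, choice, feedback) the trials at $toi-1$
(retrospective) and $toi+1$ (prospective) are stacked — respecting run
boundaries — and a cumulative Gaussian
$\psi(x) = \gamma + (1-\gamma-\lambda)\Phi((x-\mu)/\sigma)$ is fitted to
the per-level *large*-choice counts by maximum likelihood (the default
2-parameter variant fixes $\gamma = \lambda = 0$; the 4-parameter variant
bounds both in $[0, 0.5]$, bounds the source delegates to its fitting
package without stating).  The PSE is $\mu$; **negative PSE = bias toward
large**.  The reported estimate is the mean over binomial bootstrap
resamples (default 5000) drawn at the *observed* per-level proportions —
chosen over fitted proportions for model-freeness — with the resample SD as
its SE; non-identifiable resamples are dropped and the cell is flagged if
more than 20% drop.

## Fitting by inverse binomial sampling

The choice likelihood of the sequential agents is intractable, so the
log likelihood is estimated without bias by inverse binomial sampling:
for each trial, simulated choices are drawn until one matches the observed
choice, and $K$ draws contribute $-\sum_{j=1}^{K-1} 1/j$.  Latent states
are conditioned on the *observed* choices and feedback; the matching
draw's measurement feeds the mnemonic/update step, keeping the emission
consistent with the conditioning event (full-sequence resimulation is the
documented alternative, isolated behind one function).  Trials designated
as lapse trials (designated once per fit at the session-level lapse rate,
estimated as $(\gamma + \lambda)/2$ from the grand psychometric curve)
emit a fair coin, which also bounds the match probability away from zero;
a hard cap (default $10^4$ draws) floors pathological trials and counts
them.

The search is derivative-free and noise-aware.  Latin-hypercube starts
(default 20) are ranked under a cheap shared-seed objective; each optimized
start runs a pattern search whose coordinate steps shrink from 20% of each
parameter range and whose IBS repetition count grows as the steps shrink.
Three further design points matter in practice.  (i) All evaluations within
a fit reuse a fixed set of repetition seeds (common random numbers), so the
optimizer descends one consistent surface instead of chasing independent
noise — with single-repetition noise of $\approx 45$ log-units at 5,100
trials, a noise-blind simplex search fails badly.  (ii) Scale parameters
(the $\sigma$'s and $\beta$) are searched on a log scale; their likelihood
valleys are hopelessly ill-conditioned linearly, and the LHS starts are
correspondingly log-uniform over scales.  (iii) Two kinds of non-random
starts are added: a data-driven start taking $\mu_0$ and $\sigma_m$ from
the grand probit fit of the pooled psychometric curve, and — in model
comparison pipelines — embeddings of already-fitted nested submodels
(boundary updating switched off via a near-zero $\sigma_0$, value updating
via a near-zero $\alpha$ with a sharp softmax), so a supermodel never
scores below its submodels merely for want of searching.  The winning
candidate is re-evaluated with 100 fresh repetitions for the reported,
unbiased LL.  Default box bounds: SDs in $[0.01, 10]$ level units,
$\alpha \in [0,1]$, $\beta \in [0,50]$, $\mu_0 \in [-2,2]$,
$V_{init} \in [0,5]$.

One property of the sequential-conditioning likelihood deserves emphasis:
because the latent path is sampled one particle at a time (the accepted
draw's measurement drives the update), the estimated log likelihood is
biased downward by the per-trial latent entropy, and more so for models
with more latent variability.  Model comparison therefore slightly
handicaps the dynamics-rich models; at session scale the dynamics signal
dominates this handicap, but it is one reason the recovery analyses use
full-length sessions rather than very short ones, and estimator-preferred
parameters can legitimately differ from generating parameters in the
weakly identified dimensions.

Of the six BMBU parameters, $\mu_0$ and $\sigma_m$ are strongly identified
by the marginal psychometric curve; $\sigma_S$, $\sigma_{m'}$ and the
$\sigma_0/\sigma_{diffusion}$ pair trade off against one another in
choice data of this size, and their recovered values should not be
over-interpreted.  Recovered $\sigma_m$ carries a small positive bias
at desk scale: the likelihood punishes too-small $\sigma_m$ far more
harshly than too-large, so residual search scatter lands asymmetrically.

## Model comparison

Per agent, $AICc = -2LL + 2p + 2p(p+1)/(n-p-1)$ and the log model evidence
is $-AICc/2$.  Group-level inference uses the standard random-effects
variational Dirichlet scheme (uniform Dirichlet(1) prior; responsibilities
$\propto \exp(\text{evidence} + \psi(\alpha_k) - \psi(\Sigma\alpha))$;
concentration updates to $10^{-6}$ tolerance, max 500 iterations).
Exceedance probabilities are Monte-Carlo estimates from the Dirichlet
posterior (default $10^6$ samples); the Bayesian omnibus risk compares the
variational free energy of the alternative against the exact evidence of
the null of equal frequencies, and the protected exceedance probability is
$(1-BOR)\,XP + BOR/M$.  Model recovery simulates synthetic sessions per
generating model, fits every candidate, and reports the protected
exceedance probability of each candidate under each ground truth.  The
recovery model space is {Base, Hybrid, value-updating, world-updating} —
the two learning models plus the two reference models that bracket them in
complexity.

## Simulation defaults and problem sizes

The ex ante configuration follows the study conditions: a sensory-noise
grid of 25 levels on $[0.15, 3.27]$ (tests use 10), 30 runs × 170 trials,
no lapse trials, no choice bias.  The remaining parameters are package
defaults chosen once: $\alpha = 0.3$, $\beta = 8$, $V_{init} = 1$ for the
value agent and $\sigma_S = 1.5$, $\sigma_0 = 1.6$, $\sigma_{m'} = 0.5$,
$\sigma_{diffusion} = 0.5$ for BMBU.  They were selected so that (i)
simulated accuracy spans the human range (about 61–74% correct across the
grid) and (ii) the boundary dynamics sit in the regime the models were
built to express — a believed stimulus spread comparable to the true design
spread (the level SD is $\sqrt 2$), memory noise below sensory noise at
typical levels, and a baseline prior loose enough that single episodes
move the boundary measurably.  With much wider $\sigma_S$ or heavier
$\sigma_{m'}$ the mnemonic pull is diluted and the reversal shrinks toward
zero; the package exposes every one of these knobs.

For the headline signature the unit of replication is the simulation
repetition: each repetition simulates one session per grid point, pools its
trials across the grid (a pooled curve spans observer heterogeneity the way
the study's per-set averages do), and PSEs are summarized by mean ± SE
across repetitions.  Per-grid-point PSEs are also available
(`run_ex_ante()`), but at desk scale their across-grid SEM mixes strong
small-$\sigma_m$ effects with noisy near-zero large-$\sigma_m$ cells.

Desk-scale sizes used throughout the committed tests: 10 grid points × 10
repetitions for the signature; 40 session-replicates for the no-updating
null; 10 agents × 5,100 trials for parameter recovery; 4 ground truths × 5
agents × 1,530 trials for model recovery.  These sizes are the package's
choices for a single-workstation run and are configurable upward.

Model recovery deserves a caveat of its own: at desk scale the group
selection cleanly recovers the Base ground truth, but the nested and
mimicking pairs sit at the AICc-penalty scale per agent — the Hybrid's
boundary dimensions genuinely absorb part of the value model's residual
choice autocorrelation, and a boundary-updating agent with heavy sensory
noise is nearly indistinguishable from a static observer in a single
session.  Separating all four models with protected exceedance above 0.9
requires population-scale evidence (tens of agents, full-length sessions),
which is exactly how the original full-scale analysis was run.

## What passing tests do and do not show

The generator emulates the published design faithfully (blocked stimuli,
stochastic criterion, run structure) but all results here are on synthetic
agents: passing tests demonstrate internal correctness (the algebra, the
estimators, the machinery) and the qualitative model contrast under the
package's calibrated defaults — not that any particular human dataset is
fit well, and not the study's human-data statistics, which require the
original recordings.  Real data bring features the generator omits:
response deadlines and invalid trials, session-level nonstationarity,
finger-mapping artifacts, and lapse behavior that need not be a fair coin.
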