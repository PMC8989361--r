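---
title: "Optimal trigger points for ex situ, in toto conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal trigger points for ex situ, in toto conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triggerpoint)
```

## The decision problem

A single-population threatened species (SPTS) — a species whose entire
global population is one local population — is observed to decline year
after year.  Its managers run in situ conservation actions whose annual
probability of success, $q$, is unknown and may be zero.  At any point they
may instead take the entire remaining population into captivity: an
*ex situ, in toto* capture that makes the species extinct in the wild,
succeeds only with probability $p_x$, and cannot be undone.  Waiting buys
more chances for in situ success and more information, but loses abundance;
acting early forfeits both.  `triggerpoint` formulates this as a Bayesian
optimal-stopping problem on a finite-horizon Markov chain and solves it by
stochastic dynamic programming (SDP), so that the trigger condition is
computed in advance rather than improvised under pressure.

## Model components

### Decline regression and the rate distribution

The observed abundances $N_t$ are fit by ordinary least squares against
time (`fit_decline()`).  The slope estimate $\hat r$ (individuals/year)
carries its OLS standard error, and the sampling distribution of the slope
— Normal by default, Student-$t$ with $n-2$ degrees of freedom as an option
— is the decline-rate distribution $p(r)$ used everywhere downstream.
Variation around the trend is attributed to environmental and demographic
stochasticity rather than measurement error, so the reference abundance
$N(t_0)$ is the raw last observation (option `reference = "fitted"`
substitutes the regression prediction at the last year, useful when single
surveys are erratic).

For the integrals over $p(r)$ the package uses a deterministic
equal-probability quantile rule: `n_rate_nodes` (default 201) rate values
at the mid-quantiles $(k - \tfrac12)/n$ of the slope distribution, each
with weight $1/n$.  This reproduces the mean of any symmetric slope
distribution to machine precision, converges at the usual quantile-rule
rate for the nonlinear utility integrals, and — unlike Monte-Carlo draws —
makes every downstream number reproducible without seed bookkeeping.

### Extinction forecast and the horizon

Each discretized rate $r < 0$ crosses zero abundance at the first whole
year $t_E(r) = \lceil N(t_0)/|r| \rceil$; aggregating node weights by
$t_E$ gives the extinction-year distribution (`extinction_forecast()`).
Rates $r \ge 0$ never cross and contribute to the residual mass.  The
decision horizon $\tau$ is the smallest year whose cumulative extinction
mass reaches `horizon_percentile` (default the 99th percentile), beyond
which extinction is treated as certain — the dynamic program needs a finite
horizon.  When the percentile is unreachable because too much slope mass is
non-negative, $\tau$ falls back to a cap, by default
$\max(5 \times \text{observed span}, 100)$ years, with a loud warning.
Positive-slope mass is deliberately kept rather than truncated: it
represents genuine uncertainty about whether the decline is real, adds
growth-side contributions to the expected-abundance and value integrals,
and simply never contributes an extinction year.

### Belief about in situ success

The population's response to each year of in situ management is a
Bernoulli trial with unknown constant success probability $q$.  From a
uniform prior, $n_u$ consecutive failures give the conjugate posterior
$\mathrm{Beta}(1, n_u + 1)$ (`success_posterior()`) with mean

$$E[q \mid n_u] = \frac{1}{n_u + 2},$$

which decreases from $1/2$ towards 0: failures breed pessimism.  An
alternative printed form of this expectation, $1 - 1/(n_u+2)$, *increases*
with failures; it contradicts the posterior it is derived from and the
qualitative behaviour the model requires, so the package treats it as a
transcription slip and defaults to the conjugate mean, keeping the other
form available as `belief_variant = "as_printed"` for literal reproduction
exercises.

### State space and transitions

A state is $\{n_u, a_e, a_s\}$: failures so far, whether the capture was
taken, whether in situ succeeded.  Both success indicators freeze the
chain (absorbing states), so elapsed time equals $n_u + a_e + a_s$.
States are indexed $i = a_s + 2a_e + 4n_u + 1$, giving $R = 4(\tau+1)$
states.  Two row-stochastic $R \times R$ matrices drive the dynamics
(`in_situ_matrix()`, `ex_situ_matrix()`): under in situ action a live
state $\{n_u,0,0\}$ moves to $\{n_u,0,1\}$ with probability
$E[q \mid n_u]$ and to $\{n_u+1,0,0\}$ otherwise; under the capture it
moves to $\{n_u,1,0\}$ with probability $p_x$ and, on failure, to the last
state $S_R = \{\tau,1,1\}$, which doubles as the complete-extinction sink
(it is unreachable by any other route, so no dynamics are distorted).
The live end-of-horizon state $\{\tau,0,0\}$ self-loops.

### Valuation

At the horizon the fate of the species is known and each state is scored
in $[0,1]$ (`terminal_values()`):

$$V(S_i, \tau) = w_2^{a_e} \, E_r\!\left[1 -
  e^{-w_1 \max(0,\, N(t_0) + r(n_u + a_e + a_s))}\right].$$

$w_1$ (1/individuals) sets the diminishing marginal benefit of abundance;
its default calibration $w_1 = \ln(20)/N_{\text{pre}}$ makes managers 95%
satisfied at the pre-decline abundance $N_{\text{pre}}$ (the first observed
abundance in a replay).  $w_2 \in (0,1]$ (default $2/3$) discounts
persistence in captivity relative to the wild.  The extinction sink is
worth exactly 0.

The $\max(0,\cdot)$ floor inside the expectation is a deliberate numerical
choice: without it, rate nodes whose linear extrapolation has crossed zero
contribute utilities that diverge to $-\infty$ with how far past zero the
line happens to run — a bookkeeping artifact with no biological content.
Flooring anchors every extinct trajectory at value 0, the same anchor as
the extinction sink.  `clamp = "raw"` preserves the unfloored expression
for comparison.

### The Bellman recursion

`solve_sdp()` iterates

$$V(S_i, t) = \max_a \sum_j T^{(a)}_{ij} V(S_j, t+1)$$

backwards from $t = \tau - 1$ to 0, recording the optimal action at every
live state and stage.  Action values closer than $10^{-12}$ are treated as
tied and resolved in favour of the in situ action: delay preserves the
option value of an irreversible step, and the deterministic tie-break makes
output reproducible.  `brute_force_value()` provides an independent check:
it enumerates every deterministic action assignment over the (state, stage)
pairs reachable from $\{0,0,0\}$ — along the live diagonal the only live
state reachable at stage $t$ is $\{t,0,0\}$, so $2^\tau$ assignments
exhaust all distinct policies — and evaluates each by explicit
probability-tree expansion, no Bellman step involved.

## The receding-horizon replay

`replay()` simulates a manager who starts in situ actions in the first
observed year and each year re-fits the decline on the data so far,
rebuilds the forecast and the decision model, re-solves the SDP, and reads
the optimal action for the current state.  Decisions begin at the third
observation (`fit_window`), the smallest window OLS supports.  Each
pre-trigger year counts as one in situ failure — the replay never declares
an in situ success on its own, because detecting success from a short
noisy series is exactly the kind of judgement the surrounding model does
not formalise — so at the $j$-th observation the current state is
$\{j-1, 0, 0\}$, queried at stage $j-1$.  The replay stops at the first
`ex_situ` recommendation (the trigger year), at observed extinction, or at
the end of the series.

One corner needs care: late in a long decline the yearly forecast horizon
$\tau$ (measured from the current abundance) can shrink to or below the
elapsed failure count $n_u$, so the current state would fall off the state
space.  The decision model for such a year is built with horizon
$\max(\tau, n_u + 1)$, the smallest horizon in which the current state
exists; the extra states lie on trajectories the forecast already considers
effectively extinct and carry correspondingly small values.

`sensitivity_sweep()` repeats the whole replay over a grid of one value
parameter.  On the packaged steady-decline fixture the trigger year is
non-increasing in $p_x$ (a safer capture is taken sooner), non-increasing
in $w_2$ (less reluctance about captivity), and non-decreasing in $w_1$
(value that saturates more slowly erodes more slowly, affording patience);
the test suite asserts all three directions.

## Synthetic scenarios

`generate_series()` draws
$N_t = \max(0,\; \text{trend}(t) + \varepsilon_t)$,
$\varepsilon_t \sim \mathcal N(0, \sigma)$, with a piecewise-linear trend
whose slope flips sign at an optional recovery year — additive Gaussian
noise to match the model's error assumption, floored so abundances stay
valid.  The four built-in fixtures span the regimes real SPTS declines
exhibit: a long consistent decline (`steady`), a short consistent decline
that reaches zero (`steady_to_zero`), a noisy decline with a sustained
recovery (`noisy_upturn`), and a shallow noisy decline (`noisy_shallow`).
Their parameters (initial abundances 120–600, slopes −6 to −22
individuals/year, noise 4–20 individuals, 16–25 years) were chosen once to
resemble published vertebrate declines of those shapes.

A property worth noting, because it is the opposite of a common intuition:
wider slope uncertainty *accelerates* the trigger.  Pessimistic rate nodes
dominate the value lost by waiting, while the belief in in situ success
decays at the same rate regardless; on the fixtures the noisy decline
triggers after fewer failed years than the steady one, and a recovery
upturn, once visible in the data, flattens the fitted slope and postpones
or cancels the trigger (the paired-series test asserts exactly this).

What the synthetic fixtures do not emulate: observation error distinct
from process noise, non-linear (e.g. exponential or density-dependent)
declines, demographic structure, and autocorrelated environmental shocks.
Tests passing on these fixtures show the machinery is correct under the
model's own assumptions, not that the linear-Gaussian description fits any
particular real species.

## Numerical choices and problem sizes

- Quantile discretization of $p(r)$: 201 nodes by default; the tests
  verify 101 nodes already reproduce the slope mean to $10^{-6}$.
- Action comparisons: absolute tolerance $10^{-12}$, ties to in situ.
- Horizon cap $\max(5 \times \text{span}, 100)$ years, warned loudly.
- The test suite works at $\tau \le 30$ for structural checks, $\tau \le 3$
  against the enumeration oracle (50 random instances), 100 simulated
  series for slope-CI coverage, and 200 for forecast-band coverage and
  slope unbiasedness; the whole suite runs in well under a minute.

## Limitations

The Markov assumption requires that in situ success, if it occurs, is
recognised within a year; management actions with long lags (habitat
restoration) or successes only provable by multi-year increases break it.
$p_x$ is treated as known and fixed — there is no opportunity to learn
about a one-shot action — and should come from expert elicitation or a
dedicated captive-breeding model.  The linear decline is a first-order
description; the framework accepts any forecast that can be reduced to a
rate distribution, and a state-space or species-specific population model
would slot in at that interface.  Trigger outputs for real species are
decision support, not retrospective judgements of what managers should
have done.
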