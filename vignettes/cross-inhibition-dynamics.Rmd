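---
title: "Cross-inhibition consensus dynamics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-inhibition consensus dynamics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossinhib)
```

## The model

`crossinhib` studies how a population of agents settles on one of two
options, X or Y, when a third state Z holds the uncommitted. The
behavioural repertoire mirrors honeybee nest-site selection: committed
agents *recruit* uncommitted ones to their option (the waggle-dance
analogue, transitions Z→X and Z→Y), and committed agents of one camp push
committed agents of the other camp back to indecision (the stop-signal or
*cross-inhibition* analogue, transitions X→Z and Y→Z). Direct X↔Y
conversions never happen: an agent must pass through indecision to change
camp.

The package implements this at two coupled levels.

**Agent level.** Agents sit on a connected undirected graph and carry an
opinion $w^i_t \in \{X, Y, Z\}$. Each step, an agent samples small sets of
neighbours: an X-agent switches to Z with probability $p_1$ only if all
$|M|$ sampled neighbours are Y (symmetrically for Y with $p_2$); a Z-agent
adopts X with probability $p_3$ if all $|D|$ sampled neighbours are X, or
Y with probability $p_4$ if they are all Y. Five mechanisms ("cases")
differ in the sample-set sizes and in whether probabilities are scaled by
the local committed fraction:

| case | $|M|$ | $|D|$ | scaling | behavioural reading |
|------|-------|-------|---------|---------------------|
| 1 | 1 | 1 | none | broad-minded agents, linear signals |
| 2 | m | 1 | none | stubborn committed agents |
| 3 | 1 | d | none | stubborn uncommitted agents |
| 4 | 1 | 1 | $p_{1,2} / (\tilde x + \tilde y)$ | inhibition driven by the committed share |
| 5 | 1 | 1 | $p_{3,4} / (\tilde x + \tilde y)$ | recruitment driven by the committed share |

**Population level.** Writing $x, y, z$ for the population shares (with
$x + y + z = 1$), the mean-field dynamics is the discrete-time map

$$x_{t+1} = x_t - a_{12} f_2 \, x_t y_t + a_{11} f_1 \, x_t z_t,
\qquad
y_{t+1} = y_t - a_{21} f_3 \, x_t y_t + a_{22} f_4 \, y_t z_t,$$

where the four nonnegative constants $a_{11}, a_{12}, a_{21}, a_{22}$ are
the rewards of an underlying three-action evolutionary game and the
response functions $f_1, \dots, f_4$ encode the case (powers $y^{m-1}$,
$x^{m-1}$, $x^{d-1}$, $y^{d-1}$ for the group-size mechanisms, $1/(x+y)$
for the share-driven ones). The map arises from the *expected-gain
pairwise comparison* protocol: the probability of switching from action
$j$ to $i$ is $\sum_k \max(a_{ik} - a_{jk}, 0)\, x_k$ applied to the
game's payoff matrix, and `transition_rates()` is tested to coincide with
`expected_gain()` applied to `payoff_matrix()` to $10^{-12}$.

The bridge between the levels is the constant identification
$p_1 = a_{12}$, $p_2 = a_{21}$, $p_3 = a_{11}$, $p_4 = a_{22}$: in a
well-mixed population the chance that a single sampled neighbour is, say,
Y is the share $y$, so the agent-level rate $p_1 y$ matches the
macroscopic term $a_{12} y$ (and the all-of-$m$ condition yields $y^m$).
The identification is a modelling choice of this package; it is validated
empirically by the one-step drift test on a complete graph and by the
trajectory-level comparison on dense random graphs.

## Parameters that matter

* `a11, a12, a21, a22` — dimensionless rewards, each bounding a per-step
  probability. Values in $[0, 1]$ keep every rate a probability without
  intervention; larger values are allowed (with a warning) and trigger
  clipping. Defaults across the experiment runners use the study sets
  $(0.2, 0.2, 0.2, 0.2)$, $(0.9, 0.2, 0.2, 0.2)$, $(0.9, 0.4, 0.4, 0.9)$
  and $(0.1, 0.5, 0.3, 0.6)$, exposed as `study_payoffs()`.
* `m`, `d` — group sizes (agents that must unanimously agree before a
  switch), integers ≥ 1. The group-size studies use `m = 3`.
* Graph parameters — Erdős–Rényi `N = 1000`, `p = 0.2` for the well-mixed
  comparisons (expected degree ≈ 200, effectively well mixed);
  Watts–Strogatz `N = 100`, `K = m + j`, `rewire_p = 0.1` for the
  structured-network studies. Both generators rejection-sample whole
  graphs until connected with minimum degree ≥ `max(|M|, |D|)`.
* `T` — horizon; 200 steps for the standard runs, which is ample for the
  dynamics to settle at the study's reward magnitudes.

## Numerical choices

* **Clipping.** Raw rates are clipped to $[0, 1]$; if the two exit
  probabilities from Z together exceed 1 they are rescaled by their sum so
  the single-agent transition matrix stays row-stochastic. For all study
  reward sets no clipping ever triggers; the policy only matters for
  user-supplied rewards above 1, and every clip is recorded on the
  returned object.
* **The $1/(x+y)$ singularity.** At the uncommitted vertex the share-driven
  response functions are undefined; the package sets them to 0 there
  (below $x + y = 10^{-12}$). There are no committed peers to observe, and
  every affected rate carries an extra factor of $x$ or $y$ that vanishes
  faster, so this is the continuous completion of the map on the simplex.
* **Positive part.** The gain operator uses the strict ramp
  $u \mapsto u\,\mathbf 1(u > 0)$; a zero payoff difference contributes
  nothing.
* **Equilibrium search.** The three simplex vertices are fixed points by
  construction. Interior candidates solve the balance system with the
  common factors $x$ and $y$ divided out
  ($a_{12} f_2 y = a_{11} f_1 z$, $a_{21} f_3 x = a_{22} f_4 z$) — the
  undivided fixed-point residual is numerically flat near the vertices of
  the group-size mechanisms (flows of order $x^d$), and dividing removes
  that degeneracy. A damped Newton iteration runs from a 7×7 interior
  grid plus the barycentre; converged roots are deduplicated (tolerance
  $10^{-7}$), must pass both the balance residual ($10^{-10}$) and the
  fixed-point residual ($10^{-10}$), and vertices are excluded. For the
  linear-response case the closed form
  $x : y : z = a_{22}/a_{21} : a_{11}/a_{12} : 1$ (hence
  $q = y/x = a_{11} a_{21} / (a_{12} a_{22})$) is used directly and agrees
  with the numeric route.
* **Jacobians and stability.** Stability uses the discrete-time criterion
  (eigenvalue moduli vs 1, with a `marginal` band of width `tolerance`,
  default $10^{-8}$). The numeric Jacobian central-differences the *raw*
  (unclipped) map, which extends smoothly past the simplex boundary, so
  vertices need no one-sided stencils; only the share-driven cases fall
  back to one-sided differences near their singularity, with a warning.
  For the linear-response case an exact analytic Jacobian is available
  and tested against the numeric one.
* **Reproducibility.** Every stochastic entry point takes a seed;
  experiment runners derive child seeds deterministically per replicate
  (a fixed integer hash, kept below $2^{31}$), so any single cell of a
  sweep can be reproduced in isolation.

## What the generators emulate — and what they do not

All inputs are synthetic by design: random graphs, uniform initial
opinions and (for the agreement study) i.i.d. rewards drawn from
Uniform(0.05, 0.95) — bounded away from 0 so the composite ratio
$a_{11} a_{21} / (a_{22} a_{12})$ stays finite; the distribution is a
package default, configurable via `reward_sampler`. These emulate the
study conditions of the original setting: anonymous well-mixed or
ring-structured populations with homogeneous behavioural parameters.
They do **not** emulate features of real decision-making collectives such
as heterogeneous susceptibility, correlated or clustered opinion
initialisation, time-varying interaction networks, or adversarial agents.
Passing tests therefore demonstrate internal consistency between the two
model levels and the analytic theory — not predictive validity for any
empirical population.

## Design choices on genuinely open points

* **Case labelling.** The published table of sample-set cardinalities
  lists the share-driven scaling twice under one label; consistent with
  the response-function theorem, the row scaling recruitment is treated
  as the fifth mechanism.
* **Group sizes.** The group-size mechanism for uncommitted agents is
  parameterised by `d`, defaulting to `m`, since the prose uses a single
  group size while the table distinguishes the two sides; both are
  settable independently.
* **Synchronous updates.** All agents update against the time-$t$
  snapshot, matching the per-step population bookkeeping of the
  mean-field map; a random-sequential mode is available behind
  `update = "asynchronous"` but is not the default.
* **Local shares.** The committed fractions $\tilde x, \tilde y$ driving
  cases 4–5 at the agent level are computed over the focal agent's full
  neighbourhood, excluding the agent itself.
* **Agreement metric.** "Both processes reached the same decision" means
  both final states give the same opinion at least a 0.5 share
  (`final_decision()`, threshold configurable); runs where either process
  remains mixed count as disagreement.
* **Experiment scales.** The runners default to the study protocol
  (ER $N = 1000$, $T = 200$, 100 replications); `scale = "test"` switches
  to desk-scale settings ($N \le 200$, $T \le 100$, 20 replications,
  reduced grids) used by the test suite. The package's own test runs use
  those reduced sizes; they are stated here as the package's choice of
  test-scale protocol.
* **Sweep anchoring.** The ratio sweep fixes the recruitment rewards at
  `base_a11 = base_a22 = 0.5` (configurable) and sweeps
  $a_{12}/a_{11}$ and $a_{21}/a_{22}$ over $[0.1, 2]$, since only the
  ratios are identified by the original design.

## A worked pass through the API

```{r, eval = FALSE}
params <- payoff_params(0.9, 0.2, 0.2, 0.2) # recruitment to X dominates
case1 <- case_spec(1)

# population level
eq <- equilibrium_analysis(params, case1)
tidy(eq)

# agent level on a dense random graph, compared with the mean field
cmp <- compare_processes(params, case1,
                         graph_spec = list(type = "er", N = 1000, p = 0.2),
                         T_steps = 200, seed = 1)
glance(cmp)
autoplot(cmp)
```

## Known limitations

* The rate plumbing is specific to the three-action structure (two
  committed states plus one uncommitted); `expected_gain()` itself is
  generic $n \times n$.
* Continua of boundary fixed points arising from zero rewards are not
  enumerated; the search reports isolated roots only.
* Stability near the `marginal` band is not resolved: nonlinear
  (centre-manifold) behaviour, as at the uncommitted vertex of the
  stubborn-uncommitted mechanism where the linearisation is the identity,
  is left unclassified by design.
* No continuous-time limit, directed or weighted graphs, or agent
  heterogeneity.
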