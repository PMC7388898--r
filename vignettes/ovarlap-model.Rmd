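---
title: "The OVaRLAP model: opponent-channel value learning with fast generalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The OVaRLAP model: opponent-channel value learning with fast generalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovarlap)
```

## The model and its assumptions

OVaRLAP is a value-learning architecture motivated by the division of labour
in the striatum: D1-expressing projection neurons respond to phasic dopamine
increases (positive reward-prediction errors) and D2-expressing neurons to
phasic decreases (negative errors), and plasticity is confined to the
corticostriatal synapses — the *last* layer of the network. The package
implements that architecture literally:

- **Fixed encoding.** The agent's grid position is encoded one-hot over the
  `width x height` input layer and projected through *fixed* connections onto
  `n_hidden` Gaussian receptive fields. Nothing upstream of the read-out is
  ever learned; this is the extreme-learning-machine regime, except that the
  fixed weights are not random — they are laid out to preserve input
  similarity, because generalization must follow spatial proximity.
- **Opponent read-out.** Two nonnegative weight vectors `w1`, `w2` read the
  hidden layer; `v = d1 - d2`. Positive TD errors potentiate `w1` only,
  negative errors potentiate `w2` only. Both channels are monotonically
  non-decreasing; all forgetting is implemented as opposition, never as decay.
- **Afterstate SARSA.** `Q(s, a) = v(x', y')` at the square the action points
  at, including impassable squares, and learning is on-policy. SARSA rather
  than state-value TD is forced by the task semantics: after an ineffective
  action the agent stays put, and bootstrapping on the *selected* next action
  keeps those transitions well-defined.
- **Exact-increment updates.** The raw update `w_m += alpha_m |delta| h`
  would move the afterstate's value by an amount depending on `sum(h^2)`,
  i.e. on the basis realization. The normalization `h / sum(h^2)` removes
  that dependence: the updated square moves by exactly `alpha_m * delta`,
  and only the *spread* to neighbours depends on the basis. The printed form
  of the normalization term is typographically ambiguous in its source, but
  its stated purpose (the exact increment) admits a unique linear rule, which
  is what the package implements; the literal alternative reading would also
  divide by a channel activity that is zero at initialization.

Two comparison agents share every protocol. Tabular SARSA is the
no-generalization control: one table cell changes per update. The MaxPain
variant keeps separate reward and pain tables updated from split rewards
(`phi(r)`, `phi(-r)`); its pain channel bootstraps off-policy on the
`argmin` of the combined value `Q_L = Q_r - Q_p` over the four next actions
— it learns to predict the worst case — while its reward channel stays
on-policy. Decisions and displayed value maps use `v_L = v_r - v_p`
unnormalized.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `theta` | generalization amount (log-variance spread of the receptive fields) | 1 | protocol sweep {0.44, 0.66, 1.0, 1.5, 2.2} |
| `n_hidden` | hidden units | 900 | centres tile the 400 positions linearly |
| `alpha1`, `alpha2` | learning rates for positive / negative TD errors | 0.1, 0.1 | `alpha2 = 0` is the "impaired" agent |
| `gamma` | discount | 0.95 (painful task), 0.8 (disturbed task) | |
| `tau` | softmax temperature | 0.5 | common to all three agents |
| `A`, `rho` | frozen connection-noise strength and density | 0, 0 | disturbed protocol: grids {0.25..4} x {0.00125..0.02}; the dissociation checks use A = 1, rho = 0.005 |
| `alpha_r`, `alpha_p`, `gamma_r`, `gamma_p` | MaxPain rates and discounts | 0.1, 0.1, 0.95, 0.5 | |
| `wall_penalty` | reward of an ineffective action | -1 (painful), 0 (painless) | |

The variance law is read as `sigma_k^2 ~ LogN(location = -0.7/theta,
scale = 0.7*theta)` with the second argument the *standard deviation* of the
log — the usual convention — so the sampled medians sit at
`exp(-0.7/theta)`. `sample_variances()` is a thin, replaceable wrapper if
the variance-of-log reading is ever wanted.

## The grid worlds

Tasks are 20 x 20 boards whose border ring is always impassable. The
reference layouts of the published tasks exist only as figures, so the
package ships documented approximations (`maze_fixture()`), plus a
rule-based generator:

- **Painful fixture**: a 3-wide corridor of length 17 with the start at the
  west end and the reward-1 goal at the east end, and a 1-wide branch of
  length 5 ending in the reward-2 goal. The branch length is a deliberate
  choice: the published account of the painful task has the value hazard at
  the branch entrance dissolving by episode 500 as reward learning
  propagates along the narrow passage, which requires the high-reward goal
  to be discovered reasonably often under the tau = 0.5 softmax. In our
  exploration a 1-wide dead end deeper than about 6 squares is essentially
  never entered to its end by any of the three agents, so a depth of 5
  preserves the intended risk/reward trade-off while keeping the goal
  discoverable. `generate_painful_maze()` keeps the more conservative
  defaults (passage length >= 8, configurable) for generating families of
  layouts.
- **Painless fixture**: an open arena with four reward-1 goals near the
  corners and the start at the centre, for the disturbed protocol.

Off-grid moves are not a separate case: the impassable border gives every
intended target a representable position, which the afterstate convention
requires. Goals are absorbing; episodes end on entry, so goal squares are
never departure states.

What the generator and fixtures emulate is the *structure* of the published
tasks — safe versus risky goals, passages, painful walls — not their exact
layouts. Quantities that depend on corridor lengths and branch depths
(steps-to-goal scales, which agent's late reward rate is highest) are
layout-sensitive; the qualitative contrasts (generalization gradients, early
safety, relearning speed, the aberrant-valuation dissociation) are not, and
those are what the test suite asserts. One published ordering did not
survive any layout we tried: with the printed metaparameters the MaxPain
agent, rather than having the lowest late reward per step, consistently has
the highest, because it reaches the high-reward goal before its pain table
builds a barrier and then collects rewards with the fewest wall hits. The
corresponding check in `test-acceptance.R` is left failing rather than
weakened; the other clauses of that protocol (early-phase orderings, the
late reward-rate advantage of plain SARSA over OVaRLAP, MaxPain's minimal
wall hits) all hold.

## Numerical and procedural choices

- **Terminal bootstrap.** Transitions that deliver positive reward end the
  episode; `gamma * Q(s', a')` is taken as zero (standard episodic SARSA).
- **Update timing.** One update per environment step, applied to the
  executed action's afterstate after the successor action has been drawn;
  the successor action is reused as the next executed action.
- **`delta = 0`** triggers no update in either channel.
- **argmin tie-breaks** in the MaxPain pain bootstrap are uniform random
  among minimizers (ties are ubiquitous over zero-initialized tables; a
  fixed-index rule would bias early exploration geometry). The draw comes
  from the same R RNG stream as everything else.
- **Step budgets.** Painful-task episodes are capped at 100,000 steps as a
  guard against non-terminating configurations (never hit in practice);
  the disturbed task is budgeted by *total* steps (40,000 in the full
  protocol) with the final episode truncated mid-flight, which is why
  completed-episode counts are fractional on average.
- **Smoothing and aggregation.** Learning curves use a trailing 11-episode
  window (current episode plus ten preceding, truncated at the head);
  cross-run spread is the population SD. Both are conventions for
  descriptive bands and are parameters of `moving_stats()` /
  `aggregate_runs()`.
- **Value-map maxima** are scanned over all 400 squares (walls included),
  ties broken toward smallest x then y; distance to the nearest goal is
  Manhattan.
- **Floating point.** The exact-increment property holds to ~1e-12 in
  double precision (asserted at 1e-9). Gaussian tails underflow to exact
  zero for the sharpest receptive fields at large distances; downstream code
  only ever needs `sum(h^2) > 0`, which the centre tiling guarantees.
- **Determinism.** All randomness — basis widths, frozen noise, softmax
  draws, tie-breaks, maze generation — flows from R's RNG; the simulation
  core (C++) uses `unif_rand()`, so `set.seed()` gives bit-identical runs.
  Experiment runners derive named sub-seeds per run and stream
  (`derive_seed()`) so that, e.g., changing the noise setting does not
  perturb the width draws.

## Problem sizes used by the shipped checks

The full protocols (50 runs of 500 episodes; 50 runs of 40,000 steps per
disturbance setting; the 5 x 5 noise grid) are available through the
experiment runners, but the shipped test suite exercises reduced versions
chosen to make the qualitative contrasts stable: 10 runs for the painful,
theta-sweep and relearning checks, the full 50 runs and 40,000 steps for the
two disturbance settings that carry the dissociation, and 20 basis seeds for
the generalization-gradient shape. The suite completes in a few minutes on
one CPU.

## Limitations

- The encoder is fixed by construction; learning it (or a recurrent
  reservoir variant) is out of scope.
- The channel-combination weights in `v = d1 - d2` are constants; tonic
  modulation of risk attitude is not modeled.
- Transitions are deterministic, actions are the four cardinal moves, and
  only 20 x 20 boards are exercised by the tests (sizes are configurable
  internally).
- Statistical comparison between agents (beyond descriptive means and SDs)
  is deliberately not provided.
- The fixture layouts approximate figure-only originals; conclusions that
  hinge on exact corridor geometry should be drawn from
  `generate_painful_maze()` families, not from a single fixture.
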