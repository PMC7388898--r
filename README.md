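# ovarlap

Opponent-channel reinforcement learning with fast stimulus generalization,
for computational neuroscientists studying how the striatal dopamine system
shapes adaptive (and maladaptive) behaviour.

## The model

**OVaRLAP** ("Outspread Valuation for Reward Learning and Punishment
Learning") is a SARSA-style temporal-difference learner whose state value is
read out of a *fixed* layer of Gaussian radial basis functions through two
opponent weight channels:

- the agent's position (x, y) on a 20 x 20 grid is encoded one-hot and
  projected through fixed connections
  `M[p,k] = (exp(-((x-a_k)^2 + (y-b_k)^2) / (2 sigma_k^2)) + eps[p,k]) / D`
  onto 900 hidden units (D = 400 input units); centres (a_k, b_k) tile the
  grid and the variances are log-normal,
  `sigma_k^2 ~ LogN(-0.7/theta, 0.7 theta)`, so receptive fields range from
  sharp to broad — the source of a graded generalization gradient;
- two channels read the hidden layer: `d1 = w1.h` (potentiated by positive
  TD errors, the D1-striatal analogue) and `d2 = w2.h` (potentiated by
  negative TD errors, the D2 analogue); the value is `v = d1 - d2`;
- action values are afterstates, `Q(s,a) = v(x', y')` at the square the
  action points at; the TD error is `delta = r + gamma Q(s',a') - Q(s,a)`
  (on-policy SARSA, softmax with temperature tau over the four candidate
  squares);
- updates are normalized, `w_m <- w_m + alpha_m |delta| h / sum(h^2)`
  applied to the channel matching the error's sign, which makes the
  increment exact: the afterstate's value moves by precisely
  `alpha_m * delta`, while overlapping basis responses spread the change to
  nearby squares (generalization) and the opposing channel later carves it
  back where predictions mismatch outcomes (discrimination).

Two comparison agents share the protocols: plain tabular SARSA (no
generalization) and a MaxPain variant with separate reward/pain tables whose
pain channel bootstraps off-policy on the worst-case next action. Grid-world
tasks: painful navigation (wall hits cost -1; a safe reward-1 goal vs a
reward-2 goal behind a narrow passage), relearning after walls turn
pain-free, and a painless four-goal world for the disturbed-agent protocol
(impaired negative-error learning and/or sparse frozen noise in the fixed
connections), where the diagnostic is whether the value map's maximum sits
on a goal.

## Worked example

```r
library(ovarlap)
set.seed(7)
world <- maze_fixture("painful")
basis <- build_basis(basis_spec(theta = 1))
agent <- ovarlap_agent(basis, alpha1 = 0.1, alpha2 = 0.1, gamma = 0.95)

# one positive update at the arena centre: a generalization gradient
agent1 <- ovarlap_update(agent, 10, 10, 1)
radial_value_profile(value_map(agent1), c(10, 10), max_dist = 6)
#> # A tibble: 7 × 3
#>   distance mean_value n_squares
#>      <int>      <dbl>     <int>
#> 1        0   0.1              1
#> 2        1   0.0649           8
#> 3        2   0.0287          12
#> 4        3   0.0119          16
#> 5        4   0.00396         32
#> 6        5   0.00105         28
#> 7        6   0.000313        40

# 200 learning episodes in the painful maze
set.seed(7)
out <- run_steps(world, agent, n_episodes = 200)
m <- moving_stats(out$episodes$wall_hits)
c(episode_11 = m$mean[11], episode_200 = m$mean[200])
#> episode_11 episode_200
#>       21.5         4.4
state_value(out$agent, 18, 10)       # the reward-1 goal square
#> [1] 0.97
wall_value_mean(value_map(out$agent), world)
#> [1] -0.25
```

The updated square's value moves by exactly `alpha1 * delta = 0.1` and the
change decays smoothly with distance — the generalization gradient that a
look-up table lacks (`tabular_update()` changes exactly one cell). Over 200
episodes the smoothed wall-hit rate falls from ~21 to ~4 per episode as
generalized punishment learning builds negative wall values (mean -0.25),
while the goal square's value approaches its reward.

The full protocols are `run_painful_experiment()`,
`run_relearning_experiment()` and `run_disturbed_experiment()`; mazes come
from `maze_fixture()`, `generate_painful_maze()` or ASCII files via
`read_maze()`. See the vignette in `vignettes/` for the model's assumptions,
parameter choices and limitations.

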