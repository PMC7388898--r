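#' Tabular SARSA agent
#'
#' The "simple TD learning" comparison agent: a `width x height` look-up
#' table of state values `v_s`, afterstate action values
#' `Q_s(s, a) = v_s(x', y')`, and the plain on-policy update
#' `v_s(x', y') <- v_s(x', y') + alpha * delta_s`. Exactly one cell changes
#' per update, so there is no stimulus generalization.
#'
#' @param alpha learning rate (default 0.1).
#' @param gamma discount factor (default 0.95).
#' @param width,height table dimensions.
#' @return An object of class `c("tabular_agent", "rl_agent")`.
#' @export
tabular_agent <- function(alpha = 0.1, gamma = 0.95,
                          width = 20L, height = 20L) {
  stopifnot(alpha >= 0, gamma >= 0, gamma < 1)
  structure(
    list(v = matrix(0, width, height), alpha = alpha, gamma = gamma),
    class = c("tabular_agent", "rl_agent")
  )
}

#' @export
state_value.tabular_agent <- function(agent, x, y) agent$v[x, y]

#' @export
value_map.tabular_agent <- function(agent) agent$v

#' Tabular SARSA update
#'
#' @param agent a [tabular_agent()].
#' @param x,y the executed action's intended target (afterstate).
#' @param delta the TD error `delta_s`.
#' @return The updated agent.
#' @export
tabular_update <- function(agent, x, y, delta) {
  agent$v[x, y] <- agent$v[x, y] + agent$alpha * delta
  agent
}

#' MaxPain-style dual-table agent
#'
#' Keeps *separate* look-up tables for reward value `v_r` and pain value
#' `v_p`; the policy (and the displayed value map) uses their unnormalized
#' combination `v_L = v_r - v_p`. The reward table learns on-policy
#' (SARSA); the pain table bootstraps off-policy on the *worst-case* next
#' action -- the argmin of `Q_L(s', .)` -- so it learns to predict maximum
#' future pain.
#'
#' @param alpha_r,alpha_p learning rates (default 0.1 each).
#' @param gamma_r,gamma_p discount factors (defaults 0.95 and 0.5).
#' @param width,height table dimensions.
#' @return An object of class `c("maxpain_agent", "rl_agent")`.
#' @export
maxpain_agent <- function(alpha_r = 0.1, alpha_p = 0.1,
                          gamma_r = 0.95, gamma_p = 0.5,
                          width = 20L, height = 20L) {
  stopifnot(alpha_r >= 0, alpha_p >= 0,
            gamma_r >= 0, gamma_r < 1, gamma_p >= 0, gamma_p < 1)
  structure(
    list(v_r = matrix(0, width, height), v_p = matrix(0, width, height),
         alpha_r = alpha_r, alpha_p = alpha_p,
         gamma_r = gamma_r, gamma_p = gamma_p),
    class = c("maxpain_agent", "rl_agent")
  )
}

#' @export
state_value.maxpain_agent <- function(agent, x, y) {
  agent$v_r[x, y] - agent$v_p[x, y]
}

#' @export
value_map.maxpain_agent <- function(agent) agent$v_r - agent$v_p

#' Split a reward into reward and pain components
#'
#' `phi(z) = max(z, 0)` applied to `r` and `-r`: a positive reward feeds
#' the reward channel, a negative reward (pain) feeds the pain channel.
#'
#' @param r signed reward.
#' @return Named vector `c(r_plus = phi(r), r_minus = phi(-r))`.
#' @export
maxpain_split <- function(r) {
  c(r_plus = max(r, 0), r_minus = max(-r, 0))
}

#' MaxPain prediction errors
#'
#' `delta_r = phi(r) + gamma_r * Q_r(s', a') - Q_r(s, a)` (on-policy `a'`)
#' and `delta_p = phi(-r) + gamma_p * Q_p(s', a*) - Q_p(s, a)` where `a*`
#' minimizes the combined value `Q_L(s', .)` over all four actions (worst
#' case), ties broken uniformly at random from the current R stream. On
#' terminal transitions both bootstrap terms are zero.
#'
#' @param agent a [maxpain_agent()].
#' @param world a [gridworld()].
#' @param state the executed state `s`.
#' @param action the executed action.
#' @param r observed reward.
#' @param next_state `s'`.
#' @param next_action on-policy `a'` drawn at `s'` (ignored if terminal).
#' @param terminal whether the transition ended the episode.
#' @return Named vector `c(delta_r = ..., delta_p = ...)`.
#' @export
maxpain_errors <- function(agent, world, state, action, r,
                           next_state = NULL, next_action = NULL,
                           terminal = FALSE) {
  tgt <- candidate_targets(world, state)[action, ]
  split <- maxpain_split(r)
  q_r_cur <- agent$v_r[tgt[1], tgt[2]]
  q_p_cur <- agent$v_p[tgt[1], tgt[2]]
  if (terminal) {
    boot_r <- 0
    boot_p <- 0
  } else {
    nt <- candidate_targets(world, next_state)
    boot_r <- agent$v_r[nt[next_action, 1], nt[next_action, 2]]
    q_l <- agent$v_r[nt] - agent$v_p[nt]
    worst <- which(q_l == min(q_l))
    a_star <- if (length(worst) == 1) worst else {
      worst[floor(stats::runif(1) * length(worst)) + 1]
    }
    boot_p <- agent$v_p[nt[a_star, 1], nt[a_star, 2]]
  }
  c(delta_r = unname(split["r_plus"]) + agent$gamma_r * boot_r - q_r_cur,
    delta_p = unname(split["r_minus"]) + agent$gamma_p * boot_p - q_p_cur)
}

#' MaxPain table update
#'
#' Both tables update their afterstate cell independently:
#' `v_r(x', y') += alpha_r * delta_r` and `v_p(x', y') += alpha_p * delta_p`.
#'
#' @param agent a [maxpain_agent()].
#' @param x,y the executed action's intended target (afterstate).
#' @param delta_r,delta_p the two prediction errors.
#' @return The updated agent.
#' @export
maxpain_update <- function(agent, x, y, delta_r, delta_p) {
  agent$v_r[x, y] <- agent$v_r[x, y] + agent$alpha_r * delta_r
  agent$v_p[x, y] <- agent$v_p[x, y] + agent$alpha_p * delta_p
  agent
}
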