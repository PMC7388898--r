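#' Softmax action selection
#'
#' Actions are drawn with probability proportional to
#' `exp(v(x_c, y_c) / tau)` over the four intended targets, where `tau > 0`
#' trades off exploration against exploitation (0.5 throughout the standard
#' protocols). All four actions are always candidates, including those that
#' point at walls.
#'
#' @param values numeric vector of the four afterstate values.
#' @param tau temperature (> 0).
#' @return `softmax_probs()` returns the probability vector;
#'   `select_action()` draws an action index from it using the current R
#'   random stream.
#' @export
softmax_probs <- function(values, tau = 0.5) {
  if (any(!is.finite(values))) stop("action values must be finite")
  if (tau <= 0) stop("tau must be > 0")
  w <- exp((values - max(values)) / tau)
  w / sum(w)
}

#' @rdname softmax_probs
#' @export
select_action <- function(values, tau = 0.5) {
  p <- softmax_probs(values, tau)
  u <- stats::runif(1) * sum(p)
  which(u < cumsum(p))[1]
}

agent_engine_args <- function(agent) {
  if (inherits(agent, "ovarlap_agent")) {
    list(type = "ovarlap",
         state = list(Mt = t(agent$basis$M), w1 = agent$w1, w2 = agent$w2),
         params = list(alpha1 = agent$alpha1, alpha2 = agent$alpha2,
                       gamma = agent$gamma))
  } else if (inherits(agent, "tabular_agent")) {
    list(type = "tabular", state = list(v = agent$v),
         params = list(alpha = agent$alpha, gamma = agent$gamma))
  } else if (inherits(agent, "maxpain_agent")) {
    list(type = "maxpain", state = list(v_r = agent$v_r, v_p = agent$v_p),
         params = list(alpha_r = agent$alpha_r, alpha_p = agent$alpha_p,
                       gamma_r = agent$gamma_r, gamma_p = agent$gamma_p))
  } else {
    stop("unsupported agent class: ", paste(class(agent), collapse = "/"))
  }
}

absorb_engine_state <- function(agent, state) {
  if (inherits(agent, "ovarlap_agent")) {
    agent$w1 <- state$w1
    agent$w2 <- state$w2
  } else if (inherits(agent, "tabular_agent")) {
    agent$v <- state$v
  } else {
    agent$v_r <- state$v_r
    agent$v_p <- state$v_p
  }
  agent
}

#' Run the learning loop
#'
#' Executes the select-act-observe-bootstrap-update loop for a budget of
#' episodes (`n_episodes`) or of environment steps (`max_total_steps`,
#' truncating the final episode mid-flight), whichever is given. Wall-hit
#' steps consume time and trigger updates like any other step. Randomness
#' (softmax draws, tie-breaks, randomized starts) comes from R's RNG, so
#' `set.seed()` makes runs bit-reproducible.
#'
#' @param world a [gridworld()].
#' @param agent an OVaRLAP, tabular or MaxPain agent.
#' @param tau softmax temperature.
#' @param n_episodes number of episodes to run (`NULL` if step-limited).
#' @param max_total_steps total step budget (`NULL` if episode-limited).
#' @param episode_step_cap per-episode cap guarding non-terminating
#'   configurations; a capped episode is flagged `truncated`, not an error.
#' @param randomize_start draw each episode's start uniformly from passable
#'   non-goal squares instead of the world's start.
#' @param forced_actions optional injected action sequence replacing the
#'   policy (for oracle tests).
#' @param record_trace also return the per-step transition table.
#' @param log_wall_values also return the mean wall-square value after each
#'   episode (used by the relearning protocol).
#' @return A list with `agent` (updated), `episodes` (tibble: episode,
#'   steps, reward, wall_hits, truncated), `total_steps`, and optionally
#'   `trace` and `wall_values`.
#' @export
run_steps <- function(world, agent, tau = 0.5, n_episodes = NULL,
                      max_total_steps = NULL, episode_step_cap = 100000L,
                      randomize_start = FALSE,
                      forced_actions = integer(0), record_trace = FALSE,
                      log_wall_values = FALSE) {
  if (is.null(n_episodes) && is.null(max_total_steps) &&
      length(forced_actions) == 0) {
    stop("one of n_episodes / max_total_steps must be set")
  }
  args <- agent_engine_args(agent)
  res <- .engine_run(
    world$passable, world$start[1], world$start[2],
    cbind(world$goals$x, world$goals$y), world$goals$reward,
    world$wall_penalty, args$type, args$state, args$params, tau,
    if (is.null(n_episodes)) -1L else as.integer(n_episodes),
    if (is.null(max_total_steps)) -1L else as.integer(max_total_steps),
    as.integer(episode_step_cap), randomize_start,
    as.integer(forced_actions), record_trace, log_wall_values
  )
  out <- list(
    agent = absorb_engine_state(agent, res$state),
    episodes = tibble::as_tibble(res$episodes),
    total_steps = res$total_steps
  )
  if (log_wall_values) out$wall_values <- res$wall_values
  if (record_trace) out$trace <- tibble::as_tibble(res$trace)
  out
}

#' Run a single episode
#'
#' Convenience wrapper around [run_steps()] for one episode with the
#' per-step trace recorded.
#'
#' @inheritParams run_steps
#' @param step_cap per-episode step cap.
#' @return A list with `trace` (tibble of transitions), `agent`,
#'   `episodes` (one-row tibble of metrics).
#' @export
run_episode <- function(world, agent, tau = 0.5, step_cap = 100000L,
                        forced_actions = integer(0)) {
  out <- run_steps(world, agent, tau = tau, n_episodes = 1L,
                   episode_step_cap = step_cap,
                   forced_actions = forced_actions, record_trace = TRUE)
  list(trace = out$trace, agent = out$agent, episodes = out$episodes)
}
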