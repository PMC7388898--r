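#' The OVaRLAP value learner
#'
#' OVaRLAP ("Outspread Valuation for Reward Learning and Punishment
#' Learning") reads the state value out of the fixed basis layer through two
#' opponent weight channels: `d1(x,y) = w1 . h(x,y)` (the positive channel,
#' analogous to D1-expressing striatal neurons, potentiated by positive TD
#' errors) and `d2(x,y) = w2 . h(x,y)` (the negative channel, analogous to
#' D2 neurons, potentiated by negative TD errors). The output value is
#' `v = d1 - d2`. Action values follow the afterstate convention,
#' `Q(s, a) = v(x', y')` at the square the action points at, and learning is
#' on-policy SARSA. Because the basis responses overlap spatially, a single
#' update spreads to neighbouring squares (generalization); the opposing
#' channel later carves that spread back where predictions mismatch
#' outcomes (discrimination).
#'
#' Both weight vectors start at zero and, with a non-negative basis, only
#' ever receive non-negative increments: each channel accumulates evidence
#' and the *difference* does the discounting.
#'
#' @param basis a [build_basis()] network.
#' @param alpha1 learning rate for positive TD errors (default 0.1).
#' @param alpha2 learning rate for negative TD errors (default 0.1; 0 gives
#'   the "impaired" agent that cannot discriminate).
#' @param gamma discount factor in `[0, 1)` (0.95 in the painful task,
#'   0.8 in the disturbed task).
#' @return An object of class `c("ovarlap_agent", "rl_agent")`.
#' @export
ovarlap_agent <- function(basis, alpha1 = 0.1, alpha2 = 0.1, gamma = 0.95) {
  stopifnot(inherits(basis, "basis_network"),
            alpha1 >= 0, alpha2 >= 0, gamma >= 0, gamma < 1)
  structure(
    list(
      w1 = numeric(basis$spec$n_hidden),
      w2 = numeric(basis$spec$n_hidden),
      basis = basis,
      alpha1 = alpha1, alpha2 = alpha2, gamma = gamma
    ),
    class = c("ovarlap_agent", "rl_agent")
  )
}

#' @export
print.ovarlap_agent <- function(x, ...) {
  cat(sprintf(
    "<ovarlap_agent alpha1 = %g, alpha2 = %g, gamma = %g, theta = %g>\n",
    x$alpha1, x$alpha2, x$gamma, x$basis$spec$theta
  ))
  invisible(x)
}

#' Channel activities at a position
#'
#' @param agent an [ovarlap_agent()].
#' @param x,y position.
#' @return Named numeric vector `c(d1 = ..., d2 = ...)`.
#' @export
channel_values <- function(agent, x, y) {
  h <- hidden_activity(agent$basis, x, y)
  c(d1 = sum(agent$w1 * h), d2 = sum(agent$w2 * h))
}

#' State value
#'
#' Generic over agent types: the scalar value an agent assigns to a square.
#' For OVaRLAP this is `d1 - d2`; for the tabular agent the table cell; for
#' MaxPain the combined value `v_r - v_p` that drives its policy.
#'
#' @param agent an agent.
#' @param x,y position.
#' @export
state_value <- function(agent, x, y) UseMethod("state_value")

#' @export
state_value.ovarlap_agent <- function(agent, x, y) {
  d <- channel_values(agent, x, y)
  unname(d["d1"] - d["d2"])
}

#' Afterstate action value
#'
#' `Q(s, a) = v(x', y')` where `(x', y')` is the intended target of action
#' `a` from state `s` -- evaluated even when the target is impassable
#' (wall squares carry learned value).
#'
#' @param agent an agent.
#' @param world a [gridworld()].
#' @param state `c(x, y)`.
#' @param action integer 1..4.
#' @export
action_value <- function(agent, world, state, action) {
  tgt <- candidate_targets(world, state)[action, ]
  state_value(agent, tgt[1], tgt[2])
}

#' SARSA temporal-difference error
#'
#' `delta = r + gamma * q_next - q_cur`; on terminal transitions the
#' bootstrap term is dropped (episodic semantics: no successor action
#' exists once a goal is entered).
#'
#' @param r observed reward.
#' @param gamma discount factor.
#' @param q_next value of the successor state-action (ignored if
#'   `terminal`).
#' @param q_cur value of the executed state-action.
#' @param terminal whether the transition ended the episode.
#' @export
td_error <- function(r, gamma, q_next, q_cur, terminal = FALSE) {
  if (terminal) r - q_cur else r + gamma * q_next - q_cur
}

#' Apply one OVaRLAP weight update
#'
#' Updates the channel matching the sign of the TD error at the afterstate
#' `(x', y')` of the executed action: for `delta > 0`,
#' `w1 <- w1 + alpha1 * delta * h / sum(h^2)` (and `w2` untouched); for
#' `delta < 0`, `w2 <- w2 + alpha2 * (-delta) * h / sum(h^2)`; no change at
#' `delta = 0`. The `h / sum(h^2)` normalization makes the increment exact:
#' the value of `(x', y')` moves by precisely `alpha1 * delta`
#' (respectively `alpha2 * delta`), independent of the basis realization.
#'
#' @param agent an [ovarlap_agent()].
#' @param x,y the intended target (afterstate) of the updated action.
#' @param delta the TD error.
#' @return The updated agent.
#' @export
ovarlap_update <- function(agent, x, y, delta) {
  if (delta == 0) return(agent)
  h <- hidden_activity(agent$basis, x, y)
  nrm <- sum(h^2)
  if (nrm <= 0) stop("zero hidden-activity norm at (", x, ",", y, ")")
  if (delta > 0) {
    agent$w1 <- agent$w1 + agent$alpha1 * delta * h / nrm
  } else {
    agent$w2 <- agent$w2 + agent$alpha2 * (-delta) * h / nrm
  }
  agent
}

#' Full value map of an agent
#'
#' The value `v(x, y)` for every square, as a `width x height` matrix.
#' For OVaRLAP this is the basis read-out `d1 - d2`; for the tabular agent
#' its table; for MaxPain the combination `v_r - v_p` that drives its
#' decisions (and is what its value-map figures display).
#'
#' @param agent an agent.
#' @export
value_map <- function(agent) UseMethod("value_map")

#' @export
value_map.ovarlap_agent <- function(agent) {
  spec <- agent$basis$spec
  v <- as.numeric(agent$basis$M %*% (agent$w1 - agent$w2))
  # linear index p = height*(x-1) + y: columns of the matrix are x
  matrix(v, nrow = spec$height, ncol = spec$width) |> t()
}

#' Agent checkpointing
#'
#' Serializes an agent's learned state to JSON text (weights or tables plus
#' learning parameters). The basis network of an OVaRLAP agent is not
#' embedded; rebuild it with [build_basis()] under the same seed and pass it
#' to `read_agent()`.
#'
#' @param agent an agent.
#' @param path file path.
#' @param basis basis network to attach when reading an OVaRLAP checkpoint.
#' @export
write_agent <- function(agent, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for checkpoints")
  }
  payload <- unclass(agent)
  payload$basis <- NULL
  payload$.class <- class(agent)[1]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_agent
#' @export
read_agent <- function(path, basis = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for checkpoints")
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$.class
  payload$.class <- NULL
  if (cls == "ovarlap_agent") {
    if (is.null(basis)) stop("an OVaRLAP checkpoint needs its basis network")
    agent <- ovarlap_agent(basis, payload$alpha1, payload$alpha2,
                           payload$gamma)
    agent$w1 <- payload$w1
    agent$w2 <- payload$w2
  } else if (cls == "tabular_agent") {
    v <- as.matrix(payload$v)
    agent <- tabular_agent(payload$alpha, payload$gamma,
                           width = nrow(v), height = ncol(v))
    agent$v <- unname(v)
  } else if (cls == "maxpain_agent") {
    v_r <- as.matrix(payload$v_r)
    v_p <- as.matrix(payload$v_p)
    agent <- maxpain_agent(payload$alpha_r, payload$alpha_p,
                           payload$gamma_r, payload$gamma_p,
                           width = nrow(v_r), height = ncol(v_r))
    agent$v_r <- unname(v_r)
    agent$v_p <- unname(v_p)
  } else {
    stop("unknown agent class in checkpoint: ", cls)
  }
  agent
}
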