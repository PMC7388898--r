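#' Derive a sub-seed from a master seed
#'
#' Counter-based derivation of independent named random streams (basis
#' widths, connection noise, policy) from a single master seed, so that
#' e.g. changing the noise setting does not perturb the width draws of the
#' same run. Purely arithmetic (a mixed congruential walk over the provided
#' indices), always in `[1, 2^31 - 2]`.
#'
#' @param master master seed (integer).
#' @param ... integer indices naming the stream (run number, stream id...).
#' @export
derive_seed <- function(master, ...) {
  ix <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in ix) {
    s <- (s * 69069 + as.double(i) * 1234567 + 12345) %% 2147483647
  }
  as.integer(s) + 1L
}

STREAM_VARIANCES <- 1L
STREAM_NOISE <- 2L
STREAM_POLICY <- 3L
STREAM_MAZE <- 4L

# Build a per-run basis with named streams for widths and noise.
build_run_basis <- function(theta, A, rho, master, run,
                            width = 20L, height = 20L) {
  spec <- basis_spec(theta = theta, width = width, height = height,
                     noise_strength = A, noise_fraction = rho)
  set.seed(derive_seed(master, run, STREAM_VARIANCES))
  variances <- sample_variances(theta, spec$n_hidden)
  noise <- NULL
  if (A > 0 && rho > 0) {
    set.seed(derive_seed(master, run, STREAM_NOISE))
    noise <- sample_noise(A, rho, spec$n_input, spec$n_hidden)
  }
  build_basis(spec, variances = variances, noise = noise)
}

make_agent <- function(kind, world, theta = 1, master = 1L, run = 1L,
                       alpha1 = 0.1, alpha2 = 0.1, gamma = 0.95,
                       A = 0, rho = 0) {
  switch(kind,
    ovarlap = ovarlap_agent(
      build_run_basis(theta, A, rho, master, run,
                      world$width, world$height),
      alpha1 = alpha1, alpha2 = alpha2, gamma = gamma),
    tabular = tabular_agent(alpha = 0.1, gamma = 0.95,
                            width = world$width, height = world$height),
    maxpain = maxpain_agent(alpha_r = 0.1, alpha_p = 0.1,
                            gamma_r = 0.95, gamma_p = 0.5,
                            width = world$width, height = world$height),
    stop("unknown agent kind '", kind, "'")
  )
}

#' Painful grid-world navigation experiment
#'
#' The main protocol: independent runs of 500 learning episodes in a
#' painful world (wall hits cost -1) for each requested agent kind, all
#' with softmax temperature 0.5, learning rate 0.1 and discount 0.95
#' (MaxPain's pain channel uses discount 0.5). Each OVaRLAP run draws a
#' fresh basis network. Value-map snapshots are taken at the configured
#' episodes.
#'
#' @param world a painful [gridworld()] (e.g. `maze_fixture("painful")` or
#'   [generate_painful_maze()]).
#' @param agents agent kinds to run.
#' @param n_runs independent runs per agent (50 in the full protocol).
#' @param n_episodes episodes per run (500 in the full protocol).
#' @param theta OVaRLAP generalization metaparameter.
#' @param snapshots episodes at which to snapshot the value map.
#' @param seed master seed; per-run streams are derived from it.
#' @param episode_step_cap guard against non-terminating episodes.
#' @param randomize_start randomize each episode's start square.
#' @return A list with `episodes` (tibble: agent, run, episode, steps,
#'   total_reward, wall_hits, reward_per_step, truncated) and `snapshots`
#'   (tibble: agent, run, episode, map — a list-column of matrices).
#' @export
run_painful_experiment <- function(world,
                                   agents = c("ovarlap", "tabular",
                                              "maxpain"),
                                   n_runs = 50L, n_episodes = 500L,
                                   theta = 1, snapshots = c(5L, 30L, 150L,
                                                            500L),
                                   seed = 1L, episode_step_cap = 100000L,
                                   randomize_start = FALSE) {
  snapshots <- sort(unique(snapshots[snapshots <= n_episodes]))
  ep_rows <- list()
  snap_rows <- list()
  for (kind in agents) {
    for (run in seq_len(n_runs)) {
      agent <- make_agent(kind, world, theta = theta, master = seed,
                          run = run)
      set.seed(derive_seed(seed, run, STREAM_POLICY, match(kind, agents)))
      done <- 0L
      eps <- list()
      for (b in unique(c(snapshots, n_episodes))) {
        res <- run_steps(world, agent, n_episodes = b - done,
                         episode_step_cap = episode_step_cap,
                         randomize_start = randomize_start)
        agent <- res$agent
        e <- res$episodes
        e$episode <- e$episode + done
        eps[[length(eps) + 1]] <- e
        done <- b
        if (b %in% snapshots) {
          vm <- value_map(agent)
          snap_rows[[length(snap_rows) + 1]] <- tibble::tibble(
            agent = kind, run = run, episode = b, map = list(vm)
          )
        }
      }
      e <- do.call(rbind, eps)
      ep_rows[[length(ep_rows) + 1]] <- tibble::tibble(
        agent = kind, run = run, episode = e$episode, steps = e$steps,
        total_reward = e$reward, wall_hits = e$wall_hits,
        reward_per_step = e$reward / e$steps, truncated = e$truncated == 1
      )
    }
  }
  list(
    episodes = do.call(rbind, ep_rows),
    snapshots = if (length(snap_rows)) do.call(rbind, snap_rows) else NULL
  )
}

#' Relearning after pain removal
#'
#' Agents train in the painful world for `switch_episode` episodes; the
#' walls then become pain-free (penalty 0) and training continues for
#' `post_episodes` more. The mean value over wall squares is logged after
#' every episode, tracking how quickly each agent unlearns the walls'
#' painfulness once it is gone.
#'
#' @inheritParams run_painful_experiment
#' @param switch_episode episode at which the penalty switches to 0
#'   (500 in the full protocol).
#' @param post_episodes additional pain-free episodes.
#' @return A list with `wall_values` (tibble: agent, run, episode,
#'   wall_value) and `episodes` as in [run_painful_experiment()].
#' @export
run_relearning_experiment <- function(world,
                                      agents = c("ovarlap", "tabular",
                                                 "maxpain"),
                                      n_runs = 50L, switch_episode = 500L,
                                      post_episodes = 500L, theta = 1,
                                      seed = 1L,
                                      episode_step_cap = 100000L) {
  painless <- set_wall_penalty(world, 0)
  wall_rows <- list()
  ep_rows <- list()
  for (kind in agents) {
    for (run in seq_len(n_runs)) {
      agent <- make_agent(kind, world, theta = theta, master = seed,
                          run = run)
      set.seed(derive_seed(seed, run, STREAM_POLICY, match(kind, agents)))
      pre <- run_steps(world, agent, n_episodes = switch_episode,
                       episode_step_cap = episode_step_cap,
                       log_wall_values = TRUE)
      post <- run_steps(painless, pre$agent, n_episodes = post_episodes,
                        episode_step_cap = episode_step_cap,
                        log_wall_values = TRUE)
      wall_rows[[length(wall_rows) + 1]] <- tibble::tibble(
        agent = kind, run = run,
        episode = seq_len(switch_episode + post_episodes),
        wall_value = c(pre$wall_values, post$wall_values)
      )
      e <- rbind(pre$episodes, post$episodes)
      ep_rows[[length(ep_rows) + 1]] <- tibble::tibble(
        agent = kind, run = run,
        episode = seq_len(nrow(e)), steps = e$steps,
        total_reward = e$reward, wall_hits = e$wall_hits,
        reward_per_step = e$reward / e$steps, truncated = e$truncated == 1
      )
    }
  }
  list(
    wall_values = do.call(rbind, wall_rows),
    episodes = do.call(rbind, ep_rows)
  )
}

#' Disturbed-agent valuation experiment
#'
#' Runs OVaRLAP in the painless four-goal world for a fixed budget of total
#' steps (40,000 in the full protocol; episodes restart at the start square
#' after each goal and the final episode is truncated at the budget) under
#' a 2x2 disturbance design: negative-error learning intact
#' (`alpha2 = 0.1`) or impaired (`alpha2 = 0`), crossed with connection
#' noise present (`A`, `rho`) or absent. Each run draws fresh basis widths
#' and, in noised settings, a fresh frozen noise realization. The outcome
#' per run is the final value map and the location/size of its maximum.
#'
#' @param world a painless [gridworld()] (e.g. `maze_fixture("painless")`).
#' @param settings subset of `"intact_unnoised"`, `"intact_noised"`,
#'   `"impaired_unnoised"`, `"impaired_noised"`.
#' @param n_runs runs per setting (50 in the full protocol).
#' @param total_steps step budget per run.
#' @param A,rho noise strength and fraction for the noised settings.
#' @param theta,gamma OVaRLAP metaparameters (1 and 0.8 in this protocol).
#' @param seed master seed.
#' @return A list with `summary` (tibble: setting, run, episodes_completed,
#'   max_value, x, y, distance_to_nearest_goal) and `maps` (tibble:
#'   setting, run, map list-column).
#' @export
run_disturbed_experiment <- function(world,
                                     settings = c("intact_unnoised",
                                                  "intact_noised",
                                                  "impaired_unnoised",
                                                  "impaired_noised"),
                                     n_runs = 50L, total_steps = 40000L,
                                     A = 1, rho = 0.005, theta = 1,
                                     gamma = 0.8, seed = 1L) {
  sum_rows <- list()
  map_rows <- list()
  for (setting in settings) {
    impaired <- grepl("^impaired", setting)
    noised <- grepl("noised$", setting) && !grepl("unnoised$", setting)
    for (run in seq_len(n_runs)) {
      basis <- build_run_basis(theta,
                               A = if (noised) A else 0,
                               rho = if (noised) rho else 0,
                               master = seed, run = run,
                               width = world$width, height = world$height)
      agent <- ovarlap_agent(basis, alpha1 = 0.1,
                             alpha2 = if (impaired) 0 else 0.1,
                             gamma = gamma)
      set.seed(derive_seed(seed, run, STREAM_POLICY))
      res <- run_steps(world, agent, max_total_steps = total_steps,
                       episode_step_cap = total_steps)
      vm <- value_map(res$agent)
      am <- value_argmax(vm, world)
      sum_rows[[length(sum_rows) + 1]] <- tibble::tibble(
        setting = setting, run = run,
        episodes_completed = nrow(res$episodes),
        max_value = am$max_value, x = am$x, y = am$y,
        distance_to_nearest_goal = am$distance_to_nearest_goal
      )
      map_rows[[length(map_rows) + 1]] <- tibble::tibble(
        setting = setting, run = run, map = list(vm)
      )
    }
  }
  list(summary = do.call(rbind, sum_rows), maps = do.call(rbind, map_rows))
}
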