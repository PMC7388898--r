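# Small worlds and oracles shared across tests.

# 6x3 corridor: passable cells (2..5, 2), start west end, reward-1 goal east.
corridor_world <- function(wall_penalty = -1, goal_reward = 1) {
  passable <- matrix(FALSE, 6, 3)
  passable[2:5, 2] <- TRUE
  gridworld(passable, start = c(2, 2),
            goals = tibble::tibble(x = 5, y = 2, reward = goal_reward),
            wall_penalty = wall_penalty)
}

# 5x5 pocket with one interior wall at (3,2) and a goal at (4,3); start (2,2).
pocket_world <- function(wall_penalty = -1) {
  passable <- matrix(FALSE, 5, 5)
  passable[2:4, 2:4] <- TRUE
  passable[3, 2] <- FALSE
  gridworld(passable, start = c(2, 2),
            goals = tibble::tibble(x = 4, y = 3, reward = 2),
            wall_penalty = wall_penalty)
}

# Brute-force afterstate SARSA on a look-up table with an injected action
# sequence, written directly from the transition rules (independent of the
# package's engine). Mirrors the engine's episode semantics: the first
# action of each episode and every successor action are consumed from the
# sequence; a pending transition whose successor action is unavailable gets
# no update and ends the run.
oracle_tabular_sarsa <- function(world, actions, alpha, gamma) {
  dx <- c(1L, -1L, 0L, 0L)
  dy <- c(0L, 0L, -1L, 1L)
  v <- matrix(0, world$width, world$height)
  i <- 1
  repeat {
    if (i > length(actions)) break
    x <- world$start[1]; y <- world$start[2]
    a <- actions[i]; i <- i + 1
    repeat {
      tx <- x + dx[a]; ty <- y + dy[a]
      gi <- which(world$goals$x == tx & world$goals$y == ty)
      if (!world$passable[tx, ty]) {
        r <- world$wall_penalty; nx <- x; ny <- y; term <- FALSE
      } else if (length(gi) == 1) {
        r <- world$goals$reward[gi]; nx <- tx; ny <- ty; term <- TRUE
      } else {
        r <- 0; nx <- tx; ny <- ty; term <- FALSE
      }
      if (term) {
        v[tx, ty] <- v[tx, ty] + alpha * (r - v[tx, ty])
        break
      }
      if (i > length(actions)) return(v)
      a2 <- actions[i]; i <- i + 1
      q_next <- v[nx + dx[a2], ny + dy[a2]]
      v[tx, ty] <- v[tx, ty] + alpha * (r + gamma * q_next - v[tx, ty])
      x <- nx; y <- ny; a <- a2
    }
  }
  v
}
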