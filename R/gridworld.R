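#' Grid-world navigation environments
#'
#' A grid world is a `width` x `height` board of squares, each passable or
#' impassable, with a start square, one or more absorbing goal squares that
#' deliver a positive reward and end the episode, and a wall penalty: the
#' reward delivered when the agent takes an *ineffective* action, i.e. moves
#' into an impassable square and stays put. Painful worlds use a wall penalty
#' of -1; painless worlds use 0.
#'
#' Coordinates are 1-based `(x, y)` with `x` the column and `y` the row;
#' `y` increases to the north. The border ring (`x` or `y` equal to 1 or the
#' grid size) is always impassable, so every intended target of the four
#' moves has a representable position.
#'
#' @param passable logical matrix, indexed `[x, y]`, `TRUE` where the agent
#'   may stand.
#' @param start integer vector `c(x, y)`, the starting square.
#' @param goals data frame with columns `x`, `y`, `reward` (positive).
#' @param wall_penalty reward delivered on an ineffective action; must be
#'   `<= 0`.
#' @return An object of class `gridworld`: a list with fields `width`,
#'   `height`, `passable`, `start`, `goals` (a tibble), `wall_penalty`.
#' @examples
#' w <- maze_fixture("painful")
#' w$goals
#' gw_step(w, w$start, 1L)
#' @export
gridworld <- function(passable, start, goals, wall_penalty = -1) {
  stopifnot(is.matrix(passable), is.logical(passable))
  width <- nrow(passable)
  height <- ncol(passable)
  goals <- tibble::as_tibble(goals)
  stopifnot(all(c("x", "y", "reward") %in% names(goals)))
  if (wall_penalty > 0) {
    stop("wall_penalty must be <= 0, got ", wall_penalty)
  }
  w <- structure(
    list(
      width = width, height = height,
      passable = passable,
      start = as.integer(start),
      goals = goals,
      wall_penalty = wall_penalty
    ),
    class = "gridworld"
  )
  validate_gridworld(w)
  w
}

#' @export
print.gridworld <- function(x, ...) {
  cat(sprintf(
    "<gridworld %dx%d, %d goal(s), wall_penalty = %g>\n",
    x$width, x$height, nrow(x$goals), x$wall_penalty
  ))
  cat(format_maze(x))
  invisible(x)
}

validate_gridworld <- function(w) {
  border <- c(w$passable[1, ], w$passable[w$width, ],
              w$passable[, 1], w$passable[, w$height])
  if (any(border)) stop("all border squares must be impassable")
  if (!w$passable[w$start[1], w$start[2]]) stop("start square is impassable")
  if (nrow(w$goals) < 1) stop("at least one goal is required")
  if (any(w$goals$reward <= 0)) stop("goal rewards must be positive")
  gkey <- paste(w$goals$x, w$goals$y)
  if (anyDuplicated(gkey)) stop("goal positions must be pairwise distinct")
  if (any(gkey == paste(w$start[1], w$start[2]))) {
    stop("a goal may not coincide with the start square")
  }
  for (i in seq_len(nrow(w$goals))) {
    if (!w$passable[w$goals$x[i], w$goals$y[i]]) {
      stop("goal at (", w$goals$x[i], ",", w$goals$y[i], ") is impassable")
    }
  }
  reach <- reachable_mask(w)
  for (i in seq_len(nrow(w$goals))) {
    if (!reach[w$goals$x[i], w$goals$y[i]]) {
      stop("goal at (", w$goals$x[i], ",", w$goals$y[i],
           ") is not reachable from the start")
    }
  }
  invisible(w)
}

# Flood fill (BFS) over 4-neighbour moves from the start square.
reachable_mask <- function(w) {
  reach <- matrix(FALSE, w$width, w$height)
  queue <- matrix(w$start, ncol = 2)
  reach[w$start[1], w$start[2]] <- TRUE
  dx <- c(1L, -1L, 0L, 0L)
  dy <- c(0L, 0L, -1L, 1L)
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = TRUE]
    queue <- queue[-1, , drop = FALSE]
    for (a in 1:4) {
      nx <- cur[1] + dx[a]
      ny <- cur[2] + dy[a]
      if (nx >= 1 && nx <= w$width && ny >= 1 && ny <= w$height &&
          w$passable[nx, ny] && !reach[nx, ny]) {
        reach[nx, ny] <- TRUE
        queue <- rbind(queue, c(nx, ny))
      }
    }
  }
  reach
}

#' The four grid actions
#'
#' Actions are unit displacements, in the fixed order east, west, south,
#' north: `(1,0), (-1,0), (0,-1), (0,1)`. All four are always selectable;
#' an action into an impassable square is *ineffective* (a "wall hit"): the
#' agent stays put and receives the world's `wall_penalty`.
#'
#' @return A tibble with columns `action` (1..4), `name`, `dx`, `dy`.
#' @export
gw_actions <- function() {
  tibble::tibble(
    action = 1:4,
    name = c("east", "west", "south", "north"),
    dx = c(1L, -1L, 0L, 0L),
    dy = c(0L, 0L, -1L, 1L)
  )
}

goal_index <- function(world, x, y) {
  hit <- which(world$goals$x == x & world$goals$y == y)
  if (length(hit) == 0) 0L else hit[1]
}

#' Intended targets of the four actions
#'
#' Returns the square each action points at from `state`, in action order
#' east, west, south, north. Targets may be impassable: they are *valued*
#' by the agents (afterstate convention) even though they cannot be entered.
#'
#' @param world a [gridworld()].
#' @param state integer `c(x, y)`, a passable square.
#' @return A 4 x 2 integer matrix of `(x, y)` targets.
#' @export
candidate_targets <- function(world, state) {
  stopifnot(world$passable[state[1], state[2]])
  acts <- gw_actions()
  cbind(x = state[1] + acts$dx, y = state[2] + acts$dy)
}

#' Execute one action
#'
#' Applies the transition semantics: moving into a goal square delivers that
#' goal's reward and ends the episode; moving into a passable non-goal
#' square moves the agent with reward 0; moving into an impassable square is
#' a wall hit -- the agent stays at `state` and receives `wall_penalty`.
#'
#' @inheritParams candidate_targets
#' @param action integer 1..4 (east, west, south, north; see [gw_actions()]).
#' @return A list of class `gw_transition` with fields `state`, `action`,
#'   `intended_target`, `next_state`, `reward`, `terminal`, `wall_hit`.
#' @export
gw_step <- function(world, state, action) {
  x <- state[1]; y <- state[2]
  if (!world$passable[x, y]) stop("state (", x, ",", y, ") is impassable")
  if (goal_index(world, x, y) > 0) {
    stop("state (", x, ",", y, ") is a goal square; goals are absorbing")
  }
  tgt <- candidate_targets(world, state)[action, ]
  gi <- goal_index(world, tgt[1], tgt[2])
  if (!world$passable[tgt[1], tgt[2]]) {
    out <- list(reward = world$wall_penalty, next_state = c(x, y),
                terminal = FALSE, wall_hit = TRUE)
  } else if (gi > 0) {
    out <- list(reward = world$goals$reward[gi], next_state = unname(tgt),
                terminal = TRUE, wall_hit = FALSE)
  } else {
    out <- list(reward = 0, next_state = unname(tgt),
                terminal = FALSE, wall_hit = FALSE)
  }
  structure(
    c(list(state = c(x, y), action = as.integer(action),
           intended_target = unname(tgt)), out),
    class = "gw_transition"
  )
}

#' Toggle wall pain
#'
#' Returns the same world with a different wall penalty; used by the
#' relearning protocol, where walls become pain-free mid-run.
#'
#' @inheritParams candidate_targets
#' @param wall_penalty new penalty (`<= 0`).
#' @export
set_wall_penalty <- function(world, wall_penalty) {
  world$wall_penalty <- wall_penalty
  validate_gridworld(world)
  world
}
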