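test_that("step semantics: goal entry, free move, wall hit", {
  w <- pocket_world(wall_penalty = -1)

  # wall hit: (2,2) east points at the interior wall (3,2)
  tr <- gw_step(w, c(2, 2), 1L)
  expect_equal(tr$reward, -1)
  expect_equal(tr$next_state, c(2, 2))
  expect_true(tr$wall_hit)
  expect_false(tr$terminal)
  expect_equal(tr$intended_target, c(3, 2))

  # same situation in a painless world
  wp <- set_wall_penalty(w, 0)
  tr0 <- gw_step(wp, c(2, 2), 1L)
  expect_equal(tr0$reward, 0)
  expect_equal(tr0$next_state, c(2, 2))
  expect_true(tr0$wall_hit)

  # ordinary move
  tr2 <- gw_step(w, c(2, 2), 4L)  # north to (2,3)
  expect_equal(tr2$reward, 0)
  expect_equal(tr2$next_state, c(2, 3))
  expect_false(tr2$wall_hit)

  # goal entry ends the episode with the goal's reward
  tr3 <- gw_step(w, c(3, 3), 1L)  # east into goal (4,3), reward 2
  expect_equal(tr3$reward, 2)
  expect_true(tr3$terminal)

  # contract violations
  expect_error(gw_step(w, c(1, 1), 1L), "impassable")
  expect_error(gw_step(w, c(4, 3), 1L), "absorbing")
})

test_that("candidate targets follow the fixed action order and admit walls", {
  w <- maze_fixture("painless")
  expect_equal(candidate_targets(w, c(10, 10)),
               cbind(x = c(11L, 9L, 10L, 10L), y = c(10L, 10L, 9L, 11L)))
  # next to the border: still 4 targets, one impassable
  tg <- candidate_targets(w, c(2, 10))
  expect_equal(nrow(tg), 4L)
  expect_false(w$passable[tg[2, 1], tg[2, 2]])
  # fully walled pocket
  p <- matrix(FALSE, 5, 5); p[2, 2] <- TRUE; p[2, 3] <- TRUE
  wpk <- gridworld(p, c(2, 2), tibble::tibble(x = 2, y = 3, reward = 1), 0)
  tgp <- candidate_targets(wpk, c(2, 2))
  expect_equal(nrow(tgp), 4L)
})

test_that("transition invariants hold along random trajectories", {
  set.seed(301)
  for (rep in 1:5) {
    w <- generate_painful_maze()
    ag <- tabular_agent(width = w$width, height = w$height)
    out <- run_steps(w, ag, n_episodes = 3, record_trace = TRUE,
                     episode_step_cap = 2000)
    tr <- out$trace
    # wall_hit <=> stayed put <=> target impassable
    stayed <- tr$next_x == tr$x & tr$next_y == tr$y
    expect_equal(tr$wall_hit == 1, stayed)
    expect_equal(tr$wall_hit == 1,
                 !w$passable[cbind(tr$target_x, tr$target_y)])
    # terminal <=> positive reward <=> next state is a goal
    expect_equal(tr$terminal == 1, tr$reward > 0)
    gkey <- paste(w$goals$x, w$goals$y)
    expect_equal(tr$terminal == 1,
                 paste(tr$next_x, tr$next_y) %in% gkey)
    # per-episode wall hits equal the count of ineffective actions
    expect_equal(out$episodes$wall_hits,
                 as.integer(tapply(tr$wall_hit, tr$episode, sum)),
                 ignore_attr = TRUE)
  }
})

test_that("painless episodes bank exactly the entered goal's reward", {
  w <- maze_fixture("painless")
  ag <- tabular_agent()
  set.seed(302)
  out <- run_steps(w, ag, n_episodes = 5, record_trace = TRUE)
  done <- out$episodes[out$episodes$truncated == 0, ]
  expect_true(all(done$reward %in% w$goals$reward))
})

test_that("maze generator obeys the construction rules", {
  set.seed(303)
  w1 <- generate_painful_maze()
  set.seed(303)
  w2 <- generate_painful_maze()
  expect_identical(format_maze(w1), format_maze(w2))  # seed determinism

  set.seed(304)
  mazes <- generate_painful_mazes(5)
  keys <- vapply(mazes, ovarlap:::maze_canonical_key, character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (w in mazes) {
    expect_setequal(w$goals$reward, c(1, 2))
    expect_equal(w$wall_penalty, -1)
    # reachability of both goals from start (flood fill)
    reach <- ovarlap:::reachable_mask(w)
    expect_true(all(reach[cbind(w$goals$x, w$goals$y)]))
    # border ring impassable
    expect_false(any(w$passable[c(1, w$width), ]))
    expect_false(any(w$passable[, c(1, w$height)]))
  }
  expect_error(generate_painful_maze(wide_width = 10, narrow_width = 10),
               "fit")
})

test_that("ASCII maze format round-trips and rejects malformed input", {
  for (name in c("painful", "painless")) {
    w <- maze_fixture(name)
    w2 <- read_maze(format_maze(w))
    expect_equal(w2$passable, w$passable)
    expect_equal(w2$start, w$start)
    expect_equal(w2$goals[order(w2$goals$x, w2$goals$y), ],
                 w$goals[order(w$goals$x, w$goals$y), ])
    expect_equal(w2$wall_penalty, w$wall_penalty)
  }
  set.seed(305)
  w <- generate_painful_maze()
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path), add = TRUE)
  write_maze(w, path)
  expect_equal(format_maze(read_maze(path)), format_maze(w))

  good <- strsplit(format_maze(maze_fixture("painful")), "\n")[[1]]
  bad_width <- good
  bad_width[3] <- substr(bad_width[3], 1, 19)
  expect_error(read_maze(bad_width), "line 3")
  no_start <- sub("S", ".", good)
  expect_error(read_maze(no_start), "no 'S'")
  bad_glyph <- good
  substr(bad_glyph[5], 7, 7) <- "?"
  expect_error(read_maze(bad_glyph), "unknown glyph")
  expect_error(read_maze(c(good, "shiny=1")), "unknown header key")
})
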