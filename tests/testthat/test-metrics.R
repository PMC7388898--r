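test_that("episode metrics count steps, wall hits and signed rewards", {
  trace <- tibble::tibble(
    episode = rep(1L, 10),
    reward = c(0, -1, 0, 0, -1, 0, 0, 0, 0, 1),
    wall_hit = c(0, 1, 0, 0, 1, 0, 0, 0, 0, 0)
  )
  m <- episode_metrics(trace)
  expect_equal(m$steps, 10)
  expect_equal(m$wall_hits, 2)
  expect_equal(m$total_reward, -1)
  expect_equal(m$reward_per_step, -0.1)
  expect_equal(m$reward_per_step * m$steps, m$total_reward)

  one <- episode_metrics(tibble::tibble(episode = 1L, reward = 2,
                                        wall_hit = 0L))
  expect_equal(one$reward_per_step, 2)
  expect_error(episode_metrics(trace[0, ]), "empty")
})

test_that("moving statistics use a trailing truncated window", {
  const <- moving_stats(rep(3, 20))
  expect_true(all(const$mean == 3))
  expect_true(all(const$sd == 0))

  m <- moving_stats(1:11)
  expect_equal(m$mean[11], 6)
  expect_equal(m$mean[1], 1)   # head truncated to available history
  expect_equal(m$n[1], 1L)
  expect_equal(m$n[11], 11L)

  # window 1 is the identity on means
  expect_equal(moving_stats(c(4, 8, 15), window = 1)$mean, c(4, 8, 15))
})

test_that("cross-run aggregation reports mean, SD and per-point n", {
  identical_runs <- list(c(1, 2, 3), c(1, 2, 3))
  agg <- aggregate_runs(identical_runs)
  expect_equal(agg$sd, c(0, 0, 0))
  expect_equal(agg$mean, c(1, 2, 3))

  two <- aggregate_runs(list(0, 2))
  expect_equal(two$mean, 1)
  expect_equal(two$sd, 1)   # population SD

  ragged <- aggregate_runs(list(c(1, 5), c(3)))
  expect_equal(ragged$n, c(2L, 1L))
  expect_equal(ragged$mean, c(2, 5))
  expect_equal(ragged$sd[2], 0)

  single <- aggregate_runs(list(c(2, 2)))
  expect_equal(single$n, c(1L, 1L))
  expect_equal(single$sd, c(0, 0))
  expect_error(aggregate_runs(list()), "no runs")
})

test_that("wall-value mean averages exactly the impassable squares", {
  w <- pocket_world()
  vm <- matrix(0.8, 5, 5)
  vm[!w$passable] <- -0.5
  expect_equal(wall_value_mean(vm, w), -0.5)
  # changing passable cells leaves the statistic unchanged
  vm2 <- vm; vm2[w$passable] <- 99
  expect_equal(wall_value_mean(vm2, w), -0.5)
  # interior-only mask: the single interior wall at (3,2)
  vm[3, 2] <- -2
  expect_equal(wall_value_mean(vm, w, include_border = FALSE), -2)
  p_open <- matrix(FALSE, 5, 5)
  p_open[2:4, 2:4] <- TRUE
  all_open <- gridworld(p_open, c(2, 2),
                        tibble::tibble(x = 3, y = 3, reward = 1), 0)
  expect_error(wall_value_mean(matrix(0, 5, 5), all_open,
                               include_border = FALSE), "no wall")
})

test_that("value argmax scans all squares with deterministic tie-breaks", {
  w <- pocket_world()
  vm <- matrix(0, 5, 5)
  vm[4, 3] <- 1   # the goal
  am <- value_argmax(vm, w)
  expect_equal(am$distance_to_nearest_goal, 0)
  expect_equal(c(am$x, am$y), c(4L, 3L))

  vm2 <- matrix(0, 5, 5)
  vm2[5, 5] <- 2   # max at (5,5); nearest goal (4,3) -> distance 3
  expect_equal(value_argmax(vm2, w)$distance_to_nearest_goal, 3)

  uniform <- value_argmax(matrix(1, 5, 5), w)
  expect_equal(c(uniform$x, uniform$y), c(1L, 1L))

  # agreement with an exhaustive scan on random maps
  set.seed(901)
  for (rep in 1:10) {
    vm3 <- matrix(rnorm(25), 5, 5)
    am3 <- value_argmax(vm3, w)
    expect_equal(am3$max_value, max(vm3))
    expect_equal(vm3[am3$x, am3$y], max(vm3))
  }
})

test_that("value-map snapshots match each agent's representation", {
  w <- pocket_world()
  expect_equal(snapshot_value_map(tabular_agent(width = 5, height = 5)),
               matrix(0, 5, 5))
  tb <- tabular_update(tabular_agent(width = 5, height = 5), 3, 3, 1)
  expect_equal(sum(snapshot_value_map(tb) != 0), 1L)

  mp <- maxpain_agent(width = 5, height = 5)
  mp$v_r[2, 2] <- 0.4; mp$v_p[2, 2] <- 0.1
  expect_equal(snapshot_value_map(mp)[2, 2], 0.3)

  set.seed(902)
  net <- build_basis(basis_spec(theta = 1))
  ov <- ovarlap_update(ovarlap_agent(net), 10, 10, 1)
  sm <- snapshot_value_map(ov)
  expect_equal(dim(sm), c(20L, 20L))
  expect_gt(sum(sm > 1e-4), 1)   # smooth bump, not a single cell
  expect_equal(sm[10, 10], max(sm))
})

test_that("value maps export as north-up CSV grids", {
  vm <- matrix(seq_len(12) / 10, 3, 4)   # 3 wide, 4 tall
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_value_map(vm, path)
  grid <- as.matrix(utils::read.csv(path, header = FALSE))
  expect_equal(dim(grid), c(4L, 3L))
  expect_equal(unname(grid[1, ]), vm[, 4])   # first row = northernmost y
  expect_equal(unname(grid[4, ]), vm[, 1])
})
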