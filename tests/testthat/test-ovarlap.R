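test_that("channel values and state value are linear read-outs", {
  set.seed(601)
  net <- build_basis(basis_spec(theta = 1))
  ag <- ovarlap_agent(net)
  expect_equal(channel_values(ag, 5, 5), c(d1 = 0, d2 = 0))
  expect_equal(state_value(ag, 5, 5), 0)

  h <- hidden_activity(net, 5, 5)
  ag$w1[42] <- 1
  expect_equal(channel_values(ag, 5, 5)[["d1"]], h[42])
  ag$w1[42] <- 2
  expect_equal(channel_values(ag, 5, 5)[["d1"]], 2 * h[42])

  # antisymmetry: swapping the channels negates the value
  set.seed(602)
  ag$w1 <- runif(900); ag$w2 <- runif(900)
  swapped <- ag
  swapped$w1 <- ag$w2; swapped$w2 <- ag$w1
  expect_equal(state_value(swapped, 9, 14), -state_value(ag, 9, 14))
})

test_that("action values follow the afterstate convention", {
  w <- pocket_world()
  set.seed(603)
  net <- build_basis(basis_spec(theta = 1, width = 5, height = 5,
                                n_hidden = 50))
  ag <- ovarlap_agent(net)
  for (a in 1:4) expect_equal(action_value(ag, w, c(2, 3), a), 0)
  # a wall square with learned negative value yields q < 0
  ag <- ovarlap_update(ag, 3, 2, -1)
  expect_lt(action_value(ag, w, c(2, 2), 1L), 0)   # east points at wall (3,2)
  expect_equal(action_value(ag, w, c(2, 2), 1L), state_value(ag, 3, 2))
})

test_that("TD error arithmetic and terminal bootstrap", {
  expect_equal(td_error(1, 0.95, 0, 0, terminal = TRUE), 1)
  expect_equal(td_error(-1, 0.95, 0.5, 0.2), -0.725)
  expect_equal(td_error(0, 1, 3, 3), 0)
  # terminal drops the bootstrap even when q_next is nonzero
  expect_equal(td_error(2, 0.95, 99, 0.5, terminal = TRUE), 1.5)
})

test_that("updates are asymmetric, monotone and exactly incremental", {
  set.seed(604)
  net <- build_basis(basis_spec(theta = 1))
  ag <- ovarlap_agent(net, alpha1 = 0.1, alpha2 = 0.1)

  # positive error: only w1 moves; value moves by exactly alpha1 * delta
  ag1 <- ovarlap_update(ag, 10, 10, 1)
  expect_equal(state_value(ag1, 10, 10), 0.1, tolerance = 1e-12)
  expect_identical(ag1$w2, ag$w2)
  expect_true(all(ag1$w1 >= ag$w1))

  # negative error: only w2 moves; value moves by exactly alpha2 * delta
  ag2 <- ovarlap_update(ag1, 10, 10, -0.5)
  expect_identical(ag2$w1, ag1$w1)
  expect_equal(state_value(ag2, 10, 10) - state_value(ag1, 10, 10), -0.05,
               tolerance = 1e-12)
  expect_true(all(ag2$w2 >= ag1$w2))

  # delta = 0: no change; impaired (alpha2 = 0): negative errors are ignored
  expect_identical(ovarlap_update(ag2, 3, 3, 0), ag2)
  imp <- ovarlap_agent(net, alpha2 = 0)
  imp$w1 <- runif(900)
  imp2 <- ovarlap_update(imp, 7, 7, -2)
  expect_identical(imp2$w1, imp$w1)
  expect_identical(imp2$w2, imp$w2)
})

test_that("exact-increment contract holds for random bases, weights and errors", {
  set.seed(605)
  for (rep in 1:8) {
    theta <- runif(1, 0.4, 2.2)
    net <- build_basis(basis_spec(theta = theta))
    ag <- ovarlap_agent(net, alpha1 = runif(1, 0.01, 0.5),
                        alpha2 = runif(1, 0.01, 0.5))
    ag$w1 <- runif(900); ag$w2 <- runif(900)
    for (j in 1:15) {
      x <- sample(20, 1); y <- sample(20, 1)
      delta <- runif(1, -2, 2)
      before <- state_value(ag, x, y)
      ag <- ovarlap_update(ag, x, y, delta)
      target <- if (delta > 0) ag$alpha1 * delta else ag$alpha2 * delta
      expect_lt(abs(state_value(ag, x, y) - before - target), 1e-9)
    }
  }
})

test_that("a single positive update spreads as a generalization gradient", {
  set.seed(606)
  net <- build_basis(basis_spec(theta = 1))
  ag <- ovarlap_update(ovarlap_agent(net), 10, 10, 1)
  vm <- value_map(ag)
  expect_equal(vm[10, 10], 0.1, tolerance = 1e-12)
  expect_true(all(vm >= 0))
  # many squares affected (unlike a table), decaying outward
  expect_gt(sum(vm > 1e-4), 10)
  prof <- radial_value_profile(vm, c(10, 10), max_dist = 9)
  expect_gt(prof$mean_value[1], prof$mean_value[5])
  expect_gt(prof$mean_value[5], prof$mean_value[9])
})

test_that("engine updates agree with the R-level primitives", {
  w <- pocket_world()
  set.seed(607)
  net <- build_basis(basis_spec(theta = 1, width = 5, height = 5,
                                n_hidden = 50))
  # walk: north, east (wall hit), north, east, east (goal at (4,3))
  acts <- c(4L, 1L, 1L)
  eng <- run_steps(w, ovarlap_agent(net, gamma = 0.9),
                   forced_actions = acts, n_episodes = 1)

  ref <- ovarlap_agent(net, gamma = 0.9)
  s <- c(2, 2)
  for (i in seq_along(acts)[-length(acts)]) {
    tr <- gw_step(w, s, acts[i])
    q_cur <- state_value(ref, tr$intended_target[1], tr$intended_target[2])
    q_next <- action_value(ref, w, tr$next_state, acts[i + 1])
    delta <- td_error(tr$reward, 0.9, q_next, q_cur, tr$terminal)
    ref <- ovarlap_update(ref, tr$intended_target[1], tr$intended_target[2],
                          delta)
    s <- tr$next_state
  }
  tr <- gw_step(w, s, acts[length(acts)])
  delta <- td_error(tr$reward, 0.9, 0,
                    state_value(ref, tr$intended_target[1],
                                tr$intended_target[2]), tr$terminal)
  ref <- ovarlap_update(ref, tr$intended_target[1], tr$intended_target[2],
                        delta)
  expect_true(tr$terminal)
  expect_equal(eng$agent$w1, ref$w1, tolerance = 1e-12)
  expect_equal(eng$agent$w2, ref$w2, tolerance = 1e-12)
})
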