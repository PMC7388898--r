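test_that("receptive-field centres follow the linear tiling rule", {
  ctr <- basis_centers(900, 20, 20)
  expect_equal(unlist(ctr[ctr$k == 1, c("a", "b")]), c(a = 1, b = 1))
  expect_equal(unlist(ctr[ctr$k == 450, c("a", "b")]), c(a = 10, b = 20))
  expect_equal(unlist(ctr[ctr$k == 900, c("a", "b")]), c(a = 20, b = 20))
  expect_true(all(ctr$a >= 1 & ctr$a <= 20))
  expect_true(all(ctr$b >= 1 & ctr$b <= 20))
})

test_that("one-hot encoding has a single unit mass at the position", {
  I <- encode_position(1, 1)
  expect_equal(I[1, 1], 1)
  expect_equal(sum(I), 1)
  I2 <- encode_position(20, 20)
  expect_equal(I2[20, 20], 1)
  expect_equal(sum(I2 != 0), 1)
  expect_error(encode_position(0, 5), "outside")
  expect_error(encode_position(5, 21), "outside")
})

test_that("variance sampling matches the log-normal law", {
  set.seed(401)
  v <- sample_variances(theta = 1, n_hidden = 40000)
  expect_true(all(v > 0))
  # median of LogN(location, scale) is exp(location) = exp(-0.7)
  expect_equal(median(v), exp(-0.7), tolerance = 0.02)
  expect_equal(sd(log(v)), 0.7, tolerance = 0.02)
  # larger theta -> wider spread of log-variances
  set.seed(402)
  wide <- sample_variances(theta = 2.2, n_hidden = 20000)
  narrow <- sample_variances(theta = 0.44, n_hidden = 20000)
  expect_gt(sd(log(wide)), sd(log(narrow)))
  expect_error(sample_variances(0), "theta")
})

test_that("frozen connection noise is sparse Bernoulli", {
  expect_equal(sample_noise(0, 0.5), matrix(0, 400, 900))
  expect_true(all(sample_noise(2, 1) == 2))
  set.seed(403)
  eps <- sample_noise(1, 0.005)
  frac <- mean(eps != 0)
  # binomial tolerance over 360,000 entries: 5 sds of sqrt(p(1-p)/n)
  expect_lt(abs(frac - 0.005), 5 * sqrt(0.005 * 0.995 / 360000))
  expect_true(all(eps %in% c(0, 1)))
  expect_error(sample_noise(1, 1.5), "rho")
})

test_that("connection table evaluates the Gaussian formula", {
  spec <- basis_spec(theta = 1)
  net <- build_basis(spec, variances = rep(0.5, 900))
  ctr <- net$centers
  for (k in c(1, 333, 900)) {
    at_center <- hidden_activity(net, ctr$a[k], ctr$b[k])[k]
    expect_equal(at_center, 1 / 400)
    if (ctr$a[k] < 20) {
      off <- hidden_activity(net, ctr$a[k] + 1, ctr$b[k])[k]
      expect_equal(off, exp(-1) / 400)
    }
  }
  # noiseless entries lie in (0, 1/D]; column max at the centre
  expect_true(all(net$M > 0 & net$M <= 1 / 400))
  for (k in c(7, 450)) {
    p_star <- which.max(net$M[, k])
    expect_equal(p_star, 20 * (ctr$a[k] - 1) + ctr$b[k])
  }
  # additive noise raises exactly the noised cells by A/D
  eps <- matrix(0, 400, 900)
  eps[37, 12] <- 2
  noisy <- build_basis(spec, variances = rep(0.5, 900), noise = eps)
  expect_equal(noisy$M[37, 12] - net$M[37, 12], 2 / 400)
  expect_equal(noisy$M[-37, ], net$M[-37, ])
})

test_that("hidden activity is the table row / matrix-product identity", {
  set.seed(404)
  net <- build_basis(basis_spec(theta = 1))
  h <- hidden_activity(net, 7, 13)
  expect_equal(h, net$M[20 * (7 - 1) + 13, ])
  # Gaussian responses are nonnegative everywhere and positive for the
  # units whose receptive fields cover the position (far tails can
  # underflow to zero in double precision)
  expect_true(all(h >= 0))
  expect_gt(sum(h > 0), 100)
  prod_form <- as.numeric(t(net$M) %*% as.vector(t(encode_position(7, 13))))
  expect_equal(prod_form, unname(h))
  expect_gt(sum(h^2), 0)
})

test_that("activity similarity decays with distance, and building is reproducible", {
  near <- numeric(0); far <- numeric(0)
  for (s in 1:10) {
    set.seed(500 + s)
    net <- build_basis(basis_spec(theta = 1))
    h0 <- hidden_activity(net, 10, 10)
    near <- c(near, cor(h0, hidden_activity(net, 12, 10)))
    far <- c(far, cor(h0, hidden_activity(net, 16, 10)))
  }
  expect_gt(mean(near), mean(far))
  set.seed(511)
  a <- build_basis(basis_spec(theta = 1.5))
  set.seed(511)
  b <- build_basis(basis_spec(theta = 1.5))
  expect_identical(a$M, b$M)
})
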