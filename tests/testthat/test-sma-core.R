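test_that("control parameters follow the arctanh / linear decay schedule", {
  expect_equal(unname(compute_control_params(100, 100)), c(0, 0))
  expect_equal(unname(compute_control_params(50, 100)),
               c(atanh(0.5), 0.5))
  expect_equal(unname(compute_control_params(1, 1)), c(0, 0))
  # t clamped below 1 and above max_t
  expect_equal(compute_control_params(0, 10), compute_control_params(1, 10))
})

test_that("decision parameter p saturates with the fitness gap", {
  expect_equal(compute_p(3, 3), 0)
  expect_equal(compute_p(1, 0), tanh(1))
  expect_lt(compute_p(17, 0), 1)
  expect_gt(compute_p(17, 0), 1 - 1e-12)
  # double-precision saturation for huge gaps
  expect_equal(compute_p(1e6, 0), 1)
})

test_that("weights split around 1 by fitness rank", {
  # two agents, forced r = 1: best-half weight 1 + log10(1) = 1,
  # worse-half 1 - log10(2)
  w <- compute_weights(c(0, 1), dim = 1, r = matrix(1, 2, 1))
  expect_equal(w[1, 1], 1)
  expect_equal(w[2, 1], 1 - log10(2))

  # degenerate all-equal fitness: unit weights
  w0 <- compute_weights(rep(2.5, 6), dim = 3, r = matrix(1, 6, 3))
  expect_equal(w0, matrix(1, 6, 3))

  # property: better half >= 1 >= worse half, for random fitness vectors
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    f <- sort(rnorm(n))
    W <- compute_weights(f, dim = 5)
    half <- seq_len(floor(n / 2))
    expect_true(all(W[half, ] >= 1))
    expect_true(all(W[-half, ] <= 1))
  }
})

test_that("weights stay finite when the fitness spread collapses to eps scale", {
  f <- c(0, 0, 2.2e-16, 2.3e-16)
  W <- compute_weights(f, dim = 2)
  expect_true(all(is.finite(W)))
})

test_that("position update matches an independent replay of the update rule", {
  # dim 1, 2 agents: replay the exact draw sequence and recompute by hand
  X <- matrix(c(2, -3), 2, 1)
  fitness <- c(4, 9)
  W <- matrix(c(1.2, 0.8), 2, 1)
  Xb <- matrix(1.5, 1, 1)
  DF <- 4
  a <- 0.6
  b <- 0.4
  z <- 0.03
  set.seed(42)
  got <- sma_position_update(X, fitness, W, c(1.5), DF, a, b, z, -5, 5)

  set.seed(42)
  want <- X
  for (i in 1:2) {
    if (runif(1) < z) {
      want[i, ] <- -5 + runif(1) * 10
    } else {
      p <- tanh(abs(fitness[i] - DF))
      vb <- runif(1, -a, a)
      vc <- runif(1, -b, b)
      r <- runif(1)
      A <- sample.int(2, 1, replace = TRUE)
      B <- sample.int(2, 1, replace = TRUE)
      want[i, ] <- if (r < p) 1.5 + vb * (W[i, ] * X[A, ] - X[B, ]) else
        vc * X[i, ]
    }
  }
  want <- pmin(pmax(want, -5), 5)
  expect_equal(got, want)
})

test_that("update output is always inside the bounds", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 8
    d <- 4
    X <- matrix(runif(n * d, -2, 2), n, d)
    fit <- apply(X, 1, sphere)
    W <- compute_weights(sort(fit), d)
    out <- sma_position_update(X, fit, W, X[which.min(fit), ], min(fit),
                               a = 3, b = 0.9, z = 0.2, lower = -2,
                               upper = 2)
    expect_true(all(out >= -2 & out <= 2))
  }
})

test_that("runs are budget-exact, monotone and seed-reproducible", {
  cfg <- optimizer_config(pop_size = 8, max_evals = 500, dim = 3,
                          lower = -10, upper = 10, seed = 4,
                          log_evals = TRUE)
  res <- run_sma(sphere, cfg)
  expect_lte(res$n_evals, 500)
  expect_gte(res$n_evals, 500 - 8)
  # best-so-far equals the minimum over every evaluation ever made
  expect_identical(res$best_fitness, min(res$eval_log))
  expect_true(all(diff(res$trace$best_fitness) <= 0))
  expect_true(all(res$population >= -10 & res$population <= 10))
  expect_equal(res$best_fitness, sphere(res$best_position))

  res2 <- run_sma(sphere, cfg)
  expect_identical(res$trace, res2$trace)
  expect_identical(res$best_position, res2$best_position)
})

test_that("a budget below one generation is rejected", {
  cfg <- optimizer_config(pop_size = 30, max_evals = 45, dim = 2,
                          lower = -1, upper = 1)
  expect_error(run_sma(sphere, cfg), "at least")
  expect_error(optimizer_config(pop_size = 30, max_evals = 10), "max_evals")
})

test_that("config invariants are enforced", {
  expect_error(optimizer_config(z = 0), "z")
  expect_error(optimizer_config(z = 1.2), "z")
  expect_error(optimizer_config(pop_size = 1), "pop_size")
  expect_error(optimizer_config(lower = 2, upper = 1), "upper bound")
})
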