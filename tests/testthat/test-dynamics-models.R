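lpa_fitted <- c(b = 6.598, cel = 1.209e-2, cea = 1.155e-2, cpa = 0.35,
                mul = 0.2055, mua = 0.96)

test_that("Lorenz-63 vector field matches direct substitution and its equilibria", {
  p <- c(sigma = 10, rho = 28, beta = 8 / 3)
  expect_equal(lorenz63_rhs(c(0, 0, 0), p), c(0, 0, 0))
  fp <- c(sqrt(p["beta"] * (p["rho"] - 1)), sqrt(p["beta"] * (p["rho"] - 1)),
          p["rho"] - 1)
  expect_equal(lorenz63_rhs(unname(fp), p), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(lorenz63_rhs(c(1, 2, 3), p), c(10, 23, -6))
})

test_that("Hindmarsh-Rose field: uncoupled neuron, gating saturation and bound", {
  net1 <- network_spec(1, matrix(0, 1, 1))
  expect_equal(hindmarsh_rose_rhs(c(0, 0, 0), list(a = 1, b = 3, c = 5), net1),
               c(1.2, 1, 0.017))
  # two neurons, connection 2 <- 1 with strength beta
  a2 <- matrix(0, 2, 2); a2[2, 1] <- 0.7
  net2 <- network_spec(2, a2)
  base <- hindmarsh_rose_rhs(c(0, 0, 0, 0, 0, 0), list(a = 1, b = 3, c = 5),
                             network_spec(2, matrix(0, 2, 2)))
  # presynaptic voltage deep below threshold: gating kills the coupling
  st <- c(-10, 0, 0, 0, 0, 0)
  with_c <- hindmarsh_rose_rhs(st, list(a = 1, b = 3, c = 5), net2)
  no_c <- hindmarsh_rose_rhs(st, list(a = 1, b = 3, c = 5),
                             network_spec(2, matrix(0, 2, 2)))
  expect_lt(abs(with_c[4] - no_c[4]), 1e-4 * 0.7)
  # presynaptic voltage exactly zero: coupling exactly zero
  expect_equal(with_c[1:3], no_c[1:3])
  st0 <- c(0, 0, 0, 1, 1, 1)
  expect_identical(hindmarsh_rose_rhs(st0, list(a = 1, b = 3, c = 5), net2)[4],
                   hindmarsh_rose_rhs(st0, list(a = 1, b = 3, c = 5),
                                      network_spec(2, matrix(0, 2, 2)))[4])
  # |beta * g(x)| <= beta * |x| for the sigmoidal gating
  for (x in seq(-20, 20, length.out = 41)) {
    g <- x / (1 + 9 * exp(-10 * x))
    expect_lte(abs(0.7 * g), 0.7 * abs(x) + 1e-14)
  }
  expect_error(hindmarsh_rose_rhs(c(0, 0, 0), list(a = 1, b = 3, c = 5), net2),
               "3 \\* network size")
})

test_that("LPA map matches hand-computed census steps and rejects bad input", {
  expect_equal(lpa_step(c(0, 0, 0), lpa_fitted), c(0, 0, 0))
  expect_equal(lpa_step(c(10, 5, 0), lpa_fitted), c(0, 7.945, 5))
  # frozen value from an independent direct-substitution evaluation
  expect_equal(lpa_step(c(100, 50, 100), lpa_fitted),
               c(62.0497671357138, 79.45, 4.0), tolerance = 1e-12)
  expect_error(lpa_step(c(-1, 5, 5), lpa_fitted), "nonnegative")
  bad <- lpa_fitted; bad["mul"] <- 1.4
  expect_error(lpa_step(c(1, 1, 1), bad), "mortality")
})

test_that("LPA map preserves nonnegativity on random nonnegative input", {
  set.seed(11)
  for (i in 1:50) {
    pop <- runif(3, 0, 500)
    p <- c(b = runif(1, 0, 10), cel = runif(1, 0, 0.1), cea = runif(1, 0, 0.1),
           cpa = runif(1, 0, 1), mul = runif(1), mua = runif(1))
    expect_true(all(lpa_step(pop, p) >= 0))
  }
})

test_that("integrator reproduces closed forms and reports blow-ups", {
  still <- model_spec("still", "x", "k", c(k = 0), "continuous",
                      function(t, X, P) 0 * X, obs_names = "x",
                      sample_interval = 0.1, state_deps = list(x = "x"),
                      param_deps = list(x = "k"))
  tr <- integrate_model(still, 2.5, n_steps = 20)
  expect_true(all(tr$values == 2.5))

  dec <- model_spec("decay", "x", "k", c(k = 1), "continuous",
                    function(t, X, P) -P[1, ] * X, obs_names = "x",
                    sample_interval = 0.05, state_deps = list(x = "x"),
                    param_deps = list(x = "k"))
  tr <- integrate_model(dec, 1, n_steps = 101)
  expect_lt(max(abs(tr$values[, 1] - exp(-tr$times))), 1e-6)

  blow <- model_spec("blow", "x", "k", c(k = 1), "continuous",
                     function(t, X, P) X^2, obs_names = "x",
                     sample_interval = 0.5, state_deps = list(x = "x"),
                     param_deps = list(x = "k"))
  expect_error(integrate_model(blow, 10, n_steps = 50), "step [0-9]+")
})

test_that("Lorenz integration at the default refinement agrees with a 20x finer one", {
  m <- get_model("lorenz63")
  x0 <- c(1.2, 3.4, 15.0)
  tr <- integrate_model(m, x0, n_steps = 21)     # one time unit
  m_fine <- m
  m_fine$substeps <- m$substeps * 20L
  ref <- integrate_model(m_fine, x0, n_steps = 21)
  expect_lt(max(abs(tr$values - ref$values)), 1e-3)
})

test_that("integrator error drops at least 8-fold when the step is halved", {
  dec <- model_spec("decay", "x", "k", c(k = 1), "continuous",
                    function(t, X, P) -P[1, ] * X, obs_names = "x",
                    sample_interval = 0.2, state_deps = list(x = "x"),
                    param_deps = list(x = "k"))
  err <- sapply(c(0.2, 0.1), function(h) {
    n <- round(2 / h) + 1
    tr <- integrate_model(dec, 1, n_steps = n, h = h)
    abs(tr$values[n, 1] - exp(-2))
  })
  expect_gt(err[1] / err[2], 8)
})

test_that("training data: span, noise injection, reproducibility", {
  m <- get_model("lorenz63")
  td <- generate_training_data(m, 500, 0, seed = 99)
  expect_equal(diff(range(td$clean$times)), 499 * 0.05)  # ~25 time units
  expect_identical(td$clean$values, td$noisy$values)     # zero noise

  td1 <- generate_training_data(m, 100, 4, seed = 123)
  td2 <- generate_training_data(m, 100, 4, seed = 123)
  expect_identical(td1$noisy$values, td2$noisy$values)   # bit-identical

  # law of large numbers on the injected noise variance (1e5 draws; a cheap
  # linear system keeps the check fast, the noise path is model-independent)
  dec <- model_spec("decay", "x", "k", c(k = 1e-3), "continuous",
                    function(t, X, P) -P[1, ] * X, obs_names = "x",
                    sample_interval = 0.05, state_deps = list(x = "x"),
                    param_deps = list(x = "k"),
                    ic_sampler = function() stats::runif(1))
  big <- generate_training_data(dec, 1e5, 4, seed = 7, burn_in = 10)
  v <- stats::var(big$noisy$values[, 1] - big$clean$values[, 1])
  expect_lt(abs(v - 4) / 4, 0.05)
})
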