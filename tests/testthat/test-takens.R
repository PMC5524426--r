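test_that("delay library unrolls the definition and counts rows correctly", {
  lib <- build_delay_library(c(1, 2, 3, 4, 5), embedding_config(d = 2, tau = 1,
                                                                kappa = 1),
                             max_lead = 1)
  expect_equal(lib$vectors,
               matrix(c(3, 2, 1, 4, 3, 2, 5, 4, 3), 3, byrow = TRUE))
  expect_equal(lib$futures[, 1], c(4, 5, NA))
  expect_equal(lib$source_times, 3:5)

  # d = 0: the vectors are the scalar samples themselves
  lib0 <- build_delay_library(c(7, 8, 9), embedding_config(d = 0, kappa = 1),
                              max_lead = 1)
  expect_equal(drop(lib0$vectors), c(7, 8, 9))

  # length-500 series, d = 9, tau = 1: 491 rows
  lib500 <- build_delay_library(rnorm(500), embedding_config(d = 9, kappa = 1),
                                max_lead = 2)
  expect_equal(nrow(lib500$vectors), 491)
  expect_error(build_delay_library(rnorm(10), embedding_config(d = 9, kappa = 1)),
               "too short")
})

test_that("stored vectors and futures are consistent with the source series", {
  set.seed(3)
  s <- cumsum(rnorm(120))
  for (tau in c(1, 3)) {
    cfg <- embedding_config(d = 4, tau = tau, kappa = 2)
    lib <- build_delay_library(s, cfg, max_lead = 3)
    for (r in seq_len(nrow(lib$vectors))) {
      t <- lib$source_times[r]
      expect_equal(lib$vectors[r, ], s[t - (0:4) * tau])
      for (lead in 1:3)
        if (t + lead <= length(s))
          expect_equal(lib$futures[r, lead], s[t + lead])
        else expect_true(is.na(lib$futures[r, lead]))
    }
  }
})

test_that("k-NN engine agrees with the exhaustive-scan oracle", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(30:80, 1)
    d <- sample(0:3, 1)
    kappa <- sample(1:5, 1)
    s <- as.numeric(arima.sim(list(ar = 0.8), n))
    cfg <- embedding_config(d = d, tau = 1, kappa = kappa)
    lib <- build_delay_library(s, cfg, max_lead = 1)
    q <- rnorm(d + 1, sd = 2)
    nn <- nearest_neighbors(q, lib)
    eligible <- is.finite(lib$futures[, 1])
    expect_identical(as.integer(nn$indices),
                     as.integer(brute_knn(q, lib$vectors, kappa, eligible)))
    # prediction is the (uniform) average of the oracle neighbours' futures
    expect_equal(local_constant_predict(q, lib),
                 mean(lib$futures[brute_knn(q, lib$vectors, kappa, eligible), 1]))
  }
})

test_that("distance ties break toward the earlier source time", {
  s <- c(1, 2, 1, 2, 1, 2, 1, 2)       # every delay vector repeats
  cfg <- embedding_config(d = 1, tau = 1, kappa = 2)
  lib <- build_delay_library(s, cfg, max_lead = 1)
  nn <- nearest_neighbors(c(2, 1), lib)
  expect_equal(nn$dists, c(0, 0))
  expect_equal(nn$indices, c(1, 3))     # earliest matching rows
})

test_that("local-constant prediction stays inside the neighbour-future hull", {
  set.seed(9)
  s <- sin(seq(0, 20, 0.1)) + rnorm(201, 0, 0.1)
  cfg <- embedding_config(d = 3, tau = 1, kappa = 7)
  lib <- build_delay_library(s, cfg, max_lead = 1)
  for (i in 1:30) {
    q <- rnorm(4)
    nn <- nearest_neighbors(q, lib)
    p <- local_constant_predict(q, lib)
    f <- lib$futures[nn$indices, 1]
    expect_gte(p, min(f) - 1e-12)
    expect_lte(p, max(f) + 1e-12)
  }
  # kappa = 1: exactly the nearest row's future
  cfg1 <- embedding_config(d = 3, tau = 1, kappa = 1)
  lib1 <- build_delay_library(s, cfg1, max_lead = 1)
  q <- s[100 - 0:3]
  nn1 <- nearest_neighbors(q, lib1)
  expect_identical(local_constant_predict(q, lib1),
                   lib1$futures[nn1$indices[1], 1])
})

test_that("inverse-distance weights are normalized and favour closer rows", {
  set.seed(10)
  s <- rnorm(60)
  cfg <- embedding_config(d = 1, tau = 1, kappa = 4,
                          weighting = "inverse_distance")
  lib <- build_delay_library(s, cfg, max_lead = 1)
  nn <- nearest_neighbors(rnorm(2), lib)
  expect_equal(sum(nn$weights), 1)
  expect_true(all(diff(nn$weights) <= 1e-12))   # sorted by distance
})

test_that("direct prediction: constant series, periodicity, lead-1 equivalence", {
  cfgc <- embedding_config(d = 2, tau = 1, kappa = 3)
  expect_equal(direct_forecast(rep(5, 50), cfgc, 8), rep(5, 8))

  # exactly periodic series with kappa = 1 reproduces the cycle
  s <- rep(c(0, 1, 3, 2, -1), 20)
  cfg1 <- embedding_config(d = 4, tau = 1, kappa = 1)
  fc <- direct_forecast(s, cfg1, 10)
  expect_equal(fc, rep(c(0, 1, 3, 2, -1), 4)[1:10])

  # horizon-1 direct forecast = lead-1 local-constant prediction from the
  # terminal delay vector
  set.seed(2)
  s2 <- as.numeric(arima.sim(list(ar = 0.9), 150))
  cfg <- embedding_config(d = 3, tau = 1, kappa = 5)
  lib <- build_delay_library(s2, cfg, max_lead = 1)
  q <- s2[150 - 0:3]
  expect_equal(direct_forecast(s2, cfg, 1),
               local_constant_predict(q, lib, lead = 1))
})

test_that("Kalman-Takens denoiser: shape, idempotence on clean input", {
  fix <- lorenz_fixture(n = 300, noise_variance = 0, seed = 61)
  x <- fix$clean$values[, "x"]
  cfg <- embedding_config(d = 9, tau = 1, kappa = 20)
  # on noise-free data the observations deserve full trust (small r) while
  # the neighbour predictor still carries its O(1) local-spread error (q)
  den <- kalman_takens_denoise(x, cfg, q = 1, r = 0.01)
  expect_length(den, length(x))
  expect_lt(sqrt(mean((den - x)^2)) / sqrt(mean(x^2)), 0.05)
  # multivariate input: column-wise, same shape
  m2 <- cbind(a = x, b = rev(x))
  den2 <- kalman_takens_denoise(m2, cfg, q = 1, r = 0.01)
  expect_equal(dim(den2), dim(m2))
})

test_that("denoiser reduces noise on a noisy chaotic series", {
  fix <- lorenz_fixture(n = 300, noise_variance = 4, seed = 62)
  x <- fix$noisy$values[, "x"]
  truth <- fix$clean$values[, "x"]
  den <- kalman_takens_denoise(x, embedding_config(d = 9, tau = 1, kappa = 20),
                               r = 4)
  expect_lt(sqrt(mean((den - truth)^2)), sqrt(mean((x - truth)^2)))
})

test_that("cross-validated embedding selection is sane and deterministic", {
  cfg1 <- select_embedding_cv(sin(seq(0, 30, 0.2)), 2, 3, 4)
  expect_equal(c(cfg1$d, cfg1$tau, cfg1$kappa), c(2, 3, 4))  # singleton grids

  s <- sin(seq(0, 60, 0.25))
  sel <- select_embedding_cv(s, 1:3, 1:5, 1:5, horizon = 10)
  expect_lt(attr(sel, "score"), 0.05)
  sel2 <- select_embedding_cv(s, 1:3, 1:5, 1:5, horizon = 10)
  expect_identical(unclass(sel)[c("d", "tau", "kappa")],
                   unclass(sel2)[c("d", "tau", "kappa")])
  expect_error(select_embedding_cv(s[1:8], 5:6, 3:4, 2, horizon = 5),
               "no feasible embedding")
})
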