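lorenz_emb <- embedding_config(d = 9, tau = 1, kappa = 20)

test_that("hybrid specification: retained parameters and equation pruning", {
  m <- get_model("lorenz63")
  s1 <- make_hybrid_spec(m, "y", lorenz_emb)
  expect_setequal(s1$retained_params, c("sigma", "beta"))   # rho dropped
  expect_setequal(s1$mechanistic_vars, c("x", "z"))

  s2 <- make_hybrid_spec(m, c("y", "z"), lorenz_emb)
  expect_equal(s2$retained_params, "sigma")
  expect_equal(s2$mechanistic_vars, "x")

  s0 <- make_hybrid_spec(m, character(0), lorenz_emb)
  expect_setequal(s0$mechanistic_vars, c("x", "y", "z"))
  expect_setequal(s0$retained_params, c("sigma", "rho", "beta"))

  expect_error(make_hybrid_spec(m, c("x", "y", "z")), "proper subset")

  # unobserved variables cannot be replaced; unobserved equations that no
  # retained equation references are pruned from the hybrid state
  set.seed(1)
  hr <- get_model("hindmarsh_rose")
  expect_error(make_hybrid_spec(hr, "y1"), "observed")
  s3 <- make_hybrid_spec(hr, c("x1", "x2"),
                         embedding_config(d = 9, tau = 1, kappa = 10))
  expect_setequal(s3$mechanistic_vars, c("x3", "y3", "z3"))
  expect_setequal(s3$retained_params, c("a3", "b3", "c3", "beta3_1", "beta3_2"))

  # LPA: replacing larvae keeps the pupae/adult equations, estimable
  # parameters among the retained set reduce to the larval survival
  lpa <- get_model("lpa")
  s4 <- make_hybrid_spec(lpa, "L", embedding_config(d = 2, tau = 1, kappa = 5))
  expect_setequal(s4$mechanistic_vars, c("P", "A"))
  expect_setequal(s4$retained_params, c("mul", "cpa", "mua"))
  expect_equal(intersect(s4$retained_params, c("b", "cel", "cea", "mul")), "mul")
})

test_that("hybrid state dimension follows the layout formula", {
  m <- get_model("lorenz63")
  for (repl in list("y", c("y", "z"))) {
    spec <- make_hybrid_spec(m, repl, lorenz_emb)
    est <- spec$retained_params
    lay <- hybridcast:::hybrid_layout(spec, est)
    expect_equal(lay$dim,
                 length(spec$mechanistic_vars) + length(repl) * 10 + length(est))
  }
})

test_that("advancing with an exact noise-free library reproduces the truth", {
  m <- get_model("lorenz63")
  td <- generate_training_data(m, 520, 0, seed = 9)
  v <- td$clean$values
  emb1 <- embedding_config(d = 9, tau = 1, kappa = 1)
  spec <- make_hybrid_spec(m, "y", emb1)
  libs <- list(y = build_delay_library(v[1:500, "y"], emb1, max_lead = 1))
  k <- 300
  hs <- c(v[k, "x"], v[k, "z"], v[k - 0:9, "y"])
  adv <- hybrid_advance(hs, spec, libs, params = m$true_params)
  expect_identical(unname(adv[3]), unname(v[k + 1, "y"]))  # exact library, kappa = 1
  expect_equal(unname(adv[4:12]), unname(v[k - 0:8, "y"])) # lags shifted one slot
})

test_that("LPA hybrid advances pupae and adults by the retained map lines", {
  m <- get_model("lpa")
  emb <- embedding_config(d = 2, tau = 1, kappa = 1)
  spec <- make_hybrid_spec(m, "L", emb)
  set.seed(4)
  td <- generate_training_data(m, 30, 0, seed = 4, burn_in = 0)
  v <- td$clean$values
  libs <- list(L = build_delay_library(v[, "L"], emb, max_lead = 1))
  k <- 10
  hs <- c(v[k, "P"], v[k, "A"], v[k - 0:2, "L"])
  adv <- hybrid_advance(hs, spec, libs, params = m$true_params)
  p <- m$true_params
  expect_equal(adv[1], v[k, "L"] * (1 - p["mul"]), ignore_attr = TRUE)
  expect_equal(adv[2],
               v[k, "P"] * exp(-p["cpa"] * v[k, "A"]) + v[k, "A"] * (1 - p["mua"]),
               ignore_attr = TRUE)
})

test_that("degenerate hybrid (nothing replaced) equals the parametric engine", {
  m <- get_model("lorenz63")
  td <- generate_training_data(m, 120, 4, seed = 14)
  spec <- make_hybrid_spec(m, character(0), lorenz_emb)
  init <- m$true_params
  init[] <- draw_initial_parameters(m$true_params, 0.2, seed = 140)
  hfit <- run_hybrid_ukf(td$noisy, spec, init,
                         estimate_params = c("sigma", "rho", "beta"),
                         noise_variance = 4, uncertainty = 0.2)
  pfit <- run_joint_ukf(td$noisy, m, c("sigma", "rho", "beta"), init,
                        noise_variance = 4, uncertainty = 0.2)
  expect_equal(unname(hfit$estimates[c("sigma", "rho", "beta")]),
               unname(pfit$params[c("sigma", "rho", "beta")]),
               tolerance = 1e-9)
  fc_h <- hybrid_forecast(hfit, 10)
  fc_p <- parametric_forecast(m, pfit$state, pfit$params, 10)
  expect_equal(unname(fc_h), unname(fc_p[, colnames(fc_h)]), tolerance = 1e-9)
})

test_that("hybrid filter state dimension matches the layout during a run", {
  m <- get_model("lorenz63")
  td <- generate_training_data(m, 80, 4, seed = 15)
  spec <- make_hybrid_spec(m, "y", lorenz_emb)
  fit <- run_hybrid_ukf(td$noisy, spec, m$true_params,
                        noise_variance = 4, uncertainty = 0.1)
  lay <- hybridcast:::hybrid_layout(spec, spec$retained_params)
  expect_length(fit$belief$mean, lay$dim)
  expect_equal(dim(fit$belief$cov), c(lay$dim, lay$dim))
})

test_that("hybrid lead-1 forecast of a replaced variable matches the standalone predictor", {
  m <- get_model("lorenz63")
  td <- generate_training_data(m, 200, 4, seed = 16)
  spec <- make_hybrid_spec(m, "y", lorenz_emb)
  fit <- run_hybrid_ukf(td$noisy, spec, m$true_params,
                        noise_variance = 4, uncertainty = 0.1)
  fc <- hybrid_forecast(fit, 3)
  # the same delay vector queried against the same library gives the same
  # lead-1 value as the standalone local-constant predictor
  q <- fit$belief$mean[3:12]
  expect_equal(fc[1, "y"],
               local_constant_predict(q, fit$libs$y, lead = 1),
               ignore_attr = TRUE)
})

test_that("a blown-up forecast is flagged and padded with the last finite value", {
  m <- get_model("lorenz63")
  td <- generate_training_data(m, 200, 4, seed = 17)
  spec <- make_hybrid_spec(m, "y", lorenz_emb)
  fit <- run_hybrid_ukf(td$noisy, spec, m$true_params,
                        noise_variance = 4, uncertainty = 0.1)
  bad <- fit
  # the estimated parameters ride in the state vector: position 13 is sigma
  bad$belief$mean[13] <- 1e12           # geometric overflow in the map
  expect_warning(fc <- hybrid_forecast(bad, 40), "blew up")
  expect_false(is.null(attr(fc, "diverged_at")))
  expect_true(all(is.finite(fc[nrow(fc), ]) | is.na(fc[nrow(fc), ])))
})
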