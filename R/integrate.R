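#' Single fourth-order Runge-Kutta step
#'
#' Advances an ensemble of states one step of size `h`. Used to bootstrap the
#' multistep integrator and to propagate sigma points inside the filter,
#' where no step history is available.
#'
#' @param dynamics vectorised dynamics function `function(t, X, P)`.
#' @param t current time.
#' @param X state matrix (`n_state x E`) or vector.
#' @param P parameter matrix (`n_param x E`) or vector.
#' @param h step size.
#' @return advanced states, same shape as `X`.
#' @export
rk4_step <- function(dynamics, t, X, P, h) {
  k1 <- dynamics(t, X, P)
  k2 <- dynamics(t + h / 2, X + (h / 2) * k1, P)
  k3 <- dynamics(t + h / 2, X + (h / 2) * k2, P)
  k4 <- dynamics(t + h, X + h * k3, P)
  X + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
}

# Advance one sample interval: RK4 (subdivided by model$substeps) for
# continuous models, one application of the map for discrete models.
# X, P are matrices (columns = ensemble).
advance_model <- function(model, t, X, P, h = model$sample_interval) {
  if (model$kind == "discrete") return(model$dynamics(t, X, P))
  ns <- max(1L, model$substeps)
  hi <- h / ns
  for (i in seq_len(ns)) {
    X <- rk4_step(model$dynamics, t, X, P, hi)
    t <- t + hi
  }
  X
}

#' Integrate a model over a uniform grid
#'
#' Continuous models are integrated with a fourth-order Adams-Moulton
#' predictor-corrector (Adams-Bashforth-4 predictor, Adams-Moulton-4
#' corrector, re-evaluating the derivative at the corrected point),
#' bootstrapped with three Runge-Kutta-4 steps. The integration step is the
#' sample interval divided by the model's `substeps`, and every
#' `substeps`-th point is recorded, so the sampling rate of the data and
#' the accuracy of the integration are controlled separately. Discrete
#' models iterate their map once per sample. The returned trajectory has
#' `n_steps` rows, the first of which is `x0`.
#'
#' @param model a [model_spec()].
#' @param x0 initial state.
#' @param params parameter vector (defaults to the model's true values).
#' @param n_steps number of samples to return (including the initial state).
#' @param h sample interval; defaults to the model's.
#' @param t0 time of the first sample.
#' @return A [trajectory()].
#' @export
integrate_model <- function(model, x0, params = model$true_params,
                            n_steps, h = model$sample_interval, t0 = 0) {
  n <- length(model$state_names)
  stopifnot(length(x0) == n, n_steps >= 1)
  P <- matrix(as.numeric(params[model$param_names]), ncol = 1)
  if (anyNA(P)) P <- matrix(as.numeric(params), ncol = 1)
  out <- matrix(NA_real_, n_steps, n)
  out[1, ] <- as.numeric(x0)
  X <- matrix(as.numeric(x0), ncol = 1)
  if (model$kind == "discrete") {
    for (k in seq_len(n_steps - 1L)) {
      X <- model$dynamics(t0 + (k - 1) * h, X, P)
      .check_finite(X, k)
      out[k + 1L, ] <- X
    }
  } else {
    f <- model$dynamics
    ns <- max(1L, model$substeps)
    hi <- h / ns
    n_fine <- (n_steps - 1L) * ns
    fh <- vector("list", 4)            # derivative history, newest last
    fh[[1]] <- f(t0, X, P)
    k <- 1L
    while (k <= n_fine) {
      t <- t0 + (k - 1) * hi
      if (k <= 3L) {
        X <- rk4_step(f, t, X, P, hi)
        fh[[k + 1L]] <- f(t + hi, X, P)
      } else {
        # AB4 predict, evaluate, AM4 correct, evaluate
        pred <- X + (hi / 24) * (55 * fh[[4]] - 59 * fh[[3]] +
                                 37 * fh[[2]] - 9 * fh[[1]])
        fp <- f(t + hi, pred, P)
        X <- X + (hi / 24) * (9 * fp + 19 * fh[[4]] - 5 * fh[[3]] + fh[[2]])
        fh <- c(fh[2:4], list(f(t + hi, X, P)))
      }
      .check_finite(X, (k - 1L) %/% ns + 1L)
      if (k %% ns == 0L) out[k %/% ns + 1L, ] <- X
      k <- k + 1L
    }
  }
  trajectory(t0 + h * (seq_len(n_steps) - 1), out, model$state_names)
}

.check_finite <- function(X, step) {
  if (!all(is.finite(X)))
    stop(sprintf("state became non-finite at step %d (blow-up)", step))
}

#' Generate a synthetic training set
#'
#' Simulates the model from a randomized initial condition, discards a
#' burn-in transient so the recorded data lie on the attractor, and returns
#' both the clean trajectory and a copy whose observed components carry
#' i.i.d. zero-mean Gaussian observational noise of the stated variance.
#'
#' @param model a [model_spec()].
#' @param n_samples number of recorded samples.
#' @param noise_variance observation-noise variance (>= 0).
#' @param seed integer seed; the same seed reproduces the realization
#'   bit-for-bit.
#' @param burn_in transient steps discarded before recording.
#' @return list with elements `clean` and `noisy`, both [trajectory()]s.
#' @export
generate_training_data <- function(model, n_samples, noise_variance, seed = NULL,
                                   burn_in = 1000) {
  stopifnot(noise_variance >= 0)
  if (!is.null(seed)) set.seed(seed)
  x0 <- if (is.null(model$ic_sampler)) rep(0, length(model$state_names))
        else model$ic_sampler()
  if (burn_in > 0) {
    burn <- integrate_model(model, x0, n_steps = burn_in + 1L)
    x0 <- burn$values[burn_in + 1L, ]
  }
  clean <- integrate_model(model, x0, n_steps = n_samples)
  noisy_vals <- clean$values
  for (v in model$obs_names)
    noisy_vals[, v] <- noisy_vals[, v] +
      stats::rnorm(n_samples, 0, sqrt(noise_variance))
  list(clean = clean,
       noisy = trajectory(clean$times, noisy_vals, model$state_names))
}
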