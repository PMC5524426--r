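#' Gaussian belief over a (possibly augmented) filter state
#'
#' @param mean numeric mean vector.
#' @param cov symmetric positive-semidefinite covariance matrix.
#' @return object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == length(mean), ncol(cov) == length(mean))
  if (max(abs(cov - t(cov))) > 1e-10 * max(1, max(abs(cov))))
    stop("covariance is not symmetric")
  structure(list(mean = mean, cov = (cov + t(cov)) / 2),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("<gaussian_belief> dim %d, trace(cov) = %.4g\n",
              length(x$mean), sum(diag(x$cov))))
  invisible(x)
}

#' Unscented filter configuration
#'
#' Holds the noise covariances and sigma-point scaling for [ukf_step()].
#' `Q` inflates the propagated state covariance (process noise; for joint
#' estimation its parameter block acts as a small random-walk inflation),
#' `R` is the observation-noise covariance, and `P0` the initial covariance.
#' `sigma_lambda` is the unscented scaling constant: sigma points are spread
#' by `sqrt(n + lambda)` along the SVD square-root directions of the
#' covariance, with the conventional default `lambda = 3 - n`.
#'
#' @param Q process-noise covariance (matrix, or scalar/vector diagonal).
#' @param R observation-noise covariance (matrix, or scalar/vector diagonal).
#' @param P0 initial covariance (optional; matrix, scalar or vector diagonal).
#' @param obs_indices positions of the observed components in the state.
#' @param sigma_lambda unscented scaling constant; `NULL` means `3 - n`.
#' @return object of class `ukf_config`.
#' @export
ukf_config <- function(Q, R, P0 = NULL, obs_indices = NULL,
                       sigma_lambda = NULL) {
  structure(list(Q = .as_cov(Q), R = .as_cov(R),
                 P0 = if (is.null(P0)) NULL else .as_cov(P0),
                 obs_indices = obs_indices, sigma_lambda = sigma_lambda),
            class = "ukf_config")
}

.as_cov <- function(x) {
  if (is.matrix(x)) (x + t(x)) / 2 else diag(x = as.numeric(x),
                                             nrow = length(x))
}

# Symmetric square root by spectral decomposition (the SVD of a symmetric
# PSD matrix); directions with negative eigenvalues beyond tolerance are
# clipped at zero with a warning.
.cov_sqrt <- function(P) {
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  lam <- e$values
  tol <- 1e-8 * max(abs(lam), 1)
  if (any(lam < -tol))
    warning(sprintf("covariance repaired: clipped %d negative eigenvalue(s), most negative %.3g",
                    sum(lam < -tol), min(lam)))
  lam[lam < 0] <- 0
  e$vectors %*% diag(sqrt(lam), nrow = length(lam))
}

#' Generate unscented sigma points
#'
#' Forms the symmetric ensemble of `2n + 1` state vectors whose weighted
#' mean and covariance reproduce the belief exactly: the central point plus
#' points displaced by `sqrt(n + lambda)` times the columns of the SVD
#' square root of the covariance in both directions.
#'
#' @param belief a [gaussian_belief()].
#' @param cfg a [ukf_config()] (only `sigma_lambda` is used).
#' @return list with `points` (`n x (2n+1)` matrix), `mean_weights` and
#'   `cov_weights` (both length `2n+1`).
#' @export
generate_sigma_points <- function(belief, cfg = ukf_config(0, 1)) {
  n <- length(belief$mean)
  lambda <- if (is.null(cfg$sigma_lambda)) 3 - n else cfg$sigma_lambda
  c0 <- sqrt(n + lambda)
  S <- .cov_sqrt(belief$cov)
  pts <- matrix(belief$mean, n, 2 * n + 1)
  pts[, 1 + seq_len(n)] <- pts[, 1 + seq_len(n)] + c0 * S
  pts[, 1 + n + seq_len(n)] <- pts[, 1 + n + seq_len(n)] - c0 * S
  w0 <- lambda / (n + lambda)
  wi <- 1 / (2 * (n + lambda))
  w <- c(w0, rep(wi, 2 * n))
  list(points = pts, mean_weights = w, cov_weights = w)
}

# Weighted covariance of ensemble deviations: sum_i w_i (X_i - m)(Y_i - m')^T
.wcov <- function(X, mx, Y, my, w) {
  Xc <- X - mx
  Yc <- Y - my
  Xc %*% (w * t(Yc))
}

#' One unscented Kalman filter step
#'
#' Propagates the belief one sample interval through `advance`, observes the
#' propagated ensemble, and assimilates the observation with the standard
#' gain/update equations: `K = Pxy Py^-1`, `x+ = x- + K (y - y-)`,
#' `P+ = P- - Pxy Py^-1 Pyx`. The covariance is symmetrized after the
#' update. A singular innovation covariance is inverted by pseudo-inverse
#' with the condition number attached as attribute `"condition"`.
#'
#' @param belief prior [gaussian_belief()] (posterior of the previous step).
#' @param advance function taking the `n x (2n+1)` sigma-point matrix one
#'   sample interval forward (columnwise).
#' @param obs observation vector.
#' @param cfg a [ukf_config()]; observations are `obs_indices` components of
#'   the advanced state unless `cfg$obs_fn` maps the ensemble itself.
#' @return posterior [gaussian_belief()], with the innovation attached as
#'   attribute `"innovation"`.
#' @export
ukf_step <- function(belief, advance, obs, cfg) {
  sig <- generate_sigma_points(belief, cfg)
  Xf <- advance(sig$points)
  wm <- sig$mean_weights
  wc <- sig$cov_weights
  xm <- drop(Xf %*% wm)
  Pm <- .wcov(Xf, xm, Xf, xm, wc) + cfg$Q
  # the observation map is a component selection, so the observed-ensemble
  # moments are blocks of the (Q-inflated) prior
  oi <- cfg$obs_indices
  ym <- xm[oi]
  Py <- Pm[oi, oi, drop = FALSE] + cfg$R
  Pxy <- Pm[, oi, drop = FALSE]
  K <- tryCatch(t(solve(Py, t(Pxy))), error = function(e) {
    sv <- svd(Py)
    pos <- sv$d > 1e-12 * max(sv$d)
    Pyi <- sv$v[, pos, drop = FALSE] %*%
      ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
    K <- Pxy %*% Pyi
    attr(K, "condition") <- max(sv$d) / min(sv$d[pos])
    K
  })
  innov <- obs - ym
  post_mean <- xm + drop(K %*% innov)
  post_cov <- Pm - K %*% Py %*% t(K)
  post_cov <- (post_cov + t(post_cov)) / 2
  out <- gaussian_belief(post_mean, post_cov)
  attr(out, "innovation") <- innov
  if (!is.null(attr(K, "condition"))) attr(out, "condition") <- attr(K, "condition")
  out
}

#' Draw initial parameter guesses at a given uncertainty level
#'
#' Each component is drawn independently from `N(p, (u p)^2)`, so the
#' uncertainty level is the standard deviation of the initial guess relative
#' to the true value.
#'
#' @param true_params numeric vector of true values.
#' @param uncertainty relative uncertainty `u >= 0` (e.g. 0.8 for 80%).
#' @param seed optional integer seed.
#' @return numeric vector of the same length (named like the input).
#' @export
draw_initial_parameters <- function(true_params, uncertainty, seed = NULL) {
  stopifnot(uncertainty >= 0)
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(stats::rnorm(length(true_params), as.numeric(true_params),
                               uncertainty * abs(as.numeric(true_params))),
                  names(true_params))
}

# Shared filtering loop: processes the rows of obs_matrix in order starting
# from init_belief, recording the posterior mean entries in record_indices.
run_ukf_filter <- function(obs_matrix, init_belief, advance, cfg,
                           record_indices = integer(0)) {
  n_steps <- nrow(obs_matrix)
  hist <- matrix(NA_real_, n_steps, length(record_indices))
  innov <- matrix(NA_real_, n_steps, ncol(obs_matrix))
  belief <- init_belief
  for (k in seq_len(n_steps)) {
    belief <- tryCatch(ukf_step(belief, advance, obs_matrix[k, ], cfg),
                       error = function(e)
                         stop(sprintf("filter diverged at step %d (%s)", k,
                                      conditionMessage(e)), call. = FALSE))
    if (!all(is.finite(belief$mean)) || !all(is.finite(belief$cov)))
      stop(sprintf("filter diverged at step %d (non-finite mean or covariance)", k))
    if (length(record_indices)) hist[k, ] <- belief$mean[record_indices]
    innov[k, ] <- attr(belief, "innovation")
  }
  list(belief = belief, history = hist, innovations = innov)
}

# Default joint-UKF covariances. p_hat are the initial values of the
# estimated parameters; observed/unobserved state entries follow the package
# defaults (observation-noise variance for observed, 1.0 for unobserved).
# The parameter block of Q defaults to zero: parameters are pure auxiliary
# states and their uncertainty contracts as the training data accumulate.
joint_ukf_defaults <- function(n_state, obs_indices, p_hat, noise_variance,
                               uncertainty, q_state = 1e-4, q_param_rel = 0,
                               sigma_lambda = NULL) {
  n_p <- length(p_hat)
  qd <- c(rep(q_state, n_state), q_param_rel * p_hat^2)
  p0 <- rep(1, n_state)
  p0[obs_indices] <- noise_variance
  p0 <- c(p0, pmax((uncertainty * p_hat)^2, 1e-6))
  ukf_config(Q = qd, R = rep(noise_variance, length(obs_indices)),
             P0 = p0, obs_indices = obs_indices, sigma_lambda = sigma_lambda)
}

#' Joint state-and-parameter estimation with the unscented Kalman filter
#'
#' Augments the model state with the parameters to estimate, giving them
#' trivial dynamics `p_{k+1} = p_k` (plus their process-noise block), and
#' filters the noisy training data in order. The state block of each sigma
#' point is advanced one sample interval with its own parameter values
#' (Runge-Kutta-4 for continuous models, one map application for discrete
#' models).
#'
#' @param noisy a [trajectory()] of noisy observations, or a matrix whose
#'   columns are the observed variables in `model$obs_names` order.
#' @param model a [model_spec()].
#' @param estimate_params names of the parameters to estimate.
#' @param init_params full named parameter vector: initial guesses for the
#'   estimated entries, known values for the rest.
#' @param cfg optional [ukf_config()] for the augmented state; defaults are
#'   built from `noise_variance` and `uncertainty`.
#' @param noise_variance observation-noise variance used for the default
#'   `R`/`P0`.
#' @param uncertainty relative parameter uncertainty used for the default
#'   parameter block of `P0`.
#' @return list with `belief` (final augmented [gaussian_belief()]),
#'   `param_history` (per-step posterior parameter means), `params` (full
#'   parameter vector with estimated entries replaced by their final
#'   estimates), `state` (final model-state mean), and `diagnostics`
#'   (per-step innovations and parameter means, ready for `write.csv`).
#' @export
run_joint_ukf <- function(noisy, model, estimate_params,
                          init_params = model$true_params, cfg = NULL,
                          noise_variance = 1, uncertainty = 0) {
  obs_mat <- .obs_matrix(noisy, model)
  sn <- model$state_names
  n_s <- length(sn)
  stopifnot(all(estimate_params %in% model$param_names))
  init_params <- init_params[model$param_names]
  est_idx <- match(estimate_params, model$param_names)
  n_p <- length(est_idx)
  obs_indices <- match(model$obs_names, sn)
  if (is.null(cfg))
    cfg <- joint_ukf_defaults(n_s, obs_indices, as.numeric(init_params[est_idx]),
                              noise_variance, uncertainty)
  h <- model$sample_interval
  base_params <- as.numeric(init_params)
  advance <- function(X) {
    E <- ncol(X)
    P <- matrix(base_params, length(base_params), E)
    if (n_p) P[est_idx, ] <- X[n_s + seq_len(n_p), , drop = FALSE]
    S <- advance_model(model, 0, X[seq_len(n_s), , drop = FALSE], P, h)
    # saturation guard: runaway sigma points (e.g. explosive parameter
    # excursions in cubic dynamics) are capped so the update step can pull
    # them back instead of the whole filter going non-finite
    S[S > 1e6] <- 1e6
    S[S < -1e6] <- -1e6
    S[!is.finite(S)] <- 1e6
    rbind(S, X[n_s + seq_len(n_p), , drop = FALSE])
  }
  m0 <- .initial_state_mean(model, obs_mat[1, ], init_params)
  mean0 <- c(m0, as.numeric(init_params[est_idx]))
  P0 <- if (is.null(cfg$P0)) diag(1, n_s + n_p) else cfg$P0
  run <- run_ukf_filter(obs_mat[-1, , drop = FALSE],
                        gaussian_belief(mean0, P0), advance, cfg,
                        record_indices = n_s + seq_len(n_p))
  params_out <- init_params
  params_out[est_idx] <- run$belief$mean[n_s + seq_len(n_p)]
  colnames(run$history) <- estimate_params
  diagnostics <- data.frame(step = seq_len(nrow(run$history)) + 1L,
                            run$innovations, run$history,
                            check.names = FALSE)
  names(diagnostics) <- c("step", paste0("innovation_", model$obs_names),
                          estimate_params)
  list(belief = run$belief, param_history = run$history,
       params = params_out,
       state = stats::setNames(run$belief$mean[seq_len(n_s)], sn),
       diagnostics = diagnostics)
}

# Observation matrix in model$obs_names column order.
.obs_matrix <- function(noisy, model) {
  v <- if (inherits(noisy, "trajectory")) noisy$values else as.matrix(noisy)
  if (!is.null(colnames(v)) && all(model$obs_names %in% colnames(v)))
    v <- v[, model$obs_names, drop = FALSE]
  if (ncol(v) != length(model$obs_names))
    stop("observation matrix does not match the model's observed variables")
  v
}

# Initial filter mean: first observation for observed components, the
# model's latent_init (or zero) for the rest.
.initial_state_mean <- function(model, first_obs, params) {
  sn <- model$state_names
  m0 <- stats::setNames(rep(0, length(sn)), sn)
  m0[model$obs_names] <- first_obs
  latent <- setdiff(sn, model$obs_names)
  if (length(latent) && !is.null(model$latent_init)) {
    li <- model$latent_init(stats::setNames(first_obs, model$obs_names),
                            params)
    m0[intersect(latent, names(li))] <- li[intersect(latent, names(li))]
  }
  as.numeric(m0)
}

#' Forward solve a fitted parametric model
#'
#' @param model a [model_spec()].
#' @param state state at the end of the training window.
#' @param params fixed parameter vector.
#' @param horizon number of samples to predict.
#' @return matrix `horizon x n_state` of predictions for times `T+1 ... T+horizon`.
#' @export
parametric_forecast <- function(model, state, params, horizon) {
  tr <- integrate_model(model, state, params, n_steps = horizon + 1L)
  tr$values[-1, , drop = FALSE]
}
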