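#' Construct a hybrid model specification
#'
#' Partitions the model's state variables into a mechanistic set (advanced
#' by their equations) and a nonparametric set (advanced by delay-coordinate
#' nearest-neighbour prediction). Only observed variables can be replaced.
#' The retained parameters are those appearing in the retained equations;
#' parameters appearing solely in replaced equations are dropped from the
#' estimation problem.
#'
#' @param model a [model_spec()].
#' @param replace labels of the state variables to represent
#'   nonparametrically (a proper, possibly empty, subset of the observed
#'   variables).
#' @param embedding an [embedding_config()], or a named list of one per
#'   replaced variable.
#' @return object of class `hybrid_spec` with elements `model`,
#'   `mechanistic_vars`, `nonparametric_vars`, `retained_params`,
#'   `embedding` (named list).
#' @export
make_hybrid_spec <- function(model, replace, embedding = embedding_config()) {
  replace <- as.character(replace)
  if (!all(replace %in% model$obs_names))
    stop("only observed variables can be replaced nonparametrically")
  if (length(replace) >= length(model$state_names))
    stop("replace must be a proper subset of the state variables")
  mech <- setdiff(model$state_names, replace)
  # keep only the equations actually needed: start from the observed
  # mechanistic variables and close over state dependencies; unobserved
  # variables never referenced by a retained equation are dropped (their
  # equations play no role once the replaced variables are data-driven)
  keep <- intersect(mech, model$obs_names)
  repeat {
    need <- unique(unlist(model$state_deps[keep], use.names = FALSE))
    grow <- union(keep, intersect(mech, need))
    if (length(grow) == length(keep)) break
    keep <- grow
  }
  mech <- intersect(model$state_names, keep)   # model order
  retained <- unique(unlist(model$param_deps[mech], use.names = FALSE))
  retained <- intersect(model$param_names, retained)
  need <- unique(unlist(model$state_deps[mech], use.names = FALSE))
  missing_vars <- setdiff(need, c(mech, replace))
  if (length(missing_vars))
    stop(sprintf("retained equations depend on unrepresented variable(s): %s",
                 paste(missing_vars, collapse = ", ")))
  if (inherits(embedding, "embedding_config"))
    embedding <- stats::setNames(rep(list(embedding), length(replace)), replace)
  if (length(replace) && !all(replace %in% names(embedding)))
    stop("embedding must be named for every replaced variable")
  structure(list(model = model, mechanistic_vars = mech,
                 nonparametric_vars = replace, retained_params = retained,
                 embedding = embedding[replace]),
            class = "hybrid_spec")
}

#' @export
print.hybrid_spec <- function(x, ...) {
  cat(sprintf("<hybrid_spec '%s'> mechanistic: %s | nonparametric: %s | retained params: %s\n",
              x$model$name, paste(x$mechanistic_vars, collapse = ","),
              if (length(x$nonparametric_vars))
                paste(x$nonparametric_vars, collapse = ",") else "(none)",
              paste(x$retained_params, collapse = ",")))
  invisible(x)
}

# Index bookkeeping for the hybrid state layout:
# [mechanistic values; per nonparametric variable a ring of its last
#  d*tau + 1 samples (newest first); estimated parameter values].
hybrid_layout <- function(spec, estimate_params) {
  model <- spec$model
  n_m <- length(spec$mechanistic_vars)
  spans <- vapply(spec$nonparametric_vars,
                  function(v) spec$embedding[[v]]$d * spec$embedding[[v]]$tau,
                  integer(1))
  block_idx <- list()
  pos <- n_m
  for (v in spec$nonparametric_vars) {
    block_idx[[v]] <- pos + seq_len(spans[[v]] + 1L)
    pos <- pos + spans[[v]] + 1L
  }
  n_p <- length(estimate_params)
  list(n_m = n_m,
       mech_idx = seq_len(n_m),
       block_idx = block_idx,
       current_idx = vapply(block_idx, `[`, numeric(1), 1L),
       param_idx = pos + seq_len(n_p),
       dim = pos + n_p,
       spans = spans)
}

# Precomputed advancement context shared by the filter and the forecaster.
hybrid_context <- function(spec, libs, estimate_params, base_params,
                           clip = FALSE,
                           mech_scheme = c("euler", "integrate")) {
  mech_scheme <- match.arg(mech_scheme)
  model <- spec$model
  layout <- hybrid_layout(spec, estimate_params)
  sn <- model$state_names
  npv <- spec$nonparametric_vars
  np_state_rows <- match(npv, sn)
  dsel <- lapply(npv, function(v) {
    e <- spec$embedding[[v]]
    1L + (0:e$d) * e$tau
  })
  names(dsel) <- npv
  eligible <- lapply(npv, function(v) .eligible_rows(libs[[v]], 1))
  names(eligible) <- npv
  base <- as.numeric(base_params[model$param_names])
  est_rows <- match(estimate_params, model$param_names)
  list(spec = spec, model = model, layout = layout, libs = libs,
       npv = npv, np_state_rows = np_state_rows,
       mech_state_rows = match(spec$mechanistic_vars, sn),
       dsel = dsel, eligible = eligible, base_params = base,
       est_rows = est_rows, clip = clip, mech_scheme = mech_scheme,
       h = model$sample_interval)
}

# Advance a matrix of hybrid states (columns = ensemble members) one sample.
# The hybrid model is a discrete-time map: each nonparametric variable's
# next value is the lead-1 nearest-neighbour prediction from its current
# delay vector, and the mechanistic block takes one explicit step of length
# h evaluated at the current values of all represented variables. When no
# variable is replaced the hybrid degenerates to the parametric model and
# the full integrator (sub-stepped RK4) is used instead.
hybrid_advance_mat <- function(X, ctx) {
  lay <- ctx$layout
  E <- ncol(X)
  n_state <- length(ctx$model$state_names)
  F <- matrix(0, n_state, E)
  F[ctx$mech_state_rows, ] <- X[lay$mech_idx, , drop = FALSE]
  for (j in seq_along(ctx$npv))
    F[ctx$np_state_rows[j], ] <- X[lay$block_idx[[ctx$npv[j]]][1L], ]
  P <- matrix(ctx$base_params, length(ctx$base_params), E)
  if (length(ctx$est_rows))
    P[ctx$est_rows, ] <- X[lay$param_idx, , drop = FALSE]
  out <- X
  for (v in ctx$npv) {
    bi <- lay$block_idx[[v]]
    lib <- ctx$libs[[v]]
    e <- ctx$spec$embedding[[v]]
    pred <- cpp_knn_predict(t(X[bi[ctx$dsel[[v]]], , drop = FALSE]),
                            lib$vectors, lib$futures[, 1],
                            ctx$eligible[[v]], e$kappa,
                            ifelse(e$weighting == "uniform", 0L, 1L))
    out[bi, ] <- rbind(pred, X[bi[seq_len(length(bi) - 1L)], , drop = FALSE],
                       deparse.level = 0)
  }
  mech_new <- if (ctx$model$kind == "continuous") {
    if (length(ctx$npv) && ctx$mech_scheme == "euler") {
      D <- ctx$model$dynamics(0, F, P)
      F[ctx$mech_state_rows, , drop = FALSE] +
        ctx$h * D[ctx$mech_state_rows, , drop = FALSE]
    } else if (length(ctx$npv)) {
      # sub-stepped RK4 on the retained equations with the replaced
      # variables held at their current values
      np_rows <- ctx$np_state_rows
      dyn <- function(t, Z, P) {
        D <- ctx$model$dynamics(t, Z, P)
        D[np_rows, ] <- 0
        D
      }
      ns <- max(1L, ctx$model$substeps)
      G <- F
      for (i in seq_len(ns)) G <- rk4_step(dyn, 0, G, P, ctx$h / ns)
      G[ctx$mech_state_rows, , drop = FALSE]
    } else {
      advance_model(ctx$model, 0, F, P)[ctx$mech_state_rows, , drop = FALSE]
    }
  } else {
    ctx$model$dynamics(0, F, P)[ctx$mech_state_rows, , drop = FALSE]
  }
  if (ctx$clip) {
    # saturation guard (filtering only), as in the parametric joint filter
    mech_new[mech_new > 1e6] <- 1e6
    mech_new[mech_new < -1e6] <- -1e6
    mech_new[!is.finite(mech_new)] <- 1e6
  }
  out[lay$mech_idx, ] <- mech_new
  out
}

#' Advance a hybrid state one sample interval
#'
#' The hybrid model is treated as a discrete-time map. Each nonparametric
#' variable's new value is the lead-1 local-constant prediction from its
#' current delay vector, after which its lag entries shift by one slot.
#' Mechanistic variables take one explicit step of the sample interval
#' (one map application for discrete models) evaluated at the current
#' values of all represented variables. With `replace = character(0)` the
#' hybrid degenerates to the parametric model and the full sub-stepped
#' integrator is used, so the degenerate hybrid reproduces the parametric
#' engine exactly.
#'
#' @param hstate numeric hybrid state vector (see [make_hybrid_spec()] for
#'   the layout), including the values of any estimated parameters at the
#'   end.
#' @param spec a [hybrid_spec()].
#' @param libs named list of [build_delay_library()] objects (lead-1
#'   futures), one per nonparametric variable, built from denoised training
#'   data at the model's sample interval.
#' @param params full named parameter vector supplying the values of
#'   parameters not carried in the state.
#' @param estimate_params names of the parameters carried at the end of
#'   `hstate` (default: none).
#' @return the advanced hybrid state vector.
#' @export
hybrid_advance <- function(hstate, spec, libs, params = spec$model$true_params,
                           estimate_params = character(0)) {
  ctx <- hybrid_context(spec, libs, estimate_params, params)
  if (length(hstate) != ctx$layout$dim)
    stop(sprintf("hybrid state has dimension %d, expected %d",
                 length(hstate), ctx$layout$dim))
  drop(hybrid_advance_mat(matrix(hstate, ncol = 1), ctx))
}

#' Joint estimation with the hybrid unscented Kalman filter
#'
#' Filters noisy training data with the hybrid state (mechanistic values,
#' delay-coordinate blocks for the replaced variables, and the estimated
#' retained parameters with trivial dynamics). Training data for the
#' replaced variables are first denoised with the Kalman-Takens filter and
#' the advancement libraries are built from the denoised series. The
#' observation map hits the observed mechanistic values and the current
#' coordinate of each nonparametric block.
#'
#' @param noisy a [trajectory()] (or matrix of observed variables) of noisy
#'   training data.
#' @param spec a [hybrid_spec()].
#' @param init_params full named parameter vector: initial guesses for the
#'   estimated entries, known values for the rest.
#' @param estimate_params parameters to estimate (default: all retained
#'   parameters).
#' @param cfg optional [ukf_config()] for the hybrid state; defaults built
#'   from `noise_variance` and `uncertainty`.
#' @param noise_variance observation-noise variance (default `R`, `P0`, and
#'   the denoiser's observation noise).
#' @param uncertainty relative parameter uncertainty (default parameter
#'   block of `P0`).
#' @param denoise filter the replaced variables' training data with
#'   [kalman_takens_denoise()] before building libraries (default TRUE).
#' @param q_denoise process-noise variance of the denoiser.
#' @param q_mech process-noise variance of the retained mechanistic state
#'   entries; should reflect the one-step truncation error of the discrete
#'   hybrid map under the system at hand (see the package vignette for the
#'   measured scales of the built-in systems).
#' @param q_param_rel relative parameter random-walk variance: the
#'   parameter block of `Q` is `q_param_rel * p_hat^2`. A small value keeps
#'   the parameter covariance from collapsing before the estimates have
#'   converged.
#' @return object of class `hybrid_fit`: `belief`, `param_history`,
#'   `estimates` (final estimated-parameter means), `params` (full vector
#'   with estimates substituted), `state` (final hybrid mean), `spec`,
#'   `libs`, `estimate_params`.
#' @export
run_hybrid_ukf <- function(noisy, spec, init_params = spec$model$true_params,
                           estimate_params = spec$retained_params, cfg = NULL,
                           noise_variance = 1, uncertainty = 0,
                           denoise = TRUE, q_denoise = 1e-2, q_mech = 1e-4,
                           q_param_rel = 0) {
  model <- spec$model
  stopifnot(all(estimate_params %in% spec$retained_params))
  init_params <- init_params[model$param_names]
  obs_mat <- .obs_matrix(noisy, model)
  n_train <- nrow(obs_mat)
  npv <- spec$nonparametric_vars
  series <- list()
  libs <- list()
  for (v in npv) {
    s <- obs_mat[, v]
    if (denoise)
      s <- kalman_takens_denoise(s, spec$embedding[[v]], q = q_denoise,
                                 r = noise_variance)
    series[[v]] <- s
    libs[[v]] <- build_delay_library(s, spec$embedding[[v]], max_lead = 1)
  }
  ctx <- hybrid_context(spec, libs, estimate_params, init_params)
  lay <- ctx$layout
  k0 <- if (length(npv)) max(vapply(npv, function(v) lay$spans[[v]] + 1L,
                                    numeric(1))) else 1L
  if (k0 >= n_train) stop("training series too short for the embedding")

  # initial mean: observations at k0 for observed mechanistic variables,
  # latent_init for unobserved ones, denoised history for the delay blocks
  first_obs <- stats::setNames(obs_mat[k0, ], model$obs_names)
  m_full <- .initial_state_mean(model, obs_mat[k0, ], init_params)
  names(m_full) <- model$state_names
  mean0 <- numeric(lay$dim)
  mean0[lay$mech_idx] <- m_full[spec$mechanistic_vars]
  for (v in npv)
    mean0[lay$block_idx[[v]]] <- series[[v]][k0 - (seq_along(lay$block_idx[[v]]) - 1L)]
  p_hat <- as.numeric(init_params[estimate_params])
  mean0[lay$param_idx] <- p_hat

  obs_positions <- vapply(model$obs_names, function(v) {
    if (v %in% spec$mechanistic_vars) lay$mech_idx[match(v, spec$mechanistic_vars)]
    else lay$block_idx[[v]][1L]
  }, numeric(1))
  if (is.null(cfg)) {
    qd <- rep(1e-4, lay$dim)
    qd[lay$mech_idx] <- q_mech          # recycled over the retained entries
    for (v in npv) {
      bi <- lay$block_idx[[v]]
      qd[bi] <- 1e-8                  # lag entries are exact copies
      qd[bi[1L]] <- noise_variance    # neighbour-predictor error scale
    }
    qd[lay$param_idx] <- q_param_rel * p_hat^2
    p0 <- rep(1, lay$dim)
    p0[unlist(lay$block_idx, use.names = FALSE)] <- noise_variance
    p0[obs_positions] <- noise_variance
    p0[lay$param_idx] <- pmax((uncertainty * p_hat)^2, 1e-6)
    # delay-coordinate blocks make the state ten-plus dimensional, where
    # nonnegative sigma weights (lambda = 0) are numerically robust; the
    # degenerate hybrid keeps the parametric engine's default scaling
    cfg <- ukf_config(Q = qd, R = rep(noise_variance, length(obs_positions)),
                      P0 = p0, obs_indices = obs_positions,
                      sigma_lambda = if (length(npv)) 0 else NULL)
  }
  ctx_filter <- ctx
  ctx_filter$clip <- TRUE
  advance <- function(X) hybrid_advance_mat(X, ctx_filter)
  P0 <- if (is.null(cfg$P0)) diag(1, lay$dim) else cfg$P0
  run <- run_ukf_filter(obs_mat[(k0 + 1L):n_train, , drop = FALSE],
                        gaussian_belief(mean0, P0), advance, cfg,
                        record_indices = lay$param_idx)
  est <- stats::setNames(run$belief$mean[lay$param_idx], estimate_params)
  params_out <- init_params
  params_out[estimate_params] <- est
  colnames(run$history) <- estimate_params
  structure(list(belief = run$belief, param_history = run$history,
                 estimates = est, params = params_out,
                 state = run$belief$mean, spec = spec, libs = libs,
                 estimate_params = estimate_params),
            class = "hybrid_fit")
}

#' @export
print.hybrid_fit <- function(x, ...) {
  cat(sprintf("<hybrid_fit '%s'> estimates: %s\n", x$spec$model$name,
              paste(sprintf("%s = %.4g", names(x$estimates), x$estimates),
                    collapse = ", ")))
  invisible(x)
}

#' Forecast with a fitted hybrid model
#'
#' Iterates [hybrid_advance()] from the final hybrid state mean with the
#' parameters fixed at their final estimates, returning the represented
#' state variables over the prediction interval. If the forecast blows up,
#' the remaining horizon is filled with the last finite values and the
#' result carries attribute `"diverged_at"` with the offending step.
#'
#' @param fit a `hybrid_fit` from [run_hybrid_ukf()], or a numeric hybrid
#'   state vector (then `spec`, `libs`, `params`, `estimate_params` must be
#'   supplied).
#' @param horizon number of samples to predict.
#' @param spec,libs,params,estimate_params see [hybrid_advance()]; ignored
#'   when `fit` is a `hybrid_fit`.
#' @return matrix `horizon x n_vars` of predictions for the mechanistic and
#'   nonparametric variables (columns named, in model state order).
#' @export
hybrid_forecast <- function(fit, horizon, spec = NULL, libs = NULL,
                            params = NULL, estimate_params = NULL) {
  if (inherits(fit, "hybrid_fit")) {
    spec <- fit$spec
    libs <- fit$libs
    params <- fit$params
    estimate_params <- fit$estimate_params
    state <- fit$belief$mean
  } else {
    state <- as.numeric(fit)
    if (is.null(estimate_params)) estimate_params <- character(0)
    if (is.null(params)) params <- spec$model$true_params
  }
  ctx <- hybrid_context(spec, libs, estimate_params, params)
  lay <- ctx$layout
  if (!length(ctx$npv)) {            # degenerate hybrid: plain forward solve
    full <- params
    if (length(estimate_params))
      full[estimate_params] <- state[lay$param_idx]
    return(parametric_forecast(spec$model, state[lay$mech_idx], full, horizon))
  }
  vars <- intersect(spec$model$state_names,
                    c(spec$mechanistic_vars, spec$nonparametric_vars))
  out <- matrix(NA_real_, horizon, length(vars), dimnames = list(NULL, vars))
  X <- matrix(state, ncol = 1)
  diverged_at <- NA_integer_
  for (k in seq_len(horizon)) {
    X <- hybrid_advance_mat(X, ctx)
    if (!all(is.finite(X))) {
      diverged_at <- k
      warning(sprintf("hybrid forecast blew up at step %d; remaining horizon filled with last finite values", k))
      if (k == 1L) out[, ] <- NA_real_
      else out[k:horizon, ] <- matrix(out[k - 1L, ], horizon - k + 1L,
                                      length(vars), byrow = TRUE)
      break
    }
    vals <- numeric(length(vars))
    names(vals) <- vars
    vals[spec$mechanistic_vars] <- X[lay$mech_idx, 1]
    for (v in ctx$npv) vals[v] <- X[lay$block_idx[[v]][1L], 1]
    out[k, ] <- vals[vars]
  }
  if (!is.na(diverged_at)) attr(out, "diverged_at") <- diverged_at
  out
}
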