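#' Normalized root-mean-square forecast error for one realization
#'
#' Per-lead absolute prediction error normalized by the standard deviation
#' of the variable in the training data. A prediction equal to the training
#' mean scores about 1; a perfect prediction scores 0.
#'
#' @param pred predicted values, one per lead.
#' @param truth noise-free true values, same length.
#' @param train_sd standard deviation of the variable over the training
#'   window (must be > 0).
#' @return numeric vector of normalized errors per lead.
#' @export
compute_srmse <- function(pred, truth, train_sd) {
  if (!is.finite(train_sd) || train_sd <= 0) stop("training standard deviation must be positive")
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  abs(pred - truth) / train_sd
}

# Aggregate per-realization normalized errors (realizations x leads) into a
# curve: RMS across realizations per lead, with the standard error of the
# per-realization normalized errors.
aggregate_srmse <- function(err, aggregation = c("rms", "mean")) {
  aggregation <- match.arg(aggregation)
  err <- as.matrix(err)
  n <- nrow(err)
  mean_curve <- if (aggregation == "rms") sqrt(colMeans(err^2)) else colMeans(err)
  se <- apply(err, 2, stats::sd) / sqrt(n)
  list(mean = mean_curve, se = se, n = n, aggregation = aggregation)
}

#' Summarize parameter estimates across realizations
#'
#' @param estimates matrix, one row per realization, one column per
#'   parameter.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_estimates <- function(estimates) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 1) stop("at least one realization required")
  data.frame(parameter = colnames(estimates),
             mean = colMeans(estimates),
             sd = if (nrow(estimates) == 1) rep(0, ncol(estimates))
                  else apply(estimates, 2, stats::sd),
             n = nrow(estimates), row.names = NULL)
}

#' Monte-Carlo experiment configuration
#'
#' Describes one cell of the simulation study: the system, the prediction
#' method, the training/forecast design, the noise and parameter-uncertainty
#' levels, and the replicate count. [experiment_preset()] fills in the
#' standard settings for each built-in system.
#'
#' @param system model name (see [get_model()]).
#' @param method `"parametric"`, `"nonparametric"`, or `"hybrid"`.
#' @param n_train training samples.
#' @param horizon forecast samples.
#' @param noise_variance observation-noise variance.
#' @param uncertainty relative initial parameter uncertainty.
#' @param n_realizations Monte-Carlo replicates.
#' @param embedding an [embedding_config()] (nonparametric and hybrid).
#' @param replace variables replaced nonparametrically (hybrid).
#' @param estimate_params parameters treated as unknown (default: all).
#' @param seed master seed; realization seeds are derived deterministically.
#' @param burn_in transient discarded before recording training data.
#' @param n_connections,network_size Hindmarsh-Rose network design.
#' @param noise_model `"gaussian"` (additive, the default) or `"lognormal"`
#'   (multiplicative, for census-style count data).
#' @param cpa_values optional vector of LPA recruitment-cannibalism rates;
#'   realizations then cycle over `cpa_values x replicates`.
#' @param srmse_aggregation `"rms"` (default) or `"mean"` across
#'   realizations.
#' @param sigma_lambda unscented scaling override for the parametric joint
#'   filter (NULL for the default).
#' @param q_mech mechanistic-state process noise of the hybrid filter (the
#'   discrete hybrid map's truncation-error scale; NULL for 1e-4).
#' @param q_param_rel relative parameter random-walk variance used by both
#'   joint filters.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(system, method, n_train, horizon, noise_variance,
                              uncertainty, n_realizations,
                              embedding = embedding_config(),
                              replace = character(0),
                              estimate_params = NULL, seed = 1,
                              burn_in = 1000, n_connections = 5,
                              network_size = 3,
                              noise_model = c("gaussian", "lognormal"),
                              cpa_values = NULL,
                              srmse_aggregation = c("rms", "mean"),
                              sigma_lambda = NULL, q_mech = NULL,
                              q_param_rel = 0) {
  method <- match.arg(method, c("parametric", "nonparametric", "hybrid"))
  noise_model <- match.arg(noise_model)
  srmse_aggregation <- match.arg(srmse_aggregation)
  stopifnot(n_train > 0, horizon > 0, n_realizations > 0, uncertainty >= 0)
  structure(list(system = system, method = method, n_train = n_train,
                 horizon = horizon, noise_variance = noise_variance,
                 uncertainty = uncertainty, n_realizations = n_realizations,
                 embedding = embedding, replace = replace,
                 estimate_params = estimate_params, seed = seed,
                 burn_in = burn_in, n_connections = n_connections,
                 network_size = network_size, noise_model = noise_model,
                 cpa_values = cpa_values,
                 srmse_aggregation = srmse_aggregation,
                 sigma_lambda = sigma_lambda, q_mech = q_mech,
                 q_param_rel = q_param_rel),
            class = "experiment_config")
}

#' Standard experiment presets
#'
#' Encodes the standard design for each built-in system: Lorenz-63 (500
#' training samples at h = 0.05, noise variance 4, embedding d = 9, tau = 1,
#' kappa = 20, horizon 20 samples = one time unit, hybrid replaces `y`);
#' Hindmarsh-Rose (3-neuron networks with 5 random connections, 3000
#' training samples at h = 0.08 ms, noise variance 0.2, kappa = 10, horizon
#' 100 samples = 8 ms, hybrid keeps neuron 3 and replaces `x1`, `x2`); and
#' the LPA beetle map (37 training censuses, 4 predicted, d = 2, tau = 1,
#' kappa = 5, hybrid replaces larvae; `b`, `cel`, `cea`, `mul` unknown with
#' `cpa`, `mua` experimentally set).
#'
#' @param system model name.
#' @param method prediction method.
#' @param uncertainty relative initial parameter uncertainty.
#' @param n_realizations Monte-Carlo replicates.
#' @param seed master seed.
#' @param ... overrides passed to [experiment_config()].
#' @return an [experiment_config()].
#' @export
experiment_preset <- function(system, method, uncertainty = 0.8,
                              n_realizations = 100, seed = 1, ...) {
  base <- switch(system,
    lorenz63 = list(n_train = 500, horizon = 20, noise_variance = 4,
                    embedding = embedding_config(d = 9, tau = 1, kappa = 20),
                    replace = "y",
                    # measured per-equation truncation variance of the
                    # one-step hybrid map (x and z rows)
                    q_mech = c(0.37, 1.6)),
    hindmarsh_rose = list(n_train = 3000, horizon = 100, noise_variance = 0.2,
                          embedding = embedding_config(d = 9, tau = 1, kappa = 10),
                          replace = c("x1", "x2"), q_mech = 0.01,
                          # large augmented states need nonnegative sigma
                          # weights for a stable unscented transform
                          sigma_lambda = 0),
    lpa = list(n_train = 37, horizon = 4, noise_variance = 100,
               embedding = embedding_config(d = 2, tau = 1, kappa = 5),
               replace = "L", noise_model = "lognormal",
               estimate_params = c("b", "cel", "cea", "mul"),
               cpa_values = c(0, 0.05, 0.10, 0.25, 0.35, 0.50, 1.0),
               burn_in = 0),
    stop(sprintf("no preset for system '%s'", system)))
  args <- utils::modifyList(c(list(system = system, method = method,
                                   uncertainty = uncertainty,
                                   n_realizations = n_realizations,
                                   seed = seed), base),
                            list(...))
  do.call(experiment_config, args)
}

# Deterministic per-realization seed derivation (fixed counter scheme).
realization_seed <- function(master_seed, r) {
  as.integer((as.numeric(master_seed) + 104729 * r) %% 2147483629)
}

#' Run a Monte-Carlo prediction experiment
#'
#' For each realization (independently and reproducibly seeded from the
#' master seed): simulates a noise-free truth plus noisy training data, runs
#' the configured method on the training window, forecasts the horizon, and
#' scores the normalized error of each observed variable against the
#' noise-free truth. Parameter estimates and SRMSE curves are aggregated
#' across realizations; realizations whose forecast is non-finite (or with
#' normalized error beyond 1e6) are excluded from the forecast aggregation
#' and counted.
#'
#' @param cfg an [experiment_config()].
#' @return object of class `experiment_result` with elements `estimates`
#'   (from [summarize_estimates()], methods with parameters only),
#'   `estimate_draws` (matrix of per-realization final estimates), `srmse`
#'   (per-variable list of per-lead `mean` and `se`), `srmse_draws`,
#'   `exclusions` (count), `failures` (count of realizations whose filter
#'   diverged), and the echoed `config`.
#' @export
run_experiment <- function(cfg) {
  method <- cfg$method
  n_real <- cfg$n_realizations
  est_rows <- list()
  err_rows <- list()    # per observed var: realization x lead matrices
  exclusions <- 0L
  failures <- 0L
  obs_vars <- NULL
  for (r in seq_len(n_real)) {
    set.seed(realization_seed(cfg$seed, r))
    model <- .experiment_model(cfg, r)
    if (is.null(obs_vars)) obs_vars <- model$obs_names
    sim <- .experiment_data(cfg, model)
    res <- tryCatch(.run_one_method(cfg, model, sim),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      exclusions <- exclusions + 1L
      next
    }
    if (!is.null(res$estimates)) est_rows[[length(est_rows) + 1L]] <- res$estimates
    err <- res$err   # leads x vars normalized errors; NULL if the forecast blew up
    if (is.null(err) || !all(is.finite(err)) || max(abs(err)) > 1e6) {
      exclusions <- exclusions + 1L
      next
    }
    err_rows[[length(err_rows) + 1L]] <- err
  }
  est_sum <- NULL
  est_mat <- NULL
  if (length(est_rows)) {
    est_mat <- do.call(rbind, est_rows)
    est_sum <- summarize_estimates(est_mat)
  }
  srmse <- NULL
  srmse_draws <- NULL
  if (length(err_rows)) {
    srmse_draws <- lapply(stats::setNames(seq_along(obs_vars), obs_vars),
                          function(j) t(vapply(err_rows, function(e) e[, j],
                                               numeric(cfg$horizon))))
    srmse <- lapply(srmse_draws, aggregate_srmse,
                    aggregation = cfg$srmse_aggregation)
  }
  structure(list(estimates = est_sum, estimate_draws = est_mat,
                 srmse = srmse, srmse_draws = srmse_draws,
                 exclusions = exclusions, failures = failures,
                 n_scored = length(err_rows), config = cfg),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<experiment_result> %s / %s, %d realizations (%d scored, %d excluded, %d failed)\n",
              cfg$system, cfg$method, cfg$n_realizations, x$n_scored,
              x$exclusions, x$failures))
  if (!is.null(x$estimates)) {
    cat("parameter estimates:\n")
    print(x$estimates, digits = 4)
  }
  if (!is.null(x$srmse)) {
    last <- vapply(x$srmse, function(s) s$mean[length(s$mean)], numeric(1))
    cat("SRMSE at final lead:", paste(sprintf("%s = %.3f", names(last), last),
                                      collapse = ", "), "\n")
  }
  invisible(x)
}

.experiment_model <- function(cfg, r) {
  if (cfg$system == "hindmarsh_rose")
    get_model("hindmarsh_rose",
              net = make_network(cfg$network_size, cfg$n_connections))
  else if (cfg$system == "lpa" && !is.null(cfg$cpa_values))
    get_model("lpa", cpa = cfg$cpa_values[((r - 1L) %% length(cfg$cpa_values)) + 1L])
  else get_model(cfg$system)
}

.experiment_data <- function(cfg, model) {
  n_total <- cfg$n_train + cfg$horizon
  if (cfg$noise_model == "gaussian") {
    sim <- generate_training_data(model, n_total, cfg$noise_variance,
                                  seed = NULL, burn_in = cfg$burn_in)
  } else {
    sim <- generate_training_data(model, n_total, 0, seed = NULL,
                                  burn_in = cfg$burn_in)
    sigma_log <- sqrt(cfg$noise_variance) / 100   # interpreted as % scale
    v <- sim$clean$values
    for (nm in model$obs_names)
      v[, nm] <- v[, nm] * exp(stats::rnorm(nrow(v), 0, sigma_log))
    sim$noisy <- trajectory(sim$clean$times, v, model$state_names)
  }
  train_idx <- seq_len(cfg$n_train)
  list(clean = sim$clean,
       noisy_train = sim$noisy$values[train_idx, model$obs_names, drop = FALSE],
       truth_horizon = sim$clean$values[cfg$n_train + seq_len(cfg$horizon),
                                        model$obs_names, drop = FALSE])
}

.effective_R <- function(cfg, noisy_train) {
  if (cfg$noise_model == "gaussian") cfg$noise_variance
  else mean((sqrt(cfg$noise_variance) / 100 * colMeans(abs(noisy_train)))^2)
}

.run_one_method <- function(cfg, model, sim) {
  obs_vars <- model$obs_names
  train_sd <- apply(sim$noisy_train, 2, stats::sd)
  est_all <- if (is.null(cfg$estimate_params)) model$param_names
             else cfg$estimate_params
  nv <- .effective_R(cfg, sim$noisy_train)
  if (cfg$method == "parametric") {
    init <- model$true_params
    init[est_all] <- draw_initial_parameters(model$true_params[est_all],
                                             cfg$uncertainty)
    n_s <- length(model$state_names)
    ucfg <- joint_ukf_defaults(n_s, match(obs_vars, model$state_names),
                               as.numeric(init[est_all]), nv, cfg$uncertainty,
                               q_param_rel = cfg$q_param_rel,
                               sigma_lambda = cfg$sigma_lambda)
    fit <- run_joint_ukf(sim$noisy_train, model, est_all, init, cfg = ucfg)
    pred <- tryCatch(
      parametric_forecast(model, fit$state, fit$params,
                          cfg$horizon)[, obs_vars, drop = FALSE],
      error = function(e) NULL)   # forecast blow-up: estimates still count
    estimates <- stats::setNames(as.numeric(fit$params[est_all]), est_all)
  } else if (cfg$method == "nonparametric") {
    pred <- matrix(NA_real_, cfg$horizon, length(obs_vars),
                   dimnames = list(NULL, obs_vars))
    for (v in obs_vars) {
      s <- kalman_takens_denoise(sim$noisy_train[, v], cfg$embedding,
                                 r = nv)
      pred[, v] <- direct_forecast(s, cfg$embedding, cfg$horizon)
    }
    estimates <- NULL
  } else {
    spec <- make_hybrid_spec(model, cfg$replace, cfg$embedding)
    est <- intersect(spec$retained_params, est_all)
    init <- model$true_params
    init[est] <- draw_initial_parameters(model$true_params[est],
                                         cfg$uncertainty)
    fit <- run_hybrid_ukf(sim$noisy_train, spec, init, estimate_params = est,
                          noise_variance = nv, uncertainty = cfg$uncertainty,
                          q_mech = if (is.null(cfg$q_mech)) 1e-4 else cfg$q_mech,
                          q_param_rel = cfg$q_param_rel)
    fc <- tryCatch(suppressWarnings(hybrid_forecast(fit, cfg$horizon)),
                   error = function(e) NULL)
    pred <- NULL
    if (!is.null(fc)) {
      pred <- matrix(NA_real_, cfg$horizon, length(obs_vars),
                     dimnames = list(NULL, obs_vars))
      common <- intersect(obs_vars, colnames(fc))
      pred[, common] <- fc[, common]
    }
    estimates <- fit$estimates
  }
  if (is.null(pred)) return(list(err = NULL, estimates = estimates))
  err <- vapply(obs_vars, function(v)
    compute_srmse(pred[, v], sim$truth_horizon[, v], train_sd[v]),
    numeric(cfg$horizon))
  if (!is.matrix(err)) err <- matrix(err, nrow = cfg$horizon)
  colnames(err) <- obs_vars
  list(err = err, estimates = estimates)
}
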