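#' Delay-coordinate embedding configuration
#'
#' @param d number of delays; delay vectors have dimension `d + 1`.
#' @param tau time delay in samples.
#' @param kappa number of nearest neighbours in the local-constant model.
#' @param weighting `"uniform"` (plain average, the default) or
#'   `"inverse_distance"`.
#' @param theiler half-width of a temporal exclusion window around the query
#'   time; 0 (the default) excludes nothing.
#' @return object of class `embedding_config`.
#' @export
embedding_config <- function(d = 9, tau = 1, kappa = 20,
                             weighting = c("uniform", "inverse_distance"),
                             theiler = 0) {
  weighting <- match.arg(weighting)
  stopifnot(d >= 0, tau >= 1, kappa >= 1, theiler >= 0)
  structure(list(d = as.integer(d), tau = as.integer(tau),
                 kappa = as.integer(kappa), weighting = weighting,
                 theiler = as.integer(theiler)),
            class = "embedding_config")
}

#' @export
print.embedding_config <- function(x, ...) {
  cat(sprintf("<embedding_config> d = %d, tau = %d, kappa = %d, %s weights\n",
              x$d, x$tau, x$kappa, x$weighting))
  invisible(x)
}

#' Build a library of delay vectors
#'
#' For each admissible time index `t` the row
#' `[x(t), x(t - tau), ..., x(t - d tau)]` is stored, together with the known
#' future values `x(t + i)` for each lead `i = 1 ... max_lead` (NA where the
#' series ends first). Rows are ordered by `t`, so the library has
#' `length(series) - d * tau` rows.
#'
#' @param series numeric vector (one observed variable).
#' @param cfg an [embedding_config()].
#' @param max_lead largest lead for which futures are stored.
#' @return object of class `delay_library` with elements `vectors`,
#'   `futures`, `source_times`, `cfg`, `max_lead`.
#' @export
build_delay_library <- function(series, cfg, max_lead = 1) {
  series <- as.numeric(series)
  n <- length(series)
  span <- cfg$d * cfg$tau
  if (n <= span + max_lead) stop("series too short for this embedding")
  ts <- (span + 1):n
  vectors <- matrix(series[outer(ts, (0:cfg$d) * cfg$tau, "-")],
                    nrow = length(ts))
  futures <- matrix(NA_real_, length(ts), max_lead)
  for (i in seq_len(max_lead)) {
    tgt <- ts + i
    ok <- tgt <= n
    futures[ok, i] <- series[tgt[ok]]
  }
  structure(list(vectors = vectors, futures = futures, source_times = ts,
                 cfg = cfg, max_lead = as.integer(max_lead),
                 series_length = n),
            class = "delay_library")
}

#' @export
print.delay_library <- function(x, ...) {
  cat(sprintf("<delay_library> %d vectors of dim %d, futures to lead %d\n",
              nrow(x$vectors), ncol(x$vectors), x$max_lead))
  invisible(x)
}

# Eligible rows for a given lead (finite stored future), optionally minus a
# Theiler window around the query time.
.eligible_rows <- function(lib, lead, query_time = NULL, theiler = 0) {
  ok <- is.finite(lib$futures[, lead])
  if (!is.null(query_time) && theiler > 0)
    ok <- ok & abs(lib$source_times - query_time) > theiler
  ok
}

#' Nearest neighbours of a delay vector
#'
#' Returns the `kappa` Euclidean-nearest library rows (distance ties broken
#' by the earlier source time) together with their local-model weights.
#'
#' @param query delay vector of the library's dimension.
#' @param lib a [delay_library()].
#' @param lead lead whose future must be available for a row to qualify.
#' @param cfg embedding configuration; defaults to the library's.
#' @param query_time optional time index of the query, used only when a
#'   Theiler exclusion window is set.
#' @return list with `indices` (library row numbers), `source_times`,
#'   `dists`, and `weights` (nonnegative, summing to 1).
#' @export
nearest_neighbors <- function(query, lib, lead = 1, cfg = lib$cfg,
                              query_time = NULL) {
  ok <- .eligible_rows(lib, lead, query_time, cfg$theiler)
  res <- cpp_knn_query(matrix(as.numeric(query), nrow = 1), lib$vectors,
                       ok, cfg$kappa)
  idx <- drop(res$indices)
  d <- drop(res$dists)
  w <- if (cfg$weighting == "uniform") rep(1 / cfg$kappa, cfg$kappa)
       else { wi <- 1 / pmax(d, 1e-12); wi / sum(wi) }
  list(indices = idx, source_times = lib$source_times[idx], dists = d,
       weights = w)
}

#' Local-constant nearest-neighbour prediction
#'
#' Predicts the value `lead` steps after the query delay vector as the
#' weighted average of the stored futures of its `kappa` nearest library
#' rows. With uniform weights this is the plain average of the neighbours'
#' futures.
#'
#' @param query a delay vector, or a matrix of delay vectors (one per row).
#' @param lib a [delay_library()].
#' @param lead forecast lead (must not exceed `lib$max_lead`).
#' @param cfg embedding configuration; defaults to the library's.
#' @return numeric vector of predictions (one per query row).
#' @export
local_constant_predict <- function(query, lib, lead = 1, cfg = lib$cfg) {
  if (lead > lib$max_lead) stop("lead exceeds the futures stored in the library")
  Q <- if (is.matrix(query)) query else matrix(as.numeric(query), nrow = 1)
  ok <- .eligible_rows(lib, lead, NULL, cfg$theiler)
  cpp_knn_predict(Q, lib$vectors, lib$futures[, lead], ok, cfg$kappa,
                  ifelse(cfg$weighting == "uniform", 0L, 1L))
}

#' Direct nonparametric forecast
#'
#' Implements direct prediction: every lead `i = 1 ... horizon` is predicted
#' independently from the same terminal delay vector of the series, using
#' the neighbours' `i`-step futures (no iteration of a one-step model).
#'
#' @param series numeric training series.
#' @param cfg an [embedding_config()].
#' @param horizon number of leads to predict.
#' @return numeric vector of length `horizon`.
#' @export
direct_forecast <- function(series, cfg, horizon) {
  lib <- build_delay_library(series, cfg, max_lead = horizon)
  n <- length(series)
  q <- series[n - (0:cfg$d) * cfg$tau]
  vapply(seq_len(horizon),
         function(i) local_constant_predict(q, lib, lead = i), numeric(1))
}

#' Model-free denoising with the Kalman-Takens filter
#'
#' Runs an unscented Kalman filter whose state is the vector of the last
#' `d * tau + 1` samples of one variable and whose propagation model is the
#' nonparametric lead-1 local-constant predictor (library built from the
#' noisy series itself) followed by a shift of the lagged entries; the
#' scalar observation at each step is the incoming noisy sample. Process
#' noise acts on the newly predicted coordinate (the lagged entries are
#' exact copies), with variance `q` representing the error of the
#' nearest-neighbour predictor. Because every sample remains in the delay
#' state for `d * tau` further steps and keeps being corrected through the
#' state covariance, each sample's returned estimate is taken when it
#' leaves the delay window (fixed-lag smoothing at no extra cost). Each
#' variable of a multivariate input is filtered separately. The output has
#' the same length as the input.
#'
#' @param noisy_series numeric vector, or matrix with one column per
#'   variable.
#' @param cfg an [embedding_config()].
#' @param q process-noise variance of the predicted coordinate; defaults to
#'   `r/2`, reflecting that the neighbour average carries roughly half
#'   the observation-noise energy at the library sizes used here.
#' @param r observation-noise variance (typically the known noise variance
#'   of the data).
#' @param sigma_lambda unscented scaling for the internal filter; the
#'   default 0 keeps all sigma weights nonnegative, which is numerically
#'   robust for delay states of ten or more dimensions.
#' @return denoised series, same shape as the input.
#' @export
kalman_takens_denoise <- function(noisy_series, cfg, q = NULL, r,
                                  sigma_lambda = 0) {
  if (is.matrix(noisy_series))
    return(apply(noisy_series, 2, kalman_takens_denoise, cfg = cfg, q = q,
                 r = r, sigma_lambda = sigma_lambda))
  if (is.null(q)) q <- r / 2
  x <- as.numeric(noisy_series)
  n <- length(x)
  span <- cfg$d * cfg$tau
  m <- span + 1L
  lib <- build_delay_library(x, cfg, max_lead = 1)
  ok <- .eligible_rows(lib, 1)
  dsel <- 1L + (0:cfg$d) * cfg$tau
  wmode <- ifelse(cfg$weighting == "uniform", 0L, 1L)
  kappa <- cfg$kappa
  advance <- function(X) {
    preds <- cpp_knn_predict(t(X[dsel, , drop = FALSE]), lib$vectors,
                             lib$futures[, 1], ok, kappa, wmode)
    rbind(preds, X[seq_len(span), , drop = FALSE], deparse.level = 0)
  }
  cfg_ukf <- ukf_config(Q = c(q, rep(1e-8, span)), R = r, obs_indices = 1L,
                        sigma_lambda = sigma_lambda)
  belief <- gaussian_belief(x[m:1], diag(r, m))
  out <- x
  for (k in (m + 1L):n) {
    belief <- ukf_step(belief, advance, x[k], cfg_ukf)
    if (!all(is.finite(belief$mean)))
      stop(sprintf("Kalman-Takens filter diverged at sample %d", k))
    if (k - span >= 1L) out[k - span] <- belief$mean[m]
  }
  out[(n - span + 1L):n] <- belief$mean[span:1]
  out
}

#' Cross-validated embedding-parameter selection
#'
#' Splits the series into an earlier sub-training block and a later
#' validation block, direct-forecasts the validation block from the
#' sub-training block for every grid combination, and returns the
#' configuration minimizing the mean validation SRMSE (normalized by the
#' sub-training standard deviation). Deterministic for fixed inputs; ties
#' go to the earlier grid point (grids are scanned in `kappa`-within-
#' `tau`-within-`d` order).
#'
#' @param series numeric training series.
#' @param d_grid,tau_grid,kappa_grid candidate values.
#' @param validation_fraction fraction of the series held out at the end.
#' @param horizon maximum validation lead scored.
#' @param weighting passed to [embedding_config()].
#' @return the selected [embedding_config()], with the attained validation
#'   score attached as attribute `"score"`.
#' @export
select_embedding_cv <- function(series, d_grid, tau_grid, kappa_grid,
                                validation_fraction = 0.2, horizon = 20,
                                weighting = "uniform") {
  stopifnot(length(d_grid) > 0, length(tau_grid) > 0, length(kappa_grid) > 0)
  series <- as.numeric(series)
  n <- length(series)
  n_val <- max(1L, round(validation_fraction * n))
  train <- series[seq_len(n - n_val)]
  truth <- series[(n - n_val + 1L):n]
  h_eval <- min(horizon, n_val)
  sd_tr <- stats::sd(train)
  best <- NULL
  best_score <- Inf
  for (d in d_grid) for (tau in tau_grid) for (kappa in kappa_grid) {
    cfg <- embedding_config(d = d, tau = tau, kappa = kappa,
                            weighting = weighting)
    score <- tryCatch({
      pred <- direct_forecast(train, cfg, h_eval)
      mean(compute_srmse(pred, truth[seq_len(h_eval)], sd_tr))
    }, error = function(e) NA_real_)
    if (is.finite(score) && score < best_score) {
      best_score <- score
      best <- cfg
    }
  }
  if (is.null(best)) stop("no feasible embedding in the grid (series too short)")
  attr(best, "score") <- best_score
  best
}
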