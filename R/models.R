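#' Mechanistic model specification
#'
#' A `model_spec` bundles everything the filters and simulators need to know
#' about a dynamical system: its state and parameter labels, true parameter
#' values used for data generation, a vectorised dynamics function, the
#' observation map, and the sampling interval.
#'
#' The dynamics function has signature `function(t, X, P)` where `X` is an
#' `n_state x E` matrix of states (one column per ensemble member) and `P` an
#' `n_param x E` matrix of parameter values. For `kind = "continuous"` it
#' returns the time derivative; for `kind = "discrete"` it returns the state
#' one census step ahead.
#'
#' @param name model label used by the registry.
#' @param state_names ordered state variable labels.
#' @param param_names ordered parameter labels.
#' @param true_params named numeric vector of ground-truth parameter values.
#' @param kind `"continuous"` or `"discrete"`.
#' @param dynamics vectorised dynamics function (see Details).
#' @param obs_names labels of the observed state variables (the observation
#'   map is the identity on these components).
#' @param sample_interval time between consecutive samples.
#' @param state_deps named list: for each state equation, the state variables
#'   appearing on its right-hand side.
#' @param param_deps named list: for each state equation, the parameters
#'   appearing on its right-hand side.
#' @param ic_sampler function() returning a random initial condition; used
#'   with a burn-in to start each realization on the attractor.
#' @param latent_init function(first_obs, params) returning named starting
#'   values for unobserved state variables.
#' @param substeps internal integration steps per sample interval; the
#'   integrator and the filter's one-step advancement both subdivide the
#'   sample interval by this factor so that truncation error stays well
#'   below the observation noise.
#' @param extra list of model-specific extras (e.g. the network).
#'
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, state_names, param_names, true_params, kind,
                       dynamics, obs_names, sample_interval,
                       state_deps, param_deps,
                       ic_sampler = NULL, latent_init = NULL, substeps = 1L,
                       extra = list()) {
  kind <- match.arg(kind, c("continuous", "discrete"))
  stopifnot(length(param_names) == length(true_params),
            all(obs_names %in% state_names),
            all(names(state_deps) == state_names),
            all(names(param_deps) == state_names))
  true_params <- stats::setNames(as.numeric(true_params), param_names)
  structure(list(name = name, state_names = state_names,
                 param_names = param_names, true_params = true_params,
                 kind = kind, dynamics = dynamics, obs_names = obs_names,
                 sample_interval = sample_interval,
                 state_deps = state_deps, param_deps = param_deps,
                 ic_sampler = ic_sampler, latent_init = latent_init,
                 substeps = as.integer(substeps), extra = extra),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec '%s'> %s, %d states (%s), %d parameters, h = %g\n",
              x$name, x$kind, length(x$state_names),
              paste(x$state_names, collapse = ","),
              length(x$param_names), x$sample_interval))
  invisible(x)
}

#' Uniformly sampled trajectory
#'
#' @param times numeric vector of strictly increasing, uniformly spaced times.
#' @param values matrix with one row per time point, one column per variable.
#' @param state_names column labels.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, values, state_names = colnames(values)) {
  values <- as.matrix(values)
  if (length(times) != nrow(values)) stop("times and values disagree in length")
  if (length(times) > 2) {
    dt <- diff(times)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-8 * max(abs(dt[1]), 1))
      stop("times must be strictly increasing with constant spacing")
  }
  colnames(values) <- state_names
  structure(list(times = as.numeric(times), values = values,
                 state_names = state_names), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples x %d variables (%s), t in [%g, %g]\n",
              nrow(x$values), ncol(x$values),
              paste(x$state_names, collapse = ","),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Network of coupled neurons
#'
#' Connection strengths for a Hindmarsh-Rose network. Self connections are
#' not allowed, so the diagonal is fixed at zero. Entry `adjacency[i, m]` is
#' the strength of the input that neuron `i` receives from neuron `m`.
#'
#' @param size number of neurons `M`.
#' @param adjacency `M x M` nonnegative matrix with zero diagonal.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(size, adjacency) {
  adjacency <- as.matrix(adjacency)
  stopifnot(nrow(adjacency) == size, ncol(adjacency) == size)
  if (any(diag(adjacency) != 0)) stop("self connections are not allowed (nonzero diagonal)")
  if (any(adjacency < 0)) stop("connection strengths must be nonnegative")
  structure(list(size = size, adjacency = adjacency), class = "network_spec")
}

#' Draw a random network
#'
#' Places `n_connections` directed connections uniformly at random (without
#' replacement) among the `M^2 - M` off-diagonal slots, each with the given
#' strength.
#'
#' @param size number of neurons.
#' @param n_connections number of nonzero off-diagonal entries.
#' @param strength connection strength assigned to each placed connection.
#' @return A [network_spec()].
#' @export
make_network <- function(size, n_connections, strength = 1) {
  slots <- which(diag(size) == 0)
  if (n_connections > length(slots)) stop("more connections than off-diagonal slots")
  a <- matrix(0, size, size)
  a[sample(slots, n_connections)] <- strength
  network_spec(size, a)
}

# ---------------------------------------------------------------------------
# Lorenz-63

lorenz63_dynamics <- function(t, X, P) {
  x <- X[1, ]; y <- X[2, ]; z <- X[3, ]
  s <- P[1, ]; r <- P[2, ]; b <- P[3, ]
  rbind(s * (y - x), x * (r - z) - y, x * y - b * z, deparse.level = 0)
}

#' Lorenz-63 vector field
#'
#' Evaluates the right-hand side of the Lorenz-63 system
#' \eqn{\dot x = \sigma(y - x)}, \eqn{\dot y = x(\rho - z) - y},
#' \eqn{\dot z = xy - \beta z}.
#'
#' @param state numeric 3-vector `(x, y, z)`.
#' @param params numeric 3-vector or named vector with `sigma`, `rho`, `beta`.
#' @return numeric 3-vector of time derivatives.
#' @export
lorenz63_rhs <- function(state, params) {
  p <- .named_or_positional(params, c("sigma", "rho", "beta"))
  drop(lorenz63_dynamics(0, matrix(state, 3), matrix(p, 3)))
}

.named_or_positional <- function(params, nm) {
  params <- unlist(params)
  if (!is.null(names(params)) && all(nm %in% names(params))) params[nm]
  else as.numeric(params[seq_along(nm)])
}

# ---------------------------------------------------------------------------
# Hindmarsh-Rose network
#
# States are grouped per neuron as (x_i, y_i, z_i). Parameter layout for the
# registry model: (a_1, b_1, c_1, ..., a_M, b_M, c_M) followed by the
# off-diagonal connection strengths beta_i_m in row-major order.

hr_param_names <- function(M) {
  nm <- as.vector(t(outer(seq_len(M), c("a", "b", "c"),
                          function(i, s) paste0(s, i))))
  betas <- character(0)
  for (i in seq_len(M)) for (m in seq_len(M)) if (i != m)
    betas <- c(betas, sprintf("beta%d_%d", i, m))
  c(nm, betas)
}

hr_dynamics_factory <- function(M) {
  beta_index <- matrix(0L, M, M)
  k <- 3L * M
  for (i in seq_len(M)) for (m in seq_len(M)) if (i != m) {
    k <- k + 1L
    beta_index[i, m] <- k
  }
  xi <- 3L * (seq_len(M) - 1L) + 1L
  function(t, X, P) {
    x <- X[xi, , drop = FALSE]
    y <- X[xi + 1L, , drop = FALSE]
    z <- X[xi + 2L, , drop = FALSE]
    g <- x / (1 + 9 * exp(-10 * x))      # sigmoidal gating of the voltage
    out <- X
    for (i in seq_len(M)) {
      coup <- 0
      for (m in seq_len(M)) if (m != i)
        coup <- coup + P[beta_index[i, m], ] * g[m, ]
      a <- P[3 * (i - 1) + 1, ]; b <- P[3 * (i - 1) + 2, ]
      cc <- P[3 * (i - 1) + 3, ]
      out[xi[i], ] <- y[i, ] - a * x[i, ]^3 + b * x[i, ]^2 - z[i, ] + 1.2 + coup
      out[xi[i] + 1L, ] <- 1 - cc * x[i, ]^2 - y[i, ]
      out[xi[i] + 2L, ] <- 5e-5 * (4 * (x[i, ] + 85) - z[i, ])
    }
    out
  }
}

#' Hindmarsh-Rose network vector field
#'
#' Right-hand side of a network of M Hindmarsh-Rose neurons. States are
#' ordered `(x_1, y_1, z_1, ..., x_M, y_M, z_M)`. Neurons are coupled through
#' the voltages by the sigmoidal gating term
#' \eqn{\beta_{im} x_m / (1 + 9 e^{-10 x_m})}, which transfers information
#' only when the presynaptic neuron is near spiking.
#'
#' @param states numeric `3M`-vector.
#' @param params list or vector with elements `a`, `b`, `c` (scalars recycled
#'   across neurons, or length-M vectors).
#' @param net a [network_spec()] holding the connection strengths.
#' @return numeric `3M`-vector of time derivatives.
#' @export
hindmarsh_rose_rhs <- function(states, params, net) {
  M <- net$size
  if (length(states) != 3 * M) stop("states length must be 3 * network size")
  a <- rep_len(.param_get(params, "a"), M)
  b <- rep_len(.param_get(params, "b"), M)
  cc <- rep_len(.param_get(params, "c"), M)
  pvec <- numeric(0)
  for (i in seq_len(M)) pvec <- c(pvec, a[i], b[i], cc[i])
  for (i in seq_len(M)) for (m in seq_len(M)) if (i != m)
    pvec <- c(pvec, net$adjacency[i, m])
  dyn <- hr_dynamics_factory(M)
  drop(dyn(0, matrix(states, 3 * M), matrix(pvec, length(pvec))))
}

.param_get <- function(params, nm) {
  if (!is.null(names(params)) && nm %in% names(params)) {
    if (is.list(params)) params[[nm]] else unname(params[names(params) == nm])
  } else stop(sprintf("parameter '%s' missing", nm))
}

# ---------------------------------------------------------------------------
# LPA flour beetle map

lpa_dynamics <- function(t, X, P) {
  L <- X[1, ]; Pp <- X[2, ]; A <- X[3, ]
  b <- P[1, ]; cel <- P[2, ]; cea <- P[3, ]; cpa <- P[4, ]
  mul <- P[5, ]; mua <- P[6, ]
  rbind(b * A * exp(-cel * L - cea * A),
        L * (1 - mul),
        Pp * exp(-cpa * A) + A * (1 - mua), deparse.level = 0)
}

#' One census step of the LPA map
#'
#' Advances larvae, pupae and adult counts by one census interval:
#' \eqn{L' = b A e^{-c_{el} L - c_{ea} A}}, \eqn{P' = L (1 - \mu_l)},
#' \eqn{A' = P e^{-c_{pa} A} + A (1 - \mu_a)}. Cannibalism of eggs by larvae
#' and adults enters through the exponential in the recruitment term, and
#' cannibalism of pupae by adults through the exponential survival of pupae.
#'
#' @param pop numeric 3-vector `(L, P, A)` of nonnegative stage counts.
#' @param params named vector/list with `b`, `cel`, `cea`, `cpa`, `mul`, `mua`.
#' @return numeric 3-vector, the populations one census later.
#' @export
lpa_step <- function(pop, params) {
  if (any(pop < 0)) stop("populations must be nonnegative")
  p <- .named_or_positional(params, c("b", "cel", "cea", "cpa", "mul", "mua"))
  if (any(p[5:6] < 0 | p[5:6] > 1)) stop("mortality fractions must lie in [0, 1]")
  drop(lpa_dynamics(0, matrix(pop, 3), matrix(p, 6)))
}

# ---------------------------------------------------------------------------
# Registry

#' Built-in model registry
#'
#' Returns a [model_spec()] for one of the built-in systems:
#' \describe{
#'   \item{`"lorenz63"`}{the chaotic Lorenz-63 flow with
#'     \eqn{\sigma = 10, \rho = 28, \beta = 8/3}, sampled at `h = 0.05`;
#'     all three variables observed.}
#'   \item{`"hindmarsh_rose"`}{a network of `M` Hindmarsh-Rose neurons
#'     sampled at `h = 0.08` ms with voltages `x_1..x_M` observed; pass a
#'     [network_spec()] via `net` (defaults to a random network with
#'     `n_connections` links of unit strength).}
#'   \item{`"lpa"`}{the discrete larvae-pupae-adult beetle map at the fitted
#'     parameters `b = 6.598, cel = 1.209e-2, cea = 1.155e-2, mul = 0.2055`
#'     with `mua = 0.96` and configurable recruitment-cannibalism rate
#'     `cpa`; census interval 1 (two weeks), all stages observed.}
#' }
#'
#' @param name model name.
#' @param net optional [network_spec()] (`"hindmarsh_rose"` only).
#' @param M network size (`"hindmarsh_rose"` only).
#' @param n_connections connections drawn when `net` is NULL.
#' @param cpa recruitment cannibalism rate (`"lpa"` only).
#' @return A [model_spec()].
#' @export
get_model <- function(name, net = NULL, M = 3, n_connections = 5, cpa = 0.35) {
  switch(name,
    lorenz63 = {
      sn <- c("x", "y", "z")
      model_spec("lorenz63", sn, c("sigma", "rho", "beta"),
                 c(sigma = 10, rho = 28, beta = 8 / 3), "continuous",
                 lorenz63_dynamics, obs_names = sn, sample_interval = 0.05,
                 state_deps = list(x = c("x", "y"), y = c("x", "y", "z"),
                                   z = c("x", "y", "z")),
                 param_deps = list(x = "sigma", y = "rho", z = "beta"),
                 ic_sampler = function()
                   c(stats::runif(1, -10, 10), stats::runif(1, -10, 10),
                     stats::runif(1, 10, 30)),
                 substeps = 10L)
    },
    hindmarsh_rose = {
      if (is.null(net)) net <- make_network(M, n_connections)
      M <- net$size
      sn <- as.vector(t(outer(seq_len(M), c("x", "y", "z"),
                              function(i, s) paste0(s, i))))
      pn <- hr_param_names(M)
      tp <- numeric(length(pn)); names(tp) <- pn
      tp[grep("^a", pn)] <- 1; tp[grep("^b[0-9]", pn)] <- 3
      tp[grep("^c", pn)] <- 5
      for (i in seq_len(M)) for (m in seq_len(M)) if (i != m)
        tp[sprintf("beta%d_%d", i, m)] <- net$adjacency[i, m]
      sdeps <- pdeps <- vector("list", length(sn)); names(sdeps) <- names(pdeps) <- sn
      xall <- paste0("x", seq_len(M))
      for (i in seq_len(M)) {
        sdeps[[paste0("x", i)]] <- unique(c(paste0(c("x", "y", "z"), i), xall))
        sdeps[[paste0("y", i)]] <- paste0(c("x", "y"), i)
        sdeps[[paste0("z", i)]] <- paste0(c("x", "z"), i)
        pdeps[[paste0("x", i)]] <- c(paste0(c("a", "b"), i),
                                     sprintf("beta%d_%d", i, setdiff(seq_len(M), i)))
        pdeps[[paste0("y", i)]] <- paste0("c", i)
        pdeps[[paste0("z", i)]] <- character(0)
      }
      model_spec("hindmarsh_rose", sn, pn, tp, "continuous",
                 hr_dynamics_factory(M), obs_names = xall,
                 sample_interval = 0.08, state_deps = sdeps, param_deps = pdeps,
                 ic_sampler = function() {
                   x <- stats::runif(M, -1.5, 0.5)
                   y <- 1 - 5 * x^2 + stats::runif(M, -1, 1)
                   z <- stats::runif(M, -4.5, -3.5)
                   as.vector(rbind(x, y, z))
                 },
                 latent_init = function(first_obs, params) {
                   out <- numeric(0)
                   for (i in seq_len(M)) {
                     x0 <- first_obs[paste0("x", i)]
                     v <- c(1 - params[paste0("c", i)] * x0^2, 0)
                     names(v) <- paste0(c("y", "z"), i)
                     out <- c(out, v)
                   }
                   out
                 },
                 substeps = 2L, extra = list(net = net))
    },
    lpa = {
      sn <- c("L", "P", "A")
      model_spec("lpa", sn, c("b", "cel", "cea", "cpa", "mul", "mua"),
                 c(b = 6.598, cel = 1.209e-2, cea = 1.155e-2, cpa = cpa,
                   mul = 0.2055, mua = 0.96), "discrete",
                 lpa_dynamics, obs_names = sn, sample_interval = 1,
                 state_deps = list(L = c("L", "A"), P = "L", A = c("P", "A")),
                 param_deps = list(L = c("b", "cel", "cea"), P = "mul",
                                   A = c("cpa", "mua")),
                 ic_sampler = function() c(250, 5, 100))
    },
    stop(sprintf("unknown model '%s'", name))
  )
}
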