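# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (plain loops, stats:: primitives) so that
# agreement is evidence, not tautology.

# Exhaustive-scan k-nearest-neighbour search: full distance vector, full
# sort, ties broken by the earlier row.
brute_knn <- function(query, vectors, kappa, eligible = rep(TRUE, nrow(vectors))) {
  d <- rep(Inf, nrow(vectors))
  for (r in which(eligible))
    d[r] <- sqrt(sum((vectors[r, ] - query)^2))
  ord <- order(d, seq_along(d))
  ord[seq_len(kappa)]
}

# Exact Kalman filter for x_{k+1} = A x_k + w, y_k = H x_k + v.
exact_kf <- function(obs, A, H, Q, R, m0, P0) {
  m <- m0
  P <- P0
  means <- matrix(NA_real_, length(obs), length(m0))
  for (k in seq_along(obs)) {
    mp <- drop(A %*% m)
    Pp <- A %*% P %*% t(A) + Q
    S <- H %*% Pp %*% t(H) + R
    K <- Pp %*% t(H) %*% solve(S)
    m <- mp + drop(K %*% (obs[k] - drop(H %*% mp)))
    P <- Pp - K %*% H %*% Pp
    means[k, ] <- m
  }
  means
}

# Two-pass mean/SD, computed without apply/colMeans shortcuts.
brute_mean_sd <- function(m) {
  out <- matrix(NA_real_, 2, ncol(m))
  for (j in seq_len(ncol(m))) {
    s <- 0
    for (i in seq_len(nrow(m))) s <- s + m[i, j]
    mu <- s / nrow(m)
    ss <- 0
    for (i in seq_len(nrow(m))) ss <- ss + (m[i, j] - mu)^2
    out[1, j] <- mu
    out[2, j] <- if (nrow(m) > 1) sqrt(ss / (nrow(m) - 1)) else 0
  }
  out
}

# Small deterministic Lorenz training set shared by several tests.
lorenz_fixture <- function(n = 300, noise_variance = 4, seed = 4242) {
  m <- get_model("lorenz63")
  td <- generate_training_data(m, n, noise_variance, seed = seed)
  list(model = m, clean = td$clean, noisy = td$noisy)
}
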