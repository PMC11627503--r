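# Shared fixtures and independent oracles for the test suite.

small_net <- function(n_x = 3, n_z = 4, seed = 1, money_unit = 1, ...) {
  vs_network(n_x = n_x, n_z = n_z, money_unit = money_unit, seed = seed, ...)
}

tiny_design <- function(n = 12, seed = 1, hi = 1) {
  withr::with_seed(seed, tibble::tibble(
    trial = seq_len(n), session = 1L,
    gain = runif(n, 0, hi), loss = runif(n, 0, hi))) |>
    dplyr::mutate(ev = (gain - loss) / 2)
}

# Pure-R sequential reference: forward_trial + plasticity_step, trial by trial.
# Oracle for the C++ engine.
r_adapt_sequence <- function(net, design, params) {
  delta <- matrix(0, 2 * net$n_x, net$n_z)
  V <- numeric(nrow(design))
  Z <- matrix(NA_real_, net$n_z, nrow(design))
  for (t in seq_len(nrow(design))) {
    ft <- forward_trial(net, design$gain[t], design$loss[t])
    V[t] <- ft$V
    Z[, t] <- ft$z
    if (params$alpha > 0 && params$beta > 0) {
      g <- infomax_innovation(ft$x, ft$z, net$int_sigma)
      st <- plasticity_step(net$C, delta, g, params)
      net$C <- st$C
      delta <- st$delta
    }
  }
  list(net = net, V = V, Z = Z)
}

# Finite-difference gradient of ln|df_z/dv(k)| w.r.t. each entry of C,
# holding the trial's attribute outputs fixed. Oracle for infomax_innovation.
fd_log_steepness_grad <- function(net, gain, loss, h = 1e-6) {
  xvec <- as.numeric(t(forward_trial(net, gain, loss)$x))
  log_steep <- function(C) {
    v <- drop(crossprod(C, xvec))
    z <- plogis((v - net$int_mu) / net$int_sigma)
    log(z * (1 - z) / net$int_sigma)   # length n_z
  }
  G <- matrix(NA_real_, length(xvec), net$n_z)
  for (i in seq_along(xvec)) for (k in seq_len(net$n_z)) {
    Cp <- net$C; Cm <- net$C
    Cp[i, k] <- Cp[i, k] + h
    Cm[i, k] <- Cm[i, k] - h
    G[i, k] <- (log_steep(Cp)[k] - log_steep(Cm)[k]) / (2 * h)
  }
  G
}

# Kozachenko-Leonenko nearest-neighbor entropy estimator (nats), brute force
# in row blocks. Oracle for the Gaussian entropy approximation.
knn_entropy <- function(X, block = 500) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  sq <- rowSums(X^2)
  nn <- numeric(n)
  for (i0 in seq(1, n, by = block)) {
    idx <- i0:min(i0 + block - 1, n)
    D2 <- outer(sq[idx], sq, `+`) - 2 * X[idx, , drop = FALSE] %*% t(X)
    D2[cbind(seq_along(idx), idx)] <- Inf
    nn[idx] <- sqrt(pmax(apply(D2, 1, min), 0))
  }
  log_c_d <- (d / 2) * log(pi) - lgamma(d / 2 + 1)
  digamma(n) - digamma(1) + log_c_d + d * mean(log(pmax(nn, 1e-300)))
}

# Brute-force per-pair RDM regression oracle (small n): builds each pair's
# row explicitly and solves by qr.
brute_encoding_slopes <- function(D, gains, losses) {
  n <- ncol(D)
  rows <- list()
  for (t2 in 2:n) for (t1 in 1:(t2 - 1)) {
    rows[[length(rows) + 1]] <-
      c(D[t2, t1], abs(gains[t2] - gains[t1]), abs(losses[t2] - losses[t1]))
  }
  M <- do.call(rbind, rows)
  qr.solve(cbind(1, M[, 2], M[, 3]), M[, 1])[2:3]
}

condition_grid_for_test <- function(n = 16) {
  tidyr::expand_grid(gain = seq(0, 1, length.out = n),
                     loss = seq(0, 1, length.out = n))
}
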