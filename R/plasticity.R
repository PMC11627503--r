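#' Plasticity parameters
#'
#' `alpha` is the magnitude of the gradient-following step on the information
#' loss and `beta` the exponential-decay rate of the moving-average operator
#' that tracks the steepness gradient across trials; together they set the
#' magnitude and temporal scale of self-organized plasticity. `alpha = 0` or
#' `beta = 0` switches plasticity off exactly (static value synthesis).
#'
#' @param alpha step magnitude, `>= 0`.
#' @param beta moving-average rate in `[0, 1]`.
#' @return A list of class `vs_plasticity`.
#' @export
plasticity_params <- function(alpha = 0.05, beta = 0.2) {
  if (alpha < 0) abort("`alpha` must be non-negative")
  if (beta < 0 || beta > 1) abort("`beta` must lie in [0, 1]")
  structure(list(alpha = alpha, beta = beta), class = "vs_plasticity")
}

#' Per-trial infomax innovation
#'
#' The gradient of the log-steepness `ln |df_z/dv(k)|` of each integration
#' unit's activation function with respect to each connection `C(i,j,k)`:
#' `g(i,j,k) = (1 - 2 z(k)) / sigma_z(k) * x(i,j)`. This is the anti-Hebbian
#' core of the plasticity rule: for a positively firing input unit, a
#' connection weakens exactly when the receiving unit is above its half-max
#' response (`z > 0.5`).
#'
#' @param x attribute outputs, as the flattened length-`2*n_x` vector (gain
#'   sublayer first) or the `2 x n_x` matrix from [forward_trial()].
#' @param z integration outputs, length `n_z`.
#' @param int_sigma integration-unit slopes, length `n_z`.
#' @return A `(2*n_x) x n_z` innovation matrix.
#' @export
infomax_innovation <- function(x, z, int_sigma) {
  if (is.matrix(x)) x <- as.numeric(t(x))
  outer(x, (1 - 2 * z) / int_sigma)
}

#' One step of the self-organized plasticity recursion
#'
#' `dC_t = alpha (1 - beta) dC_{t-1} + alpha beta g_t`, then `C <- C + dC_t`.
#' The recursion folds the exponentially weighted moving average of the
#' steepness gradient into a single momentum-like state, so no separate
#' average needs to be carried.
#'
#' @param C connectivity matrix.
#' @param delta_prev previous trial's connectivity change (`dC_{t-1}`),
#'   all-zero before the first trial.
#' @param innovation the [infomax_innovation()] matrix `g_t`.
#' @param params a [plasticity_params()].
#' @return A list with the updated `C` and the applied `delta`.
#' @export
plasticity_step <- function(C, delta_prev, innovation, params) {
  stopifnot(inherits(params, "vs_plasticity"))
  if (!all(dim(C) == dim(delta_prev)) || !all(dim(C) == dim(innovation)))
    abort("connectivity, state and innovation shapes must match")
  delta <- params$alpha * (1 - params$beta) * delta_prev +
    params$alpha * params$beta * innovation
  list(C = C + delta, delta = delta)
}

#' Run a network through a trial series under self-organized plasticity
#'
#' Sequentially applies the forward pass and the plasticity recursion to each
#' trial in order. Deterministic given the network, parameters and trial
#' order. Connectivity is the only adapted quantity; readout weights, bias
#' and all activation parameters stay fixed.
#'
#' @param net a [vs_network()].
#' @param design trial table with `gain`, `loss` columns, in presentation
#'   order (non-empty).
#' @param plasticity a [plasticity_params()].
#' @param input_gain optional length-2 multiplicative input gains.
#' @return A list: `net` (with adapted `C`), `values` tibble (design plus
#'   per-trial `value`), `Z`, `v`, `X` trial-by-trial activities (columns are
#'   trials), and `delta_norm`, the mean absolute connectivity change per
#'   trial.
#' @export
adapt_sequence <- function(net, design, plasticity, input_gain = c(1, 1)) {
  stopifnot(inherits(plasticity, "vs_plasticity"))
  if (nrow(design) == 0) abort("trial series is empty")
  U <- normalize_inputs(net, design$gain, design$loss)
  U <- sweep(U, 2L, input_gain, `*`)
  out <- ann_run_cpp(net$attr_mu, net$attr_sigma, net$int_mu, net$int_sigma,
                     net$C, net$w, net$bias, U,
                     plasticity$alpha, plasticity$beta, TRUE)
  net_out <- net
  net_out$C <- out$C
  list(net = net_out,
       values = dplyr::mutate(tibble::as_tibble(design), value = drop(out$V)),
       Z = out$Z, v = out$v, X = out$X,
       delta_norm = drop(out$delta_norm))
}

#' Tidy long-format activity trajectory
#'
#' Reshapes the `Z` (or `v`) matrix of an [adapt_sequence()] /
#' [ann_forward()] result into a long tibble `(trial, unit, quantity, value)`
#' for plotting and export.
#'
#' @param run an [adapt_sequence()] or [ann_forward()] result.
#' @param quantities subset of `c("z", "v")`.
#' @return A long tibble.
#' @export
activity_table <- function(run, quantities = c("z", "v")) {
  quantities <- match.arg(quantities, several.ok = TRUE)
  mats <- list(z = run$Z, v = run$v)[quantities]
  purrr::imap_dfr(mats, function(m, q) {
    tibble::tibble(trial = rep(seq_len(ncol(m)), each = nrow(m)),
                   unit = rep(seq_len(nrow(m)), ncol(m)),
                   quantity = q, value = as.numeric(m))
  })
}

#' Information loss of the integration layer (Gaussian approximation)
#'
#' At the small-noise limit, the information lost between noisy and noiseless
#' integration responses decomposes (up to additive constants) into the
#' negative entropy of the integration inputs plus the mean log-steepness of
#' the activation functions. The input entropy is approximated as Gaussian:
#' `entropy_term = ln det(C' S C) / 2` with `S` the sample covariance of the
#' attribute outputs; `steepness_term` is the sample mean of
#' `sum_k ln(z_k (1 - z_k) / sigma_z_k)`. The reported loss is
#' `-entropy_term - steepness_term`.
#'
#' @param X attribute-output samples, `n_samples x (2*n_x)` (columns in the
#'   flattened attribute-major order).
#' @param C connectivity matrix `(2*n_x) x n_z`.
#' @param int_mu,int_sigma integration-unit parameters.
#' @param ridge relative ridge added to the input covariance when it is
#'   numerically rank-deficient (times `trace/dim`).
#' @return A list of class `vs_infoloss`: `entropy_term`, `steepness_term`,
#'   `info_loss` (nats, up to constants), `S`, and a `ridged` flag.
#' @export
information_loss <- function(X, C, int_mu, int_sigma, ridge = 1e-8) {
  X <- as.matrix(X)
  if (nrow(X) < 2) abort("need at least 2 samples")
  S <- cov(X)
  Sv <- crossprod(C, S) %*% C          # covariance of integration inputs
  Sv <- (Sv + t(Sv)) / 2
  ev <- eigen(Sv, symmetric = TRUE, only.values = TRUE)$values
  ridged <- FALSE
  if (min(ev) <= ridge * max(ev)) {
    Sv <- Sv + diag(ridge * sum(diag(Sv)) / ncol(Sv), ncol(Sv))
    ev <- eigen(Sv, symmetric = TRUE, only.values = TRUE)$values
    ridged <- TRUE
  }
  entropy_term <- sum(log(ev)) / 2
  V <- X %*% C
  Z <- plogis(sweep(sweep(V, 2L, int_mu, `-`), 2L, int_sigma, `/`))
  steep <- sweep(log(pmax(Z * (1 - Z), 1e-300)), 2L, log(int_sigma), `-`)
  steepness_term <- mean(rowSums(steep))
  structure(list(entropy_term = entropy_term,
                 steepness_term = steepness_term,
                 info_loss = -entropy_term - steepness_term,
                 S = S, ridged = ridged),
            class = "vs_infoloss")
}

#' One adaptation step for attribute-layer units (alternative scenario)
#'
#' The competing efficient-coding account adapts the attribute-specific
#' layer instead of the attribute-to-integration wiring: each attribute
#' unit's threshold and log-slope take a gradient-ascent step on its own
#' log-steepness `ln |df_x/du|`, derived here by the same infomax principle
#' as the connectivity rule (this re-derivation is the package's own; only
#' its qualitative predictions are asserted):
#' `d mu = rate (2x - 1) / sigma` and
#' `d ln sigma = rate ((mu - u)(1 - 2x)/sigma - 1)`.
#'
#' @param attr_mu,attr_sigma `2 x n_x` attribute parameter matrices.
#' @param u length-2 normalized attribute inputs for the current trial.
#' @param rate positive step size.
#' @param sigma_min floor on slopes; hitting it raises a warning.
#' @return A list with updated `attr_mu`, `attr_sigma`.
#' @export
attribute_adaptation_step <- function(attr_mu, attr_sigma, u, rate,
                                      sigma_min = 1e-3) {
  if (rate <= 0) abort("`rate` must be positive")
  um <- matrix(u, nrow(attr_mu), ncol(attr_mu))
  x <- plogis((um - attr_mu) / attr_sigma)
  mu_new <- attr_mu + rate * (2 * x - 1) / attr_sigma
  dlns <- rate * ((attr_mu - um) * (1 - 2 * x) / attr_sigma - 1)
  sigma_new <- attr_sigma * exp(dlns)
  if (any(sigma_new < sigma_min)) {
    warn("attribute slope floored at `sigma_min`")
    sigma_new <- pmax(sigma_new, sigma_min)
  }
  list(attr_mu = mu_new, attr_sigma = sigma_new)
}

#' Run the attribute-layer adaptation scenario over a trial series
#'
#' Counterpart of [adapt_sequence()] for the alternative scenario: the
#' connectivity stays untouched while attribute units adapt. Used to contrast
#' the two accounts' predictions about how integration-layer encoding
#' strengths scale with attribute ranges.
#'
#' @inheritParams adapt_sequence
#' @param rate attribute adaptation step size.
#' @return A list: `net` (with adapted attribute parameters), `values`, `Z`.
#' @export
adapt_attributes_sequence <- function(net, design, rate = 0.005) {
  if (nrow(design) == 0) abort("trial series is empty")
  U <- normalize_inputs(net, design$gain, design$loss)
  n_t <- nrow(U)
  Z <- matrix(NA_real_, net$n_z, n_t)
  V <- numeric(n_t)
  mu <- net$attr_mu; sg <- net$attr_sigma
  for (t in seq_len(n_t)) {
    x <- plogis((matrix(U[t, ], 2L, net$n_x) - mu) / sg)
    v <- drop(crossprod(net$C, as.numeric(t(x))))
    z <- plogis((v - net$int_mu) / net$int_sigma)
    Z[, t] <- z
    V[t] <- sum(net$w * z)
    step <- suppressWarnings(
      attribute_adaptation_step(mu, sg, U[t, ], rate))
    mu <- step$attr_mu; sg <- step$attr_sigma
  }
  net_out <- net
  net_out$attr_mu <- mu; net_out$attr_sigma <- sg
  list(net = net_out,
       values = dplyr::mutate(tibble::as_tibble(design), value = V),
       Z = Z)
}
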