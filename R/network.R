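#' Construct a two-layer value-synthesis network
#'
#' The network maps a 50/50 gamble's prospective gain and loss onto a scalar
#' value through two layers of bounded (logistic-sigmoidal) units. Each of the
#' two attributes (gain, loss) feeds a dedicated sublayer of `n_x` units whose
#' thresholds tile the canonical unit input domain; their outputs are mixed by
#' a connectivity matrix `C` into `n_z` integration units, and value is read
#' out as a linear population code `V = sum(w * z)`.
#'
#' Money enters as positive magnitudes and is affinely normalized to the
#' canonical `[0, 1]` domain by dividing by `money_unit` (use 40 for the
#' dollar designs, where $40 is the largest amount either group can face;
#' use 1 when working directly on the unit domain).
#'
#' Attribute-unit thresholds are fixed at `(j - 1/2) / n_x` with slope
#' `1 / (2 n_x)` (half the tiling spacing); integration units default to
#' threshold 0 and slope 1, so that adaptation of `C` is what relocates and
#' rescales their inputs.
#'
#' @param n_x integer, units per attribute sublayer.
#' @param n_z integer, integration units.
#' @param money_unit positive scalar; gains and losses are divided by it.
#' @param int_mu,int_sigma integration-unit thresholds and slopes, recycled to
#'   length `n_z`; all slopes must be strictly positive.
#' @param C optional `(2*n_x) x n_z` connectivity matrix (rows ordered gain
#'   sublayer first, then loss sublayer). If `NULL`, all zeros.
#' @param w optional length-`n_z` readout weight vector (default zeros).
#' @param bias decision bias used by [choice_probability()].
#' @param c_scale when `seed` is given, `C` is drawn i.i.d. Gaussian with
#'   sd `c_scale / sqrt(2*n_x)`; the default puts a sizable share of initial
#'   integration inputs into the saturating range, the starting point the
#'   adaptation account presumes.
#' @param seed optional integer seed for the random `C` draw.
#' @return An object of class `vs_network`.
#' @examples
#' net <- vs_network(n_x = 4, n_z = 6, seed = 1)
#' forward_trial(net, gain = 0.5, loss = 0.25)$V
#' @export
vs_network <- function(n_x = 8, n_z = 16, money_unit = 1,
                       int_mu = 0, int_sigma = 1,
                       C = NULL, w = NULL, bias = 0,
                       c_scale = 6, seed = NULL) {
  stopifnot(n_x >= 1, n_z >= 1, money_unit > 0)
  n_in <- 2L * as.integer(n_x)
  attr_mu <- matrix(rep((seq_len(n_x) - 0.5) / n_x, each = 2L), nrow = 2L)
  attr_sigma <- matrix(1 / (2 * n_x), nrow = 2L, ncol = n_x)
  int_mu <- rep_len(int_mu, n_z)
  int_sigma <- rep_len(int_sigma, n_z)
  if (any(int_sigma <= 0)) abort("integration slopes must be strictly positive")
  if (is.null(C)) {
    if (!is.null(seed)) {
      C <- withr::with_seed(seed, matrix(rnorm(n_in * n_z, sd = c_scale / sqrt(n_in)),
                                         n_in, n_z))
    } else {
      C <- matrix(0, n_in, n_z)
    }
  }
  C <- as.matrix(C)
  if (is.null(w)) w <- rep(0, n_z)
  net <- structure(
    list(n_x = as.integer(n_x), n_z = as.integer(n_z),
         money_unit = money_unit,
         attr_mu = attr_mu, attr_sigma = attr_sigma,
         int_mu = as.numeric(int_mu), int_sigma = as.numeric(int_sigma),
         C = C, w = as.numeric(w), bias = as.numeric(bias)),
    class = "vs_network")
  validate_network(net)
}

validate_network <- function(net) {
  n_in <- 2L * net$n_x
  if (!identical(dim(net$C), c(n_in, net$n_z)))
    abort(sprintf("connectivity must be %d x %d", n_in, net$n_z))
  if (length(net$w) != net$n_z) abort("readout weights must have length n_z")
  if (any(net$attr_sigma <= 0) || any(net$int_sigma <= 0))
    abort("all slope parameters must be strictly positive")
  if (length(net$int_mu) != net$n_z || length(net$int_sigma) != net$n_z)
    abort("integration parameters must have length n_z")
  net
}

#' @export
print.vs_network <- function(x, ...) {
  cat(sprintf(
    "<vs_network> 2 x %d attribute units -> %d integration units (money unit %g)\n",
    x$n_x, x$n_z, x$money_unit))
  cat(sprintf("  |C| mean %.3f, readout %s, bias %.3f\n",
              mean(abs(x$C)),
              if (all(x$w == 0)) "untrained" else "trained", x$bias))
  invisible(x)
}

#' Logistic unit response
#'
#' Bounded sigmoidal activation `1 / (1 + exp((mu - u) / sigma))`: strictly
#' increasing in the input and confined to (0, 1), the model of a unit whose
#' firing rate saturates at a physiological ceiling.
#'
#' @param u input (vectorized).
#' @param mu threshold, in the same units as `u`.
#' @param sigma slope, strictly positive.
#' @return Values in (0, 1).
#' @examples
#' sigmoid_response(0.5, mu = 0.5, sigma = 0.1) # 0.5 at threshold
#' @export
sigmoid_response <- function(u, mu, sigma) {
  if (any(sigma <= 0)) abort("`sigma` must be strictly positive")
  plogis((u - mu) / sigma)
}

# Normalize dollar amounts to the canonical unit domain; errors outside it.
normalize_inputs <- function(net, gain, loss) {
  U <- cbind(gain, loss) / net$money_unit
  if (any(!is.finite(U)) || any(U < -1e-9) || any(U > 1 + 1e-9))
    abort("gains/losses fall outside the canonical [0, money_unit] domain")
  U
}

#' Forward pass for a single gamble
#'
#' Deterministically propagates one gamble through the network and returns all
#' layer activities: attribute outputs `x` (2 x n_x, rows gain/loss),
#' integration inputs `v`, integration outputs `z`, and the readout value `V`.
#'
#' @param net a [vs_network()].
#' @param gain,loss positive money magnitudes (same units as `money_unit`).
#' @return A list with elements `x`, `v`, `z`, `V`.
#' @export
forward_trial <- function(net, gain, loss) {
  stopifnot(length(gain) == 1, length(loss) == 1)
  u <- drop(normalize_inputs(net, gain, loss))
  x <- sigmoid_response(matrix(u, 2L, net$n_x), net$attr_mu, net$attr_sigma)
  xvec <- as.numeric(t(x))          # attribute-major: gain units then loss units
  v <- drop(crossprod(net$C, xvec))
  z <- sigmoid_response(v, net$int_mu, net$int_sigma)
  list(x = x, v = v, z = z, V = sum(net$w * z))
}

#' Forward pass over a whole trial design
#'
#' Evaluates the network on every row of a trial table, optionally applying
#' the self-organized plasticity recursion between trials (see
#' [adapt_sequence()] for the richer trajectory interface). Without
#' plasticity this is a pure, order-independent evaluation.
#'
#' @param net a [vs_network()].
#' @param design a data frame with `gain` and `loss` columns (dollar or unit
#'   magnitudes, matching the network's `money_unit`).
#' @param input_gain optional length-2 multiplicative gains applied to the
#'   normalized (gain, loss) inputs, used by the fitting module.
#' @return A list: `values` (the design tibble plus a `value` column), `Z`
#'   (`n_z x n_t` integration outputs), `v`, `X`, and the (unchanged) network.
#' @export
ann_forward <- function(net, design, input_gain = c(1, 1)) {
  U <- normalize_inputs(net, design$gain, design$loss)
  U <- sweep(U, 2L, input_gain, `*`)
  out <- ann_run_cpp(net$attr_mu, net$attr_sigma, net$int_mu, net$int_sigma,
                     net$C, net$w, net$bias, U, 0, 0, TRUE)
  list(values = dplyr::mutate(tibble::as_tibble(design), value = drop(out$V)),
       Z = out$Z, v = out$v, X = out$X, net = net)
}

#' Choice probability from synthesized value
#'
#' Accept probability `p = sigmoid(bias + V)` with unit slope; any behavioral
#' temperature is absorbed by the readout weights.
#'
#' @param value readout value(s) `V`.
#' @param bias decision bias (the behavioral intercept).
#' @return Probabilities in (0, 1).
#' @examples
#' choice_probability(0, 0) # indifference
#' @export
choice_probability <- function(value, bias = 0) plogis(bias + value)

#' Add Gaussian response noise to integration outputs
#'
#' Models uncontrollable neural noise competing with the utile component of
#' integration-unit responses: `z + eta` with `eta` i.i.d. `N(0, sd^2)`.
#'
#' @param z numeric vector or matrix of integration outputs.
#' @param sd noise standard deviation, `>= 0`.
#' @param seed optional integer seed for reproducibility.
#' @return Noisy responses with the same shape as `z`.
#' @export
add_response_noise <- function(z, sd, seed = NULL) {
  if (sd < 0) abort("`sd` must be non-negative")
  if (sd == 0) return(z)
  draw <- function() z + rnorm(length(z), sd = sd)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Receptive field of an integration unit over the gain/loss plane
#'
#' Evaluates one integration unit's output on a grid of (gain, loss) pairs.
#' Receptive fields are generically idiosyncratic (sums of shifted sigmoids),
#' and their deformation under plasticity is the mechanism behind apparent
#' value range adaptation.
#'
#' @param net a [vs_network()].
#' @param unit integration-unit index.
#' @param gains,losses grid node vectors (non-empty).
#' @return A tibble with columns `gain`, `loss`, `z`.
#' @export
receptive_field_map <- function(net, unit, gains, losses) {
  if (length(gains) == 0 || length(losses) == 0) abort("empty receptive-field grid")
  stopifnot(unit >= 1, unit <= net$n_z)
  grid <- tidyr::expand_grid(gain = gains, loss = losses)
  fwd <- ann_forward(net, grid)
  dplyr::mutate(grid, z = fwd$Z[unit, ])
}

#' Serialize a network to JSON (and back)
#'
#' Round-trippable JSON document holding every network field, so that
#' simulation configurations are fully reproducible from disk.
#'
#' @param net a [vs_network()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `network_to_json()`: the path (invisibly) or a JSON string;
#'   `network_from_json()`: a `vs_network`.
#' @export
network_to_json <- function(net, path = NULL) {
  doc <- list(n_x = net$n_x, n_z = net$n_z, money_unit = net$money_unit,
              attr_mu = net$attr_mu, attr_sigma = net$attr_sigma,
              int_mu = net$int_mu, int_sigma = net$int_sigma,
              C = net$C, w = net$w, bias = net$bias)
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname network_to_json
#' @param json a JSON string or file path produced by [network_to_json()].
#' @export
network_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  net <- vs_network(n_x = doc$n_x, n_z = doc$n_z, money_unit = doc$money_unit,
                    int_mu = doc$int_mu, int_sigma = doc$int_sigma,
                    C = matrix(doc$C, 2L * doc$n_x, doc$n_z),
                    w = doc$w, bias = doc$bias)
  net$attr_mu <- matrix(doc$attr_mu, 2L)
  net$attr_sigma <- matrix(doc$attr_sigma, 2L)
  validate_network(net)
}
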