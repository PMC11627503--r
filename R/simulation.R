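#' Range condition for a simulated gamble environment
#'
#' A spanned bidimensional gain/loss domain on the canonical unit scale:
#' `n_levels` evenly spaced levels per attribute between the interval bounds,
#' presented factorially. By convention simulated conditions share a lower
#' bound of 0 and vary their upper bounds in (0, 1]; "narrow" = upper bound
#' 0.5 and "wide" = upper bound 1 in the four-condition protocol.
#'
#' @param gain_hi,loss_hi upper bounds in (0, 1].
#' @param gain_lo,loss_lo lower bounds (default 0).
#' @param n_levels levels per attribute (default 16).
#' @param n_trials number of trials; must be a multiple of `n_levels^2`.
#' @return A list of class `vs_condition`.
#' @export
range_condition <- function(gain_hi, loss_hi, gain_lo = 0, loss_lo = 0,
                            n_levels = 16, n_trials = n_levels^2) {
  if (!(gain_lo < gain_hi) || !(loss_lo < loss_hi))
    abort("range bounds must satisfy lo < hi")
  if (gain_lo < 0 || loss_lo < 0 || gain_hi > 1 || loss_hi > 1)
    abort("ranges must lie within the canonical unit domain")
  if (n_trials %% n_levels^2 != 0)
    abort("`n_trials` must be a multiple of n_levels^2")
  structure(list(gain_range = c(gain_lo, gain_hi),
                 loss_range = c(loss_lo, loss_hi),
                 n_levels = as.integer(n_levels),
                 n_trials = as.integer(n_trials)),
            class = "vs_condition")
}

condition_levels <- function(condition) {
  list(gain = seq(condition$gain_range[1], condition$gain_range[2],
                  length.out = condition$n_levels),
       loss = seq(condition$loss_range[1], condition$loss_range[2],
                  length.out = condition$n_levels))
}

#' Full factorial gamble design for a range condition
#'
#' Every (gain level, loss level) pair appears equally often; the
#' presentation order is shuffled with the given seed. With 16 levels this is
#' the canonical 256-trial series.
#'
#' @param condition a [range_condition()].
#' @param seed integer seed for the order shuffle (`NULL`: current RNG).
#' @return A tibble with `trial`, `gain`, `loss`, `ev`, `session` columns.
#' @export
make_factorial_design <- function(condition, seed = NULL) {
  lv <- condition_levels(condition)
  grid <- tidyr::expand_grid(gain = lv$gain, loss = lv$loss)
  reps <- condition$n_trials / nrow(grid)
  grid <- dplyr::bind_rows(rep(list(grid), reps))
  shuffle <- function() grid[sample.int(nrow(grid)), ]
  grid <- if (is.null(seed)) shuffle() else withr::with_seed(seed, shuffle())
  dplyr::mutate(grid, ev = (.data$gain - .data$loss) / 2,
                trial = dplyr::row_number(), session = 1L,
                .before = 1L) |>
    dplyr::select("trial", "session", "gain", "loss", "ev")
}

# Unshuffled factorial grid (for readout training and landscape evaluation).
condition_grid <- function(condition) {
  lv <- condition_levels(condition)
  tidyr::expand_grid(gain = lv$gain, loss = lv$loss) |>
    dplyr::mutate(ev = (.data$gain - .data$loss) / 2)
}

#' Train the linear readout to expected value
#'
#' Least-squares readout weights minimizing `sum((V - EV)^2)` over a
#' reference grid, given the current connectivity: the network is "trained"
#' to output the gamble's expected value `EV = (G - L)/2` before plasticity
#' randomizes nothing further. The minimum-norm solution is used when the
#' integration features are rank-deficient (with a warning).
#'
#' @param net a [vs_network()].
#' @param design reference grid (defaults require passing a grid tibble with
#'   `gain`, `loss` columns); EV targets are recomputed from it.
#' @param value_scale optional multiplier applied to the trained weights;
#'   absorbs behavioral temperature when the network drives choices.
#' @return The network with trained `w`; attributes `readout_r2` and
#'   `readout_rank_deficient` record the fit.
#' @export
train_readout_to_ev <- function(net, design, value_scale = 1) {
  fwd <- ann_forward(net, design)
  Z <- t(fwd$Z)                         # n_grid x n_z
  ev <- (design$gain - design$loss) / 2
  sv <- svd(Z)
  tol <- max(dim(Z)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  if (!all(pos)) warn("integration features are rank-deficient; minimum-norm readout used")
  w <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], ev)) / sv$d[pos])
  fitted <- drop(Z %*% w)
  net$w <- drop(w) * value_scale
  attr(net, "readout_r2") <- 1 - sum((ev - fitted)^2) / sum((ev - mean(ev))^2)
  attr(net, "readout_rank_deficient") <- !all(pos)
  net
}

#' Monte-Carlo runs of one range condition
#'
#' For each run: draw a fresh random connectivity, train the readout to EV on
#' the condition's grid, freeze it, then let the network self-organize over a
#' freshly shuffled factorial trial series. The adapted (steady-state)
#' network is then evaluated once on the unshuffled grid, giving
#' order-aligned integration patterns for binning and encoding analyses.
#'
#' @param condition a [range_condition()].
#' @param plasticity a [plasticity_params()] (`alpha = 0` gives the static
#'   control: summaries then equal those of the initial network).
#' @param n_runs number of Monte-Carlo runs (the headline protocol uses 1000;
#'   analyses in this package's tests use 100 for tractability).
#' @param seed integer seed governing all runs.
#' @param n_x,n_z,c_scale network construction parameters.
#' @param scenario `"value_synthesis"` adapts the connectivity (the efficient
#'   value synthesis rule); `"attribute_coding"` adapts the attribute layer
#'   instead (the alternative efficient-coding account).
#' @param rate attribute-layer step size (only for `"attribute_coding"`).
#' @return A list of runs; each has `net0`, `net`, `Z` (adapted network's
#'   integration outputs on the grid), `grid`, `delta_norm`, and `Z0`
#'   (pre-adaptation outputs).
#' @export
run_condition <- function(condition, plasticity, n_runs = 1000, seed = 1,
                          n_x = 8, n_z = 16, c_scale = 6,
                          scenario = c("value_synthesis", "attribute_coding"),
                          rate = 0.005) {
  scenario <- match.arg(scenario)
  grid <- condition_grid(condition)
  withr::with_seed(seed, {
    purrr::map(seq_len(n_runs), function(r) {
      net0 <- vs_network(n_x = n_x, n_z = n_z,
                         C = matrix(rnorm(2 * n_x * n_z,
                                          sd = c_scale / sqrt(2 * n_x)),
                                    2 * n_x, n_z))
      net0 <- train_readout_to_ev(net0, grid)
      design <- make_factorial_design(condition)
      fwd0 <- ann_forward(net0, grid)
      if (scenario == "value_synthesis") {
        run <- adapt_sequence(net0, design, plasticity)
        delta_norm <- run$delta_norm
      } else {
        run <- adapt_attributes_sequence(net0, design, rate = rate)
        delta_norm <- NULL
      }
      fwd <- ann_forward(run$net, grid)
      list(net0 = net0, net = run$net, grid = grid,
           Z0 = fwd0$Z, Z = fwd$Z, V = fwd$values$value,
           delta_norm = delta_norm)
    })
  })
}

#' EV-binned mean unit response curves
#'
#' Pools integration units by the sign of their correlation with EV
#' (`+EV` / `-EV` classes), bins trials into equal-width EV bins within the
#' realized EV range, and returns the per-bin mean response of each class.
#' Units with response variance below `min_var` are excluded; an empty sign
#' class yields a flagged empty result.
#'
#' @param Z `n_z x n_t` integration outputs.
#' @param design trial table aligned with the columns of `Z` (needs `ev`).
#' @param n_bins number of EV bins (`>= 2`), default 9.
#' @param min_var variance floor for including a unit.
#' @return A tibble `(class, bin, ev_mid, response, n_units)`.
#' @export
ev_binned_unit_curves <- function(Z, design, n_bins = 9, min_var = 1e-8) {
  if (n_bins < 2) abort("need at least 2 EV bins")
  ev <- if ("ev" %in% names(design)) design$ev else (design$gain - design$loss) / 2
  keep <- apply(Z, 1L, var) >= min_var
  if (!any(keep)) abort("all units are (numerically) constant")
  Zk <- Z[keep, , drop = FALSE]
  cls <- ifelse(apply(Zk, 1L, function(z) cor(z, ev)) >= 0, "+EV", "-EV")
  brk <- seq(min(ev), max(ev), length.out = n_bins + 1)
  bin <- cut(ev, breaks = brk, include.lowest = TRUE, labels = FALSE)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  out <- purrr::map_dfr(c("+EV", "-EV"), function(cl) {
    zz <- Zk[cls == cl, , drop = FALSE]
    if (nrow(zz) == 0)
      return(tibble::tibble(class = cl, bin = integer(), ev_mid = numeric(),
                            response = numeric(), n_units = integer()))
    resp <- vapply(seq_len(n_bins),
                   function(b) mean(zz[, bin == b, drop = FALSE]), numeric(1))
    tibble::tibble(class = cl, bin = seq_len(n_bins), ev_mid = mids,
                   response = resp, n_units = nrow(zz))
  })
  attr(out, "empty_class") <- setdiff(c("+EV", "-EV"), unique(out$class[out$n_units > 0]))
  out
}

#' Behavioral sensitivities of the readout value landscape
#'
#' Ordinary least-squares regression of the synthesized value on gain and on
#' minus-loss (plus intercept) over a condition's factorial grid. The slopes
#' are the behavioral sensitivities; their ratio `sens_loss / sens_gain` is
#' the loss-aversion ratio (flagged missing unless both are positive). A
#' network emitting exactly `V = EV` gives sensitivities 0.5 / 0.5, ratio 1.
#'
#' @param x either a [vs_network()] (then `condition` is required) or a data
#'   frame with `gain`, `loss`, `value` columns.
#' @param condition a [range_condition()] defining the evaluation grid.
#' @return A one-row tibble `(sens_gain, sens_loss, loss_aversion_ratio,
#'   ratio_ok)`.
#' @export
behavioral_sensitivities <- function(x, condition = NULL) {
  if (inherits(x, "vs_network")) {
    if (is.null(condition)) abort("`condition` is required with a network")
    grid <- condition_grid(condition)
    x <- ann_forward(x, grid)$values
  }
  fit <- lm(value ~ gain + I(-loss), data = x)
  b <- coef(fit)
  sens_gain <- unname(b["gain"]); sens_loss <- unname(b["I(-loss)"])
  ok <- is.finite(sens_gain) && is.finite(sens_loss) && sens_gain > 0 && sens_loss > 0
  tibble::tibble(sens_gain = sens_gain, sens_loss = sens_loss,
                 loss_aversion_ratio = ifelse(ok, sens_loss / sens_gain, NA_real_),
                 ratio_ok = ok)
}

#' Sweep a grid of gain/loss range conditions
#'
#' For every combination of gain and loss upper bounds (all lower bounds 0),
#' runs `n_runs` Monte-Carlo adaptations and summarizes, per condition:
#' neural encoding strengths of gain, loss (joint regression on the
#' integration-layer RDM) and EV (separate regression), behavioral
#' sensitivities and the loss-aversion ratio — each averaged over runs.
#'
#' @param gain_his,loss_his vectors of upper bounds in (0, 1].
#' @param plasticity a [plasticity_params()].
#' @param n_runs Monte-Carlo runs per condition.
#' @param seed integer seed.
#' @param n_levels levels per attribute.
#' @param scenario passed to [run_condition()].
#' @param ... further arguments to [run_condition()].
#' @return A tibble, one row per condition cell, with columns `gain_hi`,
#'   `loss_hi`, `enc_gain`, `enc_loss`, `enc_ev`, `sens_gain`, `sens_loss`,
#'   `loss_aversion_ratio`, `n_runs`, `seed`.
#' @export
range_grid_sweep <- function(gain_his, loss_his, plasticity, n_runs = 100,
                             seed = 1, n_levels = 16,
                             scenario = "value_synthesis", ...) {
  cells <- tidyr::expand_grid(gain_hi = gain_his, loss_hi = loss_his)
  purrr::pmap_dfr(cells, function(gain_hi, loss_hi) {
    cond <- range_condition(gain_hi, loss_hi, n_levels = n_levels)
    cell_seed <- seed + round(1e4 * gain_hi) + round(1e2 * loss_hi)
    runs <- run_condition(cond, plasticity, n_runs = n_runs, seed = cell_seed,
                          scenario = scenario, ...)
    per_run <- purrr::map_dfr(runs, function(run) {
      D <- compute_rdm(run$Z)
      enc <- attribute_encoding_strength(D, run$grid$gain, run$grid$loss)
      ev_enc <- ev_encoding_strength(D, run$grid$ev)
      sens <- behavioral_sensitivities(
        dplyr::mutate(run$grid, value = run$V))
      tibble::tibble(
        enc_gain = enc$estimate[enc$term == "gain_distance"],
        enc_loss = enc$estimate[enc$term == "loss_distance"],
        enc_ev = ev_enc$estimate[ev_enc$term == "ev_distance"],
        sens_gain = sens$sens_gain, sens_loss = sens$sens_loss)
    })
    out <- dplyr::summarise(per_run,
                            dplyr::across(dplyr::everything(),
                                          ~ mean(.x, na.rm = TRUE)))
    # ratio of run-averaged sensitivities (ratios of per-run noisy
    # sensitivities are upward-biased); missing unless both are positive
    dplyr::mutate(out,
                  loss_aversion_ratio = ifelse(
                    .data$sens_gain > 0 & .data$sens_loss > 0,
                    .data$sens_loss / .data$sens_gain, NA_real_),
                  gain_hi = gain_hi, loss_hi = loss_hi,
                  n_runs = n_runs, seed = cell_seed, .before = 1L)
  })
}

#' Classify integration units as choice / chosen-value / offer-value cells
#'
#' Labels each unit by the significance of its across-trial correlation with
#' the binary choice (point-biserial), the chosen value (gamble value if
#' accepted, 0 if rejected), and the gamble (offer) value. Classes may
#' overlap, as they do for real orbitofrontal neurons; constant units are
#' unclassified.
#'
#' @param Z `n_z x n_t` integration outputs.
#' @param accept binary choices (0/1), length `n_t`.
#' @param gamble_value per-trial gamble value (e.g. `wG*G - wL*L` from a
#'   static logistic fit).
#' @param chosen_value per-trial chosen value; default `gamble_value * accept`.
#' @param alpha_level per-test significance level.
#' @return A list: `units` (per-unit tibble of correlations, p-values and
#'   labels) and `proportions` (fraction of units in each class and
#'   unclassified).
#' @export
classify_value_cells <- function(Z, accept, gamble_value,
                                 chosen_value = gamble_value * accept,
                                 alpha_level = 0.05) {
  n_t <- ncol(Z)
  if (n_t < 20) abort("need at least 20 trials to classify units")
  cor_p <- function(z, y) {
    if (var(z) < 1e-12 || var(y) < 1e-12) return(c(NA_real_, NA_real_))
    r <- cor(z, y)
    tv <- r * sqrt((n_t - 2) / max(1 - r^2, 1e-12))
    c(r, 2 * pt(abs(tv), n_t - 2, lower.tail = FALSE))
  }
  units <- purrr::map_dfr(seq_len(nrow(Z)), function(k) {
    z <- Z[k, ]
    ch <- cor_p(z, accept); cv <- cor_p(z, chosen_value); ov <- cor_p(z, gamble_value)
    tibble::tibble(unit = k,
                   r_choice = ch[1], p_choice = ch[2],
                   r_chosen = cv[1], p_chosen = cv[2],
                   r_offer = ov[1], p_offer = ov[2])
  })
  units <- dplyr::mutate(units,
    choice_cell = !is.na(.data$p_choice) & .data$p_choice < alpha_level,
    chosen_value_cell = !is.na(.data$p_chosen) & .data$p_chosen < alpha_level,
    offer_value_cell = !is.na(.data$p_offer) & .data$p_offer < alpha_level,
    unclassified = !(.data$choice_cell | .data$chosen_value_cell | .data$offer_value_cell))
  props <- dplyr::summarise(units,
    choice_cell = mean(.data$choice_cell),
    chosen_value_cell = mean(.data$chosen_value_cell),
    offer_value_cell = mean(.data$offer_value_cell),
    unclassified = mean(.data$unclassified))
  list(units = units, proportions = props)
}

#' Behavioral consistency under integration-layer noise
#'
#' For each noise level, the probability that the choice implied by the noisy
#' value (`sign(bias + V + w'eta)`) matches the noiseless choice, averaged
#' over trials and noise replicates. Comparing an adapted with a static
#' network quantifies the behavioral resilience that range adaptation buys.
#'
#' @param nets named list of [vs_network()] objects (e.g.
#'   `list(adapted = ..., static = ...)`).
#' @param design trial table for evaluation.
#' @param sds non-negative noise standard deviations (on `z`).
#' @param n_reps noise replicates per trial.
#' @param seed integer seed.
#' @return A tibble `(variant, sd, consistency)`.
#' @export
noise_robustness_curve <- function(nets, design, sds, n_reps = 100, seed = 1) {
  if (any(sds < 0)) abort("noise sds must be non-negative")
  withr::with_seed(seed, {
    purrr::imap_dfr(nets, function(net, nm) {
      V <- ann_forward(net, design)$values$value
      eta_scale <- sqrt(sum(net$w^2))   # w'eta ~ N(0, sd^2 * sum(w^2))
      choice0 <- (net$bias + V) > 0
      purrr::map_dfr(sds, function(s) {
        if (s == 0) return(tibble::tibble(variant = nm, sd = 0, consistency = 1))
        noisy <- matrix(rnorm(length(V) * n_reps, sd = s * eta_scale),
                        length(V), n_reps) + (net$bias + V)
        tibble::tibble(variant = nm, sd = s,
                       consistency = mean((noisy > 0) == choice0))
      })
    })
  })
}
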