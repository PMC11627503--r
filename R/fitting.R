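#' Configuration for fitting value-synthesis networks to choices
#'
#' The free parameters are the decision bias, the readout weights, two
#' per-attribute input gains (log scale), and — for the plastic variant —
#' the plasticity magnitude and rate on the logit scale. The initial
#' connectivity `C0` is NOT fitted: it is a fixed random draw from a
#' subject-specific seed, with the input gains and readout providing the
#' flexible value landscape (an identifiability-driven choice). Priors are
#' zero-mean Gaussians on bias, readout and log input gains, and
#' logit-normals centered at `logit(0.1)` for the plasticity parameters.
#'
#' @param n_starts seeded multi-starts (the first start initializes the
#'   readout at the EV-trained solution, the rest perturb it).
#' @param n_x,n_z,money_unit,c_scale network construction parameters; must
#'   match the generating network when used for parameter recovery.
#' @param prior_sd_b,prior_sd_w,prior_sd_loggain prior sds.
#' @param prior_mu_plast,prior_sd_plast logit-scale prior on alpha and beta.
#' @param fix_beta optional known plasticity rate: when supplied, the plastic
#'   variant frees only the magnitude (used by recovery harnesses, where the
#'   magnitude/rate product is the identified quantity and the rate is known
#'   by construction).
#' @param max_iter BFGS iteration cap per start.
#' @param reltol BFGS relative convergence tolerance.
#' @param seed integer seed for the multi-start draws.
#' @return A list of class `vs_fit_config`.
#' @export
fit_config <- function(n_starts = 8, n_x = 8, n_z = 16, money_unit = 40,
                       c_scale = 6, prior_sd_b = 2, prior_sd_w = 2,
                       prior_sd_loggain = 0.5,
                       prior_mu_plast = qlogis(0.1), prior_sd_plast = 2,
                       fix_beta = NULL, max_iter = 200, reltol = 1e-8,
                       seed = 1) {
  structure(list(n_starts = n_starts, n_x = n_x, n_z = n_z,
                 money_unit = money_unit, c_scale = c_scale,
                 prior_sd_b = prior_sd_b, prior_sd_w = prior_sd_w,
                 prior_sd_loggain = prior_sd_loggain,
                 prior_mu_plast = prior_mu_plast,
                 prior_sd_plast = prior_sd_plast,
                 fix_beta = fix_beta, max_iter = max_iter,
                 reltol = reltol, seed = seed),
            class = "vs_fit_config")
}

# Unpack a free-parameter vector. Layout: b, w (n_z), logGainG, logGainL,
# then (plastic only) logit-alpha, logit-beta.
unpack_theta <- function(theta, n_z, plastic, fix_beta = NULL) {
  out <- list(b = theta[1], w = theta[2:(n_z + 1)],
              input_gain = exp(theta[(n_z + 2):(n_z + 3)]))
  if (plastic) {
    out$alpha <- plogis(theta[n_z + 4])
    out$beta <- if (is.null(fix_beta)) plogis(theta[n_z + 5]) else fix_beta
  } else {
    out$alpha <- 0
    out$beta <- 0
  }
  out
}

ann_neg_logpost <- function(theta, net, U0, choice, config, plastic) {
  p <- unpack_theta(theta, net$n_z, plastic, config$fix_beta)
  U <- sweep(U0, 2L, p$input_gain, `*`)
  nll <- ann_nll_cpp(net$attr_mu, net$attr_sigma, net$int_mu, net$int_sigma,
                     net$C, p$w, p$b, U, p$alpha, p$beta, choice)
  free_plast <- if (plastic) {
    if (is.null(config$fix_beta)) (net$n_z + 4):(net$n_z + 5) else net$n_z + 4
  } else integer()
  prior <- p$b^2 / (2 * config$prior_sd_b^2) +
    sum(p$w^2) / (2 * config$prior_sd_w^2) +
    sum(theta[(net$n_z + 2):(net$n_z + 3)]^2) / (2 * config$prior_sd_loggain^2)
  if (length(free_plast) > 0) {
    prior <- prior + sum((theta[free_plast] - config$prior_mu_plast)^2) /
      (2 * config$prior_sd_plast^2)
  }
  nll + prior
}

#' Fit a value-synthesis network to a subject's choice series
#'
#' Maximum-a-posteriori fit of the sequential model: at each trial the
#' network's (possibly plasticity-updated) value drives
#' `p = sigmoid(b + V)`, and the Bernoulli log-likelihood of the observed
#' accept/reject series plus the log prior is maximized by seeded
#' multi-start BFGS. The static variant pins `alpha = beta = 0` and removes
#' them from the free set, making it an exact nested special case of the
#' plastic variant. Deterministic given the config seed and net seed.
#'
#' @param data trial table with `gain`, `loss`, `accept` (missing responses
#'   allowed) in presentation order; at least 64 usable trials.
#' @param config a [fit_config()].
#' @param variant `"plastic"` or `"static"`.
#' @param net_seed subject-specific seed fixing `C0`.
#' @param subject_id optional label carried into the result.
#' @return An object of class `vs_ann_fit`: MAP `estimates` (`b`, `w`,
#'   `input_gain`, `alpha`, `beta`), the negative log-likelihood and
#'   log-posterior at the optimum, per-trial postdicted `p`, per-start
#'   objective values, and convergence flags. [tidy()] and [glance()]
#'   methods are provided.
#' @export
fit_ann_to_choices <- function(data, config, variant = c("plastic", "static"),
                               net_seed = 1, subject_id = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "vs_fit_config"))
  if (sum(is.finite(data$accept)) < 64)
    abort("need at least 64 non-missing trials")
  plastic <- variant == "plastic"
  beta_free <- plastic && is.null(config$fix_beta)
  net <- vs_network(n_x = config$n_x, n_z = config$n_z,
                    money_unit = config$money_unit, c_scale = config$c_scale,
                    seed = net_seed)
  U0 <- normalize_inputs(net, data$gain, data$loss)
  choice <- ifelse(is.finite(data$accept), data$accept, -1)
  n_par <- net$n_z + 3L + (if (plastic) 1L else 0L) + (if (beta_free) 1L else 0L)
  # EV-trained readout as the informed base; plastic starts additionally
  # tile the (alpha, beta) plane, since the likelihood is ridged along
  # alpha*beta and a single init tends to stall on the ridge
  w_ev <- train_readout_to_ev(net, dplyr::distinct(data[, c("gain", "loss")]))$w
  base <- c(0, w_ev, 0, 0,
            if (plastic) config$prior_mu_plast,
            if (beta_free) config$prior_mu_plast)
  plast_grid <- if (beta_free) {
    list(qlogis(c(0.01, 0.2)), qlogis(c(0.05, 0.2)), qlogis(c(0.2, 0.2)),
         qlogis(c(0.02, 0.4)), qlogis(c(0.1, 0.1)))
  } else {
    list(qlogis(0.01), qlogis(0.03), qlogis(0.1), qlogis(0.3))
  }
  starts <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_starts), function(s) {
      th0 <- base
      if (s > 1) th0 <- th0 + rnorm(n_par, sd = 0.3)
      if (plastic && s <= length(plast_grid))
        th0[(net$n_z + 4):n_par] <- plast_grid[[s]]
      th0
    })
  })
  fits <- lapply(starts, function(th0) {
    optim(th0, ann_neg_logpost, method = "BFGS",
          control = list(maxit = config$max_iter, reltol = config$reltol),
          net = net, U0 = U0, choice = choice, config = config,
          plastic = plastic)
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  est <- unpack_theta(best$par, net$n_z, plastic, config$fix_beta)
  net$w <- est$w
  net$bias <- est$b
  U <- sweep(U0, 2L, est$input_gain, `*`)
  run <- ann_run_cpp(net$attr_mu, net$attr_sigma, net$int_mu, net$int_sigma,
                     net$C, est$w, est$b, U, est$alpha, est$beta, TRUE)
  nll <- ann_nll_cpp(net$attr_mu, net$attr_sigma, net$int_mu, net$int_sigma,
                     net$C, est$w, est$b, U, est$alpha, est$beta, choice)
  structure(list(
    estimates = est, theta = best$par, variant = variant,
    nll = nll, neg_logpost = best$value, start_values = vals,
    p = drop(run$p), Z = run$Z,
    converged = best$convergence == 0,
    all_converged = all(vapply(fits, `[[`, numeric(1), "convergence") == 0),
    net = net, config = config, net_seed = net_seed,
    subject_id = subject_id, data = tibble::as_tibble(data)),
    class = "vs_ann_fit")
}

#' @export
print.vs_ann_fit <- function(x, ...) {
  cat(sprintf("<vs_ann_fit %s> n=%d  nll=%.2f  alpha=%.3f beta=%.3f b=%.3f%s\n",
              x$variant, nrow(x$data), x$nll, x$estimates$alpha,
              x$estimates$beta, x$estimates$b,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @method tidy vs_ann_fit
#' @export
tidy.vs_ann_fit <- function(x, ...) {
  est <- x$estimates
  tibble::tibble(
    term = c("bias", "input_gain_G", "input_gain_L", "alpha", "beta",
             paste0("w", seq_along(est$w))),
    estimate = c(est$b, est$input_gain, est$alpha, est$beta, est$w))
}

#' @method glance vs_ann_fit
#' @export
glance.vs_ann_fit <- function(x, ...) {
  pd <- postdict(x)
  tibble::tibble(variant = x$variant, nll = x$nll,
                 neg_logpost = x$neg_logpost,
                 balanced_accuracy = pd$balanced_accuracy,
                 variance_explained = pd$variance_explained,
                 alpha = x$estimates$alpha, beta = x$estimates$beta,
                 converged = x$converged, nobs = nrow(x$data))
}

#' Postdiction: model agreement with its own fitted data
#'
#' Sequential simulation with the fitted parameters on the fitted trial
#' series, summarized as balanced accuracy (predictions thresholded at 0.5)
#' and variance explained (`100 * cor(p, choice)^2`).
#'
#' @param model a [fit_ann_to_choices()] result.
#' @return A one-row tibble `(balanced_accuracy, variance_explained)` with
#'   the per-trial probabilities in the `p` attribute.
#' @export
postdict <- function(model) {
  g <- model$data$accept
  keep <- is.finite(g)
  out <- tibble::tibble(
    balanced_accuracy = as.numeric(balanced_accuracy(model$p[keep], g[keep])),
    variance_explained = 100 * cor(model$p[keep], g[keep])^2)
  attr(out, "p") <- model$p
  out
}

#' Counterfactual cross-context prediction
#'
#' Resets the plasticity state to its fitted initial condition and runs the
#' fitted model forward on a trial series from the other context, with no
#' parameter re-adjustment. For static variants the predicted probability
#' for any shared (gain, loss) pair is identical across contexts; plastic
#' variants re-adapt to the new attribute ranges.
#'
#' @param model a [fit_ann_to_choices()] result.
#' @param other_design trial table from the other context (must share the
#'   money normalization; amounts outside the canonical domain error).
#' @return The design tibble plus a `p_accept` column.
#' @export
counterfactual_predict <- function(model, other_design) {
  net <- model$net
  est <- model$estimates
  U <- normalize_inputs(net, other_design$gain, other_design$loss)
  U <- sweep(U, 2L, est$input_gain, `*`)
  run <- ann_run_cpp(net$attr_mu, net$attr_sigma, net$int_mu, net$int_sigma,
                     net$C, est$w, est$b, U, est$alpha, est$beta, FALSE)
  dplyr::mutate(tibble::as_tibble(other_design), p_accept = drop(run$p))
}

#' Mean absolute out-of-sample prediction error
#'
#' `mean(|p_t - g_t|)` over non-missing trials.
#'
#' @param p predicted acceptance probabilities.
#' @param g observed 0/1 choices (missing allowed).
#' @return A scalar in `[0, 1]`.
#' @export
out_of_sample_error <- function(p, g) {
  if (length(p) != length(g)) abort("prediction and choice series differ in length")
  keep <- is.finite(p) & is.finite(g)
  mean(abs(p[keep] - g[keep]))
}

#' Postdicted loss-aversion dynamics
#'
#' Sliding-window logistic refits on the model's postdicted acceptance
#' probabilities, mirroring the behavioral sliding-window analysis. A static
#' model yields a flat series; a plastic model fitted to range-adapting
#' behavior reproduces the drift.
#'
#' @param model a [fit_ann_to_choices()] result.
#' @param window window length in trials.
#' @return A tibble as from [sliding_window_loss_aversion()].
#' @export
postdicted_lambda_series <- function(model, window = 16) {
  d <- dplyr::mutate(model$data, accept = model$p)
  sliding_window_loss_aversion(d, window = window)
}

#' Parameter recovery on a synthetic cohort
#'
#' Fits the plastic variant to every subject of a [gen_cohort()] table
#' (reusing each subject's connectivity seed) and reports truth-vs-estimate
#' correlations and biases for the plasticity magnitude, rate and bias.
#'
#' @param cohort a [gen_cohort()] tibble.
#' @param config a [fit_config()]; its network dimensions must match the
#'   cohort's generating agents.
#' @return A list: `subjects` (per-subject truth and estimates) and
#'   `summary` (correlation and mean bias per parameter).
#' @export
parameter_recovery <- function(cohort, config) {
  subjects <- purrr::pmap_dfr(
    cohort[, c("subject_id", "alpha", "beta", "bias", "net_seed", "choices")],
    function(subject_id, alpha, beta, bias, net_seed, choices) {
      fit <- fit_ann_to_choices(choices, config, variant = "plastic",
                                net_seed = net_seed, subject_id = subject_id)
      tibble::tibble(subject_id = subject_id,
                     alpha_true = alpha, beta_true = beta, bias_true = bias,
                     alpha_est = fit$estimates$alpha,
                     beta_est = fit$estimates$beta,
                     bias_est = fit$estimates$b,
                     nll = fit$nll, converged = fit$converged)
    })
  summary <- tibble::tibble(
    parameter = c("alpha", "beta", "bias"),
    correlation = c(cor(subjects$alpha_true, subjects$alpha_est),
                    cor(subjects$beta_true, subjects$beta_est),
                    cor(subjects$bias_true, subjects$bias_est)),
    mean_bias = c(mean(subjects$alpha_est - subjects$alpha_true),
                  mean(subjects$beta_est - subjects$beta_true),
                  mean(subjects$bias_est - subjects$bias_true)))
  list(subjects = subjects, summary = summary)
}
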