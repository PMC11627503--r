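#' Two-group gamble design specification
#'
#' The narrow-range design crosses 16 gain levels with 16 loss levels, both
#' $5–$20 in $1 steps; the wide-range design doubles the gain levels
#' ($10–$40 in $2 steps) while keeping the same losses. All 16 x 16 = 256
#' combinations are presented exactly once, in seeded random order, split
#' into contiguous equal sessions.
#'
#' @param group `"narrow"` or `"wide"`.
#' @param n_sessions number of equal contiguous sessions (default 4).
#' @param seed integer seed for the trial-order shuffle.
#' @return A list of class `vs_design_spec`.
#' @export
group_design_spec <- function(group = c("narrow", "wide"), n_sessions = 4,
                              seed = 1) {
  group <- match.arg(group)
  gains <- if (group == "narrow") 5:20 else seq(10, 40, by = 2)
  structure(list(group = group, gain_levels = gains, loss_levels = 5:20,
                 n_trials = 256L, n_sessions = as.integer(n_sessions),
                 money_unit = 40, seed = seed),
            class = "vs_design_spec")
}

#' Generate a trial table from a design specification
#'
#' @param spec a [group_design_spec()].
#' @return A tibble `(trial, session, gain, loss, ev)` of 256 gambles.
#' @export
gen_group_design <- function(spec) {
  stopifnot(inherits(spec, "vs_design_spec"))
  grid <- tidyr::expand_grid(gain = spec$gain_levels, loss = spec$loss_levels)
  grid <- withr::with_seed(spec$seed, grid[sample.int(nrow(grid)), ])
  per_sess <- spec$n_trials / spec$n_sessions
  dplyr::mutate(grid,
                trial = dplyr::row_number(),
                session = as.integer(ceiling(.data$trial / per_sess)),
                ev = (.data$gain - .data$loss) / 2) |>
    dplyr::select("trial", "session", "gain", "loss", "ev")
}

#' Ground-truth range-adapting agent
#'
#' A plastic value-synthesis network that stands in for a participant:
#' random initial connectivity (seeded), readout trained to the expected
#' value over the agent's own design grid (then frozen), a decision bias,
#' and self-organized plasticity with the given magnitude and rate. With
#' `value_scale = 1` the pre-adaptation agent is a noisy EV maximizer whose
#' value is in dollars; larger scales sharpen (cool) its choices.
#'
#' @param spec the agent's [group_design_spec()].
#' @param alpha,beta plasticity magnitude and rate (0 for a static agent).
#' @param bias decision bias (logit units).
#' @param value_scale multiplier on the trained readout weights.
#' @param n_x,n_z,c_scale network construction parameters.
#' @param seed integer seed for the connectivity draw.
#' @return A list of class `vs_agent` (`net`, `plasticity`, `spec`).
#' @export
value_agent <- function(spec, alpha = 0.02, beta = 0.2, bias = 0,
                        value_scale = 1, n_x = 8, n_z = 16, c_scale = 6,
                        seed = 1) {
  net <- vs_network(n_x = n_x, n_z = n_z, money_unit = spec$money_unit,
                    bias = bias, c_scale = c_scale, seed = seed)
  grid <- tidyr::expand_grid(gain = spec$gain_levels, loss = spec$loss_levels)
  net <- train_readout_to_ev(net, grid, value_scale = value_scale)
  structure(list(kind = "plastic_ann", net = net,
                 plasticity = plasticity_params(alpha, beta),
                 spec = spec, seed = seed),
            class = "vs_agent")
}

#' Drifting-logistic ground-truth agent
#'
#' A model-free chooser `p = sigmoid(w0 + wG*G - wL(t)*L)` whose loss
#' sensitivity follows a programmed trajectory, used to validate the
#' sliding-window analyses (e.g. a loss-aversion index drifting linearly
#' from `lambda_start` to `lambda_end` over the session).
#'
#' @param w0 intercept.
#' @param wG gain sensitivity (logit per $).
#' @param lambda_start,lambda_end loss-aversion index at the first and last
#'   trial; `wL(t) = wG * exp(lambda(t))` interpolates linearly in lambda.
#' @param n_trials length of the trajectory.
#' @return A list of class `vs_agent`.
#' @export
drifting_logistic_agent <- function(w0 = 0, wG = 0.3, lambda_start = 0.25,
                                    lambda_end = 0.41, n_trials = 256) {
  lam <- seq(lambda_start, lambda_end, length.out = n_trials)
  structure(list(kind = "drifting_logistic", w0 = w0, wG = wG,
                 wL = wG * exp(lam), lambda = lam),
            class = "vs_agent")
}

#' Simulate a choice series from a ground-truth agent
#'
#' Sequential Bernoulli draws from the agent's acceptance probability; for
#' plastic network agents the plasticity state evolves across trials (the
#' value trajectory does not depend on the sampled choices). The four-level
#' response is synthesized by splitting accept/reject at `|p - 0.5| >= 0.25`
#' (strong vs weak).
#'
#' @param agent a [value_agent()] or [drifting_logistic_agent()].
#' @param design trial table (`gain`, `loss`, in the agent's money units).
#' @param seed integer seed for the choice draws.
#' @return The design tibble plus `p_accept`, `accept` and `response`
#'   columns.
#' @export
simulate_choices <- function(agent, design, seed = NULL) {
  stopifnot(inherits(agent, "vs_agent"))
  if (agent$kind == "plastic_ann") {
    run <- adapt_sequence(agent$net, design, agent$plasticity)
    p <- choice_probability(run$values$value, agent$net$bias)
  } else {
    n <- nrow(design)
    if (length(agent$wL) < n) abort("drifting agent trajectory shorter than design")
    p <- plogis(agent$w0 + agent$wG * design$gain - agent$wL[seq_len(n)] * design$loss)
  }
  draw <- function() rbinom(length(p), 1L, p)
  accept <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  strong <- abs(p - 0.5) >= 0.25
  response <- dplyr::case_when(
    accept == 1 & strong ~ "strongly_accept",
    accept == 1 ~ "weakly_accept",
    accept == 0 & strong ~ "strongly_reject",
    TRUE ~ "weakly_reject")
  dplyr::mutate(tibble::as_tibble(design), p_accept = p, accept = accept,
                response = response)
}

#' Generate a synthetic two-group cohort
#'
#' Emulates the two-study design: `n_per_group` subjects per group, each
#' with a fresh trial-order shuffle of their group's 256 gambles and a
#' range-adapting agent whose parameters are drawn from documented
#' hyperpriors (`alpha ~ U[0.01, 0.04]`, `beta ~ U[0.1, 0.3]`,
#' `bias ~ N(0, 0.3)` by default; the magnitudes are on this rule's own
#' scale, where unit integration slopes make single-trial innovations large).
#'
#' @param n_per_group subjects per group (`>= 2`).
#' @param hyper list with `alpha` and `beta` ranges and `bias_sd`; set an
#'   `alpha` range of `c(0, 0)` for a cohort of static agents.
#' @param value_scale agent readout scaling.
#' @param seed integer master seed; the cohort is a pure function of it.
#' @param n_sessions sessions per subject.
#' @param paired when `TRUE`, subject i of the wide group is the "twin" of
#'   subject i of the narrow group (same connectivity seed, plasticity
#'   parameters and bias), so between-group contrasts isolate the context.
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `alpha`, `beta`, `bias`, `net_seed`, and list-columns `design`,
#'   `choices`.
#' @export
gen_cohort <- function(n_per_group = 54,
                       hyper = list(alpha = c(0.01, 0.04),
                                    beta = c(0.1, 0.3), bias_sd = 0.3),
                       value_scale = 1, seed = 1, n_sessions = 4,
                       paired = FALSE) {
  if (n_per_group < 2) abort("need at least 2 subjects per group")
  withr::with_seed(seed, {
    subj_par <- purrr::map(seq_len(n_per_group * 2), function(i) {
      list(net_seed = sample.int(2^30, 1),
           a = runif(1, hyper$alpha[1], hyper$alpha[2]),
           b = runif(1, hyper$beta[1], hyper$beta[2]),
           bias = rnorm(1, 0, hyper$bias_sd))
    })
    purrr::map_dfr(c("narrow", "wide"), function(grp) {
      purrr::map_dfr(seq_len(n_per_group), function(i) {
        k <- if (paired) i else i + (grp == "wide") * n_per_group
        par <- subj_par[[k]]
        sid <- sprintf("%s-%02d", grp, i)
        spec <- group_design_spec(grp, n_sessions = n_sessions,
                                  seed = sample.int(2^30, 1))
        agent <- value_agent(spec, alpha = par$a, beta = par$b,
                             bias = par$bias, value_scale = value_scale,
                             seed = par$net_seed)
        design <- gen_group_design(spec)
        choices <- simulate_choices(agent, design, seed = sample.int(2^30, 1))
        tibble::tibble(subject_id = sid, group = grp, alpha = par$a,
                       beta = par$b, bias = par$bias, net_seed = par$net_seed,
                       design = list(design), choices = list(choices))
      })
    })
  })
}

#' Synthetic multivoxel trial patterns from integration activity
#'
#' Stands in for ROI trial-wise activity patterns: voxels linearly mix the
#' integration-layer outputs through a seeded random mixing matrix, receive
#' per-session offsets, and AR(1) noise across trials scaled per voxel so
#' that `var(signal) / var(noise) = snr^2`.
#'
#' @param Z `n_z x n_t` integration outputs.
#' @param n_vox number of synthetic voxels.
#' @param snr signal-to-noise ratio (`> 0`).
#' @param sessions session label per trial.
#' @param ar1 AR(1) coefficient of the trial-wise noise (`|ar1| < 1`).
#' @param offset_sd sd of per-voxel, per-session offsets, in units of the
#'   average signal sd.
#' @param seed integer seed.
#' @return An `n_vox x n_t` matrix with attributes `sessions` and
#'   `source = "synthetic"`.
#' @export
gen_voxel_patterns <- function(Z, n_vox = 100, snr = 1,
                               sessions = rep(1L, ncol(Z)), ar1 = 0.5,
                               offset_sd = 1, seed = 1) {
  if (snr <= 0) abort("`snr` must be positive")
  if (abs(ar1) >= 1) abort("`ar1` must lie strictly inside (-1, 1)")
  n_z <- nrow(Z); n_t <- ncol(Z)
  withr::with_seed(seed, {
    M <- matrix(rnorm(n_vox * n_z), n_vox, n_z)
    signal <- M %*% Z
    sig_sd <- pmax(apply(signal, 1L, sd), 1e-12)
    offs <- matrix(rnorm(n_vox * length(unique(sessions)),
                         sd = offset_sd * mean(sig_sd)),
                   n_vox)
    colnames(offs) <- unique(sessions)
    noise <- t(vapply(seq_len(n_vox), function(v) {
      e <- numeric(n_t)
      e[1] <- rnorm(1)
      innov_sd <- sqrt(1 - ar1^2)       # unit marginal variance
      for (t in 2:n_t) e[t] <- ar1 * e[t - 1] + rnorm(1, sd = innov_sd)
      e * sig_sd[v] / snr
    }, numeric(n_t)))
    Y <- signal + offs[, as.character(sessions), drop = FALSE] + noise
    structure(Y, sessions = sessions, source = "synthetic")
  })
}

.response_map <- c(strongly_accept = 1, weakly_accept = 1,
                   weakly_reject = 0, strongly_reject = 0, NoResp = NA)

#' Write / read gamble events tables
#'
#' The native dialect is a single TSV with columns `onset`, `duration`,
#' `gain`, `loss`, `response`, `session` (responses in the four-level
#' vocabulary plus `NoResp`); round trips are lossless. The `narps` dialect
#' reads one TSV per run (columns `onset`, `duration`, `gain`, `loss`,
#' `participant_response`), concatenating files in run order with the run
#' index as session label, and maps weak/strong accepts to `accept = 1` and
#' `NoResp` to missing.
#'
#' @param choices a [simulate_choices()] table (needs `gain`, `loss`,
#'   `response`, `session`).
#' @param path output file path.
#' @param iti,duration trial spacing and event duration written as onsets
#'   (seconds).
#' @return `write_events_tsv()`: the path, invisibly. `read_events_tsv()`:
#'   a tibble `(trial, session, gain, loss, ev, response, accept)`.
#' @export
write_events_tsv <- function(choices, path, iti = 7, duration = 4) {
  stopifnot(all(c("gain", "loss", "response", "session") %in% names(choices)))
  tab <- choices |>
    dplyr::group_by(.data$session) |>
    dplyr::mutate(onset = (dplyr::row_number() - 1) * iti,
                  duration = duration) |>
    dplyr::ungroup() |>
    dplyr::select("onset", "duration", "gain", "loss", "response", "session")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param paths one file (native) or per-run files in run order (narps).
#' @param dialect `"native"` or `"narps"`.
#' @export
read_events_tsv <- function(paths, dialect = c("native", "narps")) {
  dialect <- match.arg(dialect)
  resp_col <- if (dialect == "native") "response" else "participant_response"
  tabs <- purrr::imap(paths, function(p, run) {
    tab <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    need <- c("onset", "duration", "gain", "loss", resp_col)
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols) > 0)
      abort(sprintf("events file lacks required column(s): %s",
                    paste(missing_cols, collapse = ", ")))
    if (dialect == "narps") tab$session <- as.integer(run)
    if (!"session" %in% names(tab)) tab$session <- 1L
    tab
  })
  tab <- dplyr::bind_rows(tabs)
  resp <- as.character(tab[[resp_col]])
  unknown <- setdiff(unique(resp), names(.response_map))
  if (length(unknown) > 0)
    abort(sprintf("unknown response token(s): %s", paste(unknown, collapse = ", ")))
  tibble::tibble(trial = seq_len(nrow(tab)),
                 session = as.integer(tab$session),
                 gain = tab$gain, loss = tab$loss,
                 ev = (tab$gain - tab$loss) / 2,
                 response = resp,
                 accept = unname(.response_map[resp]))
}
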