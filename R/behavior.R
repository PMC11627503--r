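#' Within-subject choice logistic regression
#'
#' Maximum-likelihood fit of `p(accept) = sigmoid(w0 + wG*G - wL*L)` (losses
#' entered as positive magnitudes, hence the minus sign) via iteratively
#' reweighted least squares. Missing responses are excluded trial-wise. When
#' the unpenalized fit diverges (perfect separation, or a single response
#' class), the model is refitted as a MAP estimate under independent
#' zero-mean Gaussian priors (sd `ridge_sd`) on each coefficient and flagged.
#'
#' The response may also be a probability series (e.g. model postdictions);
#' the same quasi-likelihood machinery then yields postdicted sensitivities.
#'
#' @param data data frame with `gain`, `loss` and `accept` (0/1 or
#'   probability; `NA` = missing response) columns.
#' @param min_trials minimum number of usable trials.
#' @param ridge_sd prior sd of the separation fallback.
#' @return An object of class `vs_logistic` with coefficients `w0`, `wG`,
#'   `wL`, their covariance, the loss-aversion index `lambda = log(wL/wG)`
#'   (missing unless both sensitivities are positive), fitted probabilities
#'   and `converged`/`ridged`/`degenerate` flags. [tidy()] and [glance()]
#'   methods are provided.
#' @export
fit_choice_logistic <- function(data, min_trials = 10, ridge_sd = 10) {
  keep <- stats::complete.cases(data[, c("gain", "loss", "accept")])
  d <- data[keep, ]
  if (nrow(d) < min_trials) abort(sprintf("fewer than %d usable trials", min_trials))
  X <- cbind(`(Intercept)` = 1, gain = d$gain, neg_loss = -d$loss)
  y <- d$accept
  binary <- all(y %in% c(0, 1))
  degenerate <- binary && length(unique(y)) < 2
  beta <- NULL; vc <- matrix(NA_real_, 3, 3); converged <- FALSE; ridged <- FALSE
  if (!degenerate) {
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    converged <- isTRUE(fit$converged) && max(abs(fit$coefficients)) < 50
    if (converged) {
      beta <- fit$coefficients
      W <- fit$weights
      XtWX <- crossprod(X * sqrt(W))
      vc <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, 3, 3))
    }
  }
  if (is.null(beta)) {                   # ridge MAP fallback
    ridged <- TRUE
    obj <- function(b) {
      eta <- drop(X %*% b)
      sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + sum(b^2) / (2 * ridge_sd^2)
    }
    gr <- function(b) {
      p <- plogis(drop(X %*% b))
      drop(crossprod(X, p - y)) + b / ridge_sd^2
    }
    opt <- optim(c(0, 0, 0), obj, gr, method = "BFGS", hessian = TRUE)
    beta <- opt$par
    vc <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA_real_, 3, 3))
    converged <- opt$convergence == 0
  }
  names(beta) <- c("w0", "wG", "wL")    # wL is the coefficient on -L
  dimnames(vc) <- list(names(beta), names(beta))
  lambda_ok <- beta["wG"] > 0 && beta["wL"] > 0
  structure(list(
    coefficients = beta, vcov = vc,
    lambda = if (lambda_ok) unname(log(beta["wL"] / beta["wG"])) else NA_real_,
    lambda_reason = if (lambda_ok) NA_character_ else "non-positive sensitivity",
    fitted = plogis(drop(X %*% beta)),
    accept = y, nobs = nrow(d),
    converged = converged, ridged = ridged, degenerate = degenerate),
    class = "vs_logistic")
}

#' @export
print.vs_logistic <- function(x, ...) {
  cat(sprintf("<vs_logistic> n=%d  w0=%.3f wG=%.3f wL=%.3f  lambda=%.3f%s\n",
              x$nobs, x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$lambda,
              if (x$ridged) " [ridged]" else if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @method tidy vs_logistic
#' @export
tidy.vs_logistic <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  est <- x$coefficients
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se), statistic = unname(est / se),
                 p.value = 2 * stats::pnorm(abs(unname(est / se)), lower.tail = FALSE))
}

#' @method glance vs_logistic
#' @export
glance.vs_logistic <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, nobs = x$nobs, converged = x$converged,
                 ridged = x$ridged, degenerate = x$degenerate,
                 balanced_accuracy = if (all(x$accept %in% c(0, 1)))
                   balanced_accuracy(x$fitted, x$accept) else NA_real_)
}

#' Loss-aversion index
#'
#' `lambda = log(wL / wG)`, the log ratio of loss to gain sensitivity.
#' Because any behavioral temperature rescales all logistic coefficients by
#' the same positive constant, the index is temperature-invariant. Missing
#' (with a reason) unless both sensitivities are positive.
#'
#' @param fit a [fit_choice_logistic()] result.
#' @return A scalar (possibly `NA` with a `"reason"` attribute).
#' @export
loss_aversion_index <- function(fit) {
  out <- fit$lambda
  if (is.na(out)) attr(out, "reason") <- fit$lambda_reason
  out
}

#' Balanced accuracy of choice predictions
#'
#' Mean of sensitivity and specificity, in percent, with predictions
#' thresholded at `p >= 0.5`. When one observed class is absent, the
#' accuracy on the present class is returned and flagged.
#'
#' @param p predicted acceptance probabilities (or a `vs_logistic` fit, whose
#'   fitted values are used).
#' @param accept observed 0/1 choices.
#' @return A percentage (attribute `one_class` flags a missing class).
#' @export
balanced_accuracy <- function(p, accept) {
  if (inherits(p, "vs_logistic")) {
    accept <- p$accept
    p <- p$fitted
  }
  keep <- is.finite(p) & is.finite(accept)
  p <- p[keep]; accept <- accept[keep]
  pred <- as.integer(p >= 0.5)
  if (length(unique(accept)) < 2) {
    out <- 100 * mean(pred == accept)
    attr(out, "one_class") <- TRUE
    return(out)
  }
  sens <- mean(pred[accept == 1] == 1)
  spec <- mean(pred[accept == 0] == 0)
  100 * (sens + spec) / 2
}

#' Sliding-window loss-aversion series
#'
#' Partitions the trial series into consecutive non-overlapping windows
#' (default 16 trials: a 256-trial session gives 16 windows), fits the choice
#' logistic within each, and returns the per-window coefficient and
#' loss-aversion series. A trailing remainder is dropped with a warning;
#' windows under 8 trials are refused as unidentifiable.
#'
#' @param data trial table with `gain`, `loss`, `accept` in presentation
#'   order.
#' @param window window length in trials.
#' @return A tibble `(window, w0, wG, wL, lambda, ridged)`.
#' @export
sliding_window_loss_aversion <- function(data, window = 16) {
  if (window < 8) abort("windows shorter than 8 trials are unidentifiable")
  n <- nrow(data)
  n_win <- n %/% window
  if (n %% window != 0) warn("trailing trials beyond the last full window dropped")
  purrr::map_dfr(seq_len(n_win), function(wi) {
    d <- data[((wi - 1) * window + 1):(wi * window), ]
    fit <- fit_choice_logistic(d, min_trials = min(8, window))
    tibble::tibble(window = wi, w0 = fit$coefficients["w0"],
                   wG = fit$coefficients["wG"], wL = fit$coefficients["wL"],
                   lambda = fit$lambda, ridged = fit$ridged)
  })
}

#' Acceptance rate by within-subject EV decile
#'
#' Bins trials by deciles of expected value within the subject and returns
#' the per-bin acceptance rate. Heavy EV ties collapse duplicate quantile
#' breaks; the result is flagged when fewer than 10 bins survive.
#'
#' @param data trial table with `gain`, `loss` (or `ev`) and `accept`.
#' @param n_bins number of quantile bins (default 10).
#' @return A tibble `(bin, ev_mid, accept_rate, n)`; attribute `merged_bins`
#'   flags collapsed deciles.
#' @export
ev_decile_curve <- function(data, n_bins = 10) {
  ev <- if ("ev" %in% names(data)) data$ev else (data$gain - data$loss) / 2
  keep <- is.finite(ev) & is.finite(data$accept)
  if (sum(keep) < 10) abort("need at least 10 usable trials")
  ev <- ev[keep]; accept <- data$accept[keep]
  brk <- unique(quantile(ev, probs = seq(0, 1, length.out = n_bins + 1)))
  merged <- length(brk) < n_bins + 1
  bin <- cut(ev, breaks = brk, include.lowest = TRUE, labels = FALSE)
  out <- tibble::tibble(ev = ev, accept = accept, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(ev_mid = median(.data$ev),
                     accept_rate = mean(.data$accept), n = dplyr::n(),
                     .groups = "drop")
  attr(out, "merged_bins") <- merged
  out
}

#' One-way two-group F test
#'
#' Pooled-variance one-way F test of a group difference — exactly the square
#' of the pooled two-sample t statistic, with `dof = n1 + n2 - 2` (e.g. 101
#' for groups of 54 and 49).
#'
#' @param x,y numeric vectors (one per group, each `n >= 2`).
#' @return A one-row tibble `(f, df1, df2, p, zero_variance)`.
#' @export
group_f_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) abort("need at least 2 values per group")
  n1 <- length(x); n2 <- length(y)
  df2 <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df2
  if (sp2 == 0)
    return(tibble::tibble(f = NA_real_, df1 = 1L, df2 = df2, p = NA_real_,
                          zero_variance = TRUE))
  f <- (mean(x) - mean(y))^2 / (sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(f = f, df1 = 1L, df2 = df2,
                 p = pf(f, 1, df2, lower.tail = FALSE), zero_variance = FALSE)
}

#' Trials within the EV range common to two designs
#'
#' Marks trials whose expected value lies in the intersection of two
#' designs' EV ranges, computed from the design specifications (for the
#' narrow/wide dollar designs: `[-7.5, 7.5] ∩ [-5, 17.5] = [-5, 7.5]`).
#'
#' @param ev per-trial expected values.
#' @param design_a,design_b either length-2 numeric EV ranges or trial tables
#'   with an `ev` (or `gain`/`loss`) column.
#' @return A logical vector.
#' @export
common_ev_mask <- function(ev, design_a, design_b) {
  rng <- function(d) {
    if (is.numeric(d) && length(d) == 2) return(sort(d))
    e <- if ("ev" %in% names(d)) d$ev else (d$gain - d$loss) / 2
    range(e)
  }
  a <- rng(design_a); b <- rng(design_b)
  lo <- max(a[1], b[1]); hi <- min(a[2], b[2])
  if (lo > hi) abort("the two designs' EV ranges do not intersect")
  ev >= lo & ev <= hi
}
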