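#' Remove between-session offsets from a trial pattern matrix
#'
#' Projects each unit's (or voxel's) trial series onto the null space of a
#' categorical session-encoding design matrix — equivalently, removes each
#' unit's within-session mean. Idempotent; with a single session it returns
#' the input unchanged with a warning.
#'
#' @param Y `n_units x n_trials` pattern matrix.
#' @param sessions session label per trial (length `n_trials`).
#' @return The corrected matrix.
#' @export
project_out_sessions <- function(Y, sessions) {
  Y <- as.matrix(Y)
  if (length(sessions) != ncol(Y)) abort("one session label per trial is required")
  if (length(unique(sessions)) < 2) {
    warn("only one session: projection is the identity")
    return(Y)
  }
  for (s in unique(sessions)) {
    idx <- sessions == s
    Y[, idx] <- Y[, idx, drop = FALSE] - rowMeans(Y[, idx, drop = FALSE])
  }
  Y
}

#' Representational dissimilarity matrix of trial patterns
#'
#' `D[t, t'] = 1 - cor(Y[, t], Y[, t'])` (Pearson), a symmetric zero-diagonal
#' matrix with raw entries in `[0, 2]`. By construction the RDM is invariant
#' to affine transformations of individual trial patterns. Constant trial
#' patterns yield flagged missing entries.
#'
#' @param Y `n_units x n_trials` pattern matrix with `n_units >= 2`.
#' @return A `vs_rdm` matrix (attributes record correction provenance).
#' @export
compute_rdm <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2) abort("need at least 2 units to correlate patterns")
  const <- apply(Y, 2L, function(p) var(p) < 1e-24)
  D <- 1 - suppressWarnings(cor(Y))
  if (any(const)) {
    D[const, ] <- NA_real_
    D[, const] <- NA_real_
  }
  diag(D) <- 0
  structure(D, class = c("vs_rdm", "matrix"),
            corrected = FALSE, provenance = character(),
            flagged_constant = which(const))
}

#' Remove per-delay mean dissimilarity (temporal autocorrelation confound)
#'
#' For each possible delay `d = |t - t'|` between trial pairs, subtracts the
#' mean dissimilarity at that delay. Afterwards every per-delay mean is zero,
#' so slow trends in the trial series cannot masquerade as attribute coding;
#' because gains and losses are randomized across trials, their structure
#' survives the correction. Corrected entries may be negative.
#'
#' @param rdm a [compute_rdm()] matrix.
#' @param order trial indices defining delay (default `1:n_t`).
#' @return The corrected `vs_rdm`.
#' @export
delay_detrend <- function(rdm, order = seq_len(ncol(rdm))) {
  D <- unclass(rdm)
  n <- ncol(D)
  delay <- abs(outer(order, order, `-`))
  for (d in unique(delay[delay > 0])) {
    idx <- delay == d
    D[idx] <- D[idx] - mean(D[idx], na.rm = TRUE)
  }
  diag(D) <- 0
  structure(D, class = c("vs_rdm", "matrix"),
            corrected = TRUE,
            provenance = c(attr(rdm, "provenance"), "delay_detrend"),
            flagged_constant = attr(rdm, "flagged_constant"))
}

rdm_lower <- function(D) {
  D <- unclass(D)
  D[lower.tri(D)]
}

#' Neural encoding strength of gains and losses
#'
#' Regresses the vectorized lower triangle of the RDM jointly on the absolute
#' pairwise differences in gains and in losses (plus an intercept). The
#' slopes — dissimilarity per unit attribute difference — are the encoding
#' strengths. Standard errors are nominal: pair entries are not independent.
#'
#' @param rdm a [compute_rdm()] matrix (corrected or raw).
#' @param gains,losses per-trial attribute values aligned with the RDM.
#' @return A tibble `(term, estimate, std.error, n_pairs, collinear)`.
#' @export
attribute_encoding_strength <- function(rdm, gains, losses) {
  y <- rdm_lower(rdm)
  dg <- rdm_lower(abs(outer(gains, gains, `-`)))
  dl <- rdm_lower(abs(outer(losses, losses, `-`)))
  keep <- is.finite(y)
  df <- data.frame(y = y[keep], gain_distance = dg[keep], loss_distance = dl[keep])
  collinear <- abs(cor(df$gain_distance, df$loss_distance)) > 1 - 1e-10 ||
    var(df$gain_distance) == 0 || var(df$loss_distance) == 0
  if (collinear) warn("distance regressors are collinear; slopes are not separable")
  fit <- lm(y ~ gain_distance + loss_distance, data = df)
  sm <- summary(fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                 std.error = unname(sm[, 2]),
                 n_pairs = nrow(df), collinear = collinear)
}

#' Neural encoding strength of expected value
#'
#' Same estimator as [attribute_encoding_strength()] but with the single
#' regressor `|delta EV|`, fitted separately to avoid collinearity with the
#' attribute distances.
#'
#' @param rdm a [compute_rdm()] matrix.
#' @param evs per-trial expected values.
#' @return A tibble `(term, estimate, std.error, n_pairs)`.
#' @export
ev_encoding_strength <- function(rdm, evs) {
  y <- rdm_lower(rdm)
  dv <- rdm_lower(abs(outer(evs, evs, `-`)))
  keep <- is.finite(y)
  fit <- lm(y[keep] ~ dv[keep])
  sm <- summary(fit)$coefficients
  tibble::tibble(term = c("(Intercept)", "ev_distance"),
                 estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
                 n_pairs = sum(keep))
}

#' Bin an RDM by an attribute's levels
#'
#' Entry `(a, b)` is the mean dissimilarity over all trial pairs with one
#' trial at level `a` and the other at level `b`; the diagonal averages
#' within-level pairs (missing and flagged when a level holds a single
#' trial). Averaging trial-pair dissimilarities (rather than correlating
#' bin-mean patterns) is robust to unequal bin counts.
#'
#' @param rdm a [compute_rdm()] matrix.
#' @param values per-trial attribute values (gain, loss or EV).
#' @param levels optional explicit level values (default: sorted unique).
#' @return A `n_levels x n_levels` matrix (class `vs_rdm`); empty level pairs
#'   are `NA` and recorded in the `empty_pairs` attribute.
#' @export
binned_rdm <- function(rdm, values, levels = sort(unique(values))) {
  D <- unclass(rdm)
  idx <- lapply(levels, function(l) which(values == l))
  n <- length(levels)
  out <- matrix(NA_real_, n, n, dimnames = list(levels, levels))
  empty <- character()
  for (a in seq_len(n)) for (b in seq_len(a)) {
    if (a == b) {
      block <- D[idx[[a]], idx[[a]], drop = FALSE]
      vals <- block[lower.tri(block)]
    } else {
      vals <- as.numeric(D[idx[[a]], idx[[b]], drop = FALSE])
    }
    if (length(vals) == 0 || all(!is.finite(vals))) {
      empty <- c(empty, sprintf("%s:%s", levels[a], levels[b]))
    } else {
      out[a, b] <- out[b, a] <- mean(vals, na.rm = TRUE)
    }
  }
  structure(out, class = c("vs_rdm", "matrix"),
            corrected = isTRUE(attr(rdm, "corrected")),
            provenance = c(attr(rdm, "provenance"), "binned"),
            empty_pairs = empty)
}

#' Similarity between two RDMs
#'
#' Pearson correlation of the vectorized lower triangles (missing entries
#' pairwise-dropped), plus its Fisher z-transform `atanh(r)`. Group-level
#' inference is a one-sample t-test on subjects' Fisher z values, provided by
#' [rdm_group_test()].
#'
#' @param rdm_model,rdm_data matching-size RDMs.
#' @return A one-row tibble `(r, fisher_z, n_pairs)`.
#' @export
rdm_similarity <- function(rdm_model, rdm_data) {
  a <- rdm_lower(rdm_model); b <- rdm_lower(rdm_data)
  if (length(a) != length(b)) abort("RDM shapes do not match")
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < 3) abort("fewer than 3 valid trial pairs")
  r <- cor(a[keep], b[keep])
  tibble::tibble(r = r, fisher_z = atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)),
                 n_pairs = sum(keep))
}

#' Group test on Fisher-transformed RDM correlations
#'
#' One-sample t-test of subjects' Fisher z values against zero.
#'
#' @param fisher_z per-subject Fisher z values.
#' @return A one-row tibble `(mean_z, t, df, p)`.
#' @export
rdm_group_test <- function(fisher_z) {
  tt <- t.test(fisher_z)
  tibble::tibble(mean_z = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
}
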