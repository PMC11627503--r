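#' Plot EV-binned unit response curves
#'
#' One line per condition and unit class, as in the apparent value range
#' adaptation displays: after efficient adaptation the curves of different
#' range conditions share their endpoints while their slopes track the EV
#' range.
#'
#' @param curves a tibble of [ev_binned_unit_curves()] results, optionally
#'   with a `condition` column distinguishing range conditions.
#' @return A ggplot object.
#' @export
plot_ev_binned_curves <- function(curves) {
  if (!"condition" %in% names(curves)) curves$condition <- "condition"
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$ev_mid, y = .data$response,
                               colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$class)) +
    ggplot2::labs(x = "expected value (bin mid)", y = "mean unit response",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a range-grid sweep metric
#'
#' @param sweep a [range_grid_sweep()] tibble.
#' @param metric column to display (e.g. `"enc_gain"`,
#'   `"loss_aversion_ratio"`).
#' @return A ggplot object.
#' @export
plot_range_grid <- function(sweep, metric = "enc_gain") {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = factor(.data$loss_hi), y = factor(.data$gain_hi),
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "loss range (upper bound)", y = "gain range (upper bound)",
                  fill = metric) +
    ggplot2::theme_minimal()
}

#' Display a representational dissimilarity matrix
#'
#' @param x a `vs_rdm` matrix.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot vs_rdm
#' @export
autoplot.vs_rdm <- function(x, ...) {
  df <- tibble::tibble(row = rep(seq_len(nrow(x)), ncol(x)),
                       col = rep(seq_len(ncol(x)), each = nrow(x)),
                       dissimilarity = as.numeric(unclass(x)))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$dissimilarity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot sliding-window loss-aversion dynamics
#'
#' @param series a [sliding_window_loss_aversion()] tibble, optionally with a
#'   `group` column.
#' @return A ggplot object.
#' @export
plot_lambda_series <- function(series) {
  aes <- if ("group" %in% names(series)) {
    ggplot2::aes(.data$window, .data$lambda, colour = .data$group)
  } else {
    ggplot2::aes(.data$window, .data$lambda)
  }
  ggplot2::ggplot(series, aes) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "ribbon",
                          alpha = 0.2, colour = NA) +
    ggplot2::labs(x = "window (16 trials)", y = "loss aversion  log(wL/wG)") +
    ggplot2::theme_minimal()
}
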