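#' Plot smoothed firing rates
#'
#' @param object A `rate_matrix`.
#' @param ... Unused.
#' @return A ggplot: one line per unit over time.
#' @export
autoplot.rate_matrix <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time_s, .data$rate_pps,
                                 group = .data$unit_id,
                                 colour = .data$unit_id)) +
    ggplot2::geom_line(alpha = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "Time (s)",
                  y = if (object$detrended) "Detrended rate (pps)"
                      else "Smoothed rate (pps)") +
    ggplot2::theme_minimal()
}

#' Plot the R-squared curves of a dimensionality report
#'
#' Solid: data; dashed: ISI-shuffled surrogate. The vertical line marks the
#' factor count selected by the surrogate-slope criterion.
#'
#' @param object A `dimensionality_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dimensionality_report <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("r2_data", "r2_surrogate"),
                        names_to = "series", values_to = "r2")
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$r2,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_slope, colour = "grey40") +
    ggplot2::scale_linetype_manual(values = c(r2_data = "solid",
                                              r2_surrogate = "dashed"),
                                   labels = c("data", "surrogate"),
                                   name = NULL) +
    ggplot2::labs(x = "Number of latent factors", y = expression(R^2)) +
    ggplot2::theme_minimal()
}

#' Raster plot of a scenario run
#'
#' @param object A `scenario_run`.
#' @param max_units Cap on displayed units (default 60).
#' @param ... Unused.
#' @return A ggplot raster of pool-1 firing times.
#' @export
autoplot.scenario_run <- function(object, max_units = 60, ...) {
  spk <- object$pop$spikes
  ids <- unit_ids(object$pop)
  if (length(ids) > max_units) {
    spk <- spk[spk$unit_id %in% ids[seq_len(max_units)], ]
  }
  ggplot2::ggplot(spk, ggplot2::aes(.data$time_s, .data$unit_id)) +
    ggplot2::geom_point(shape = "|", size = 1) +
    ggplot2::labs(x = "Time (s)", y = NULL,
                  title = sprintf("Scenario %s", object$scenario)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Heat map of a MUAP amplitude map
#'
#' @param map A `(rows-1) x cols` amplitude matrix from [amplitude_map()].
#' @return A ggplot tile map.
#' @export
plot_amplitude_map <- function(map) {
  df <- expand.grid(row = seq_len(nrow(map)), col = seq_len(ncol(map)))
  df$amp <- as.vector(map)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$amp)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "p-p amp") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Column", y = "Row") +
    ggplot2::theme_minimal()
}
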