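#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types:
#' load-indentation curves (with an optional Sneddon fit overlay), work
#' profiles as W against h^3 (the linearity diagnostic), depth-resolved W/V
#' profiles, and mechanical-property maps as heatmaps.
#'
#' @param object The object to plot.
#' @param fit Optional `sneddon_fit` overlaid on an indentation curve.
#' @param field Map field to show, see [summarize_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @name afmwv-plots
NULL

#' @rdname afmwv-plots
#' @method autoplot indentation_curve
#' @export
autoplot.indentation_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$h * 1e9, y = .data$P * 1e9)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "indentation depth h (nm)", y = "load P (nN)")
  if (!is.null(fit)) {
    hh <- seq(0, max(object$h), length.out = 200)
    fl <- tibble::tibble(h = hh, P = stats::predict(fit, hh))
    p <- p + ggplot2::geom_line(
      data = fl, ggplot2::aes(x = .data$h * 1e9, y = .data$P * 1e9),
      colour = "firebrick"
    )
  }
  p
}

#' @rdname afmwv-plots
#' @method autoplot work_profile
#' @export
autoplot.work_profile <- function(object, ...) {
  df <- tibble::tibble(x = object$h^3 * 1e27, W = object$W * 1e18)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$W)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      linewidth = 0.4, colour = "steelblue") +
    ggplot2::labs(x = expression(h^3 ~ (nm^3)), y = "work W (aJ)")
}

#' @rdname afmwv-plots
#' @method autoplot wv_profile
#' @export
autoplot.wv_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$h * 1e9, y = .data$wv / 1e3)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "indentation depth h (nm)", y = "W/V (kJ/m³)")
}

#' @rdname afmwv-plots
#' @method autoplot map_grid
#' @export
autoplot.map_grid <- function(object, field = "E_fit_Pa", ...) {
  stopifnot(field %in% names(object))
  df <- tibble::as_tibble(object)
  lab <- c(
    E_fit_Pa = "E (Sneddon fit, kPa)", E_wv_Pa = "E (W/V route, kPa)",
    wv_mean_Jm3 = "W/V (kJ/m³)"
  )[field]
  df$value <- df[[field]] / 1e3
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = if (is.na(lab)) field else lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row")
}

#' Histogram of a mapped property
#'
#' @param map A `map_grid`.
#' @param field Map field, see [summarize_map()].
#' @param bins Bin count, default 10.
#' @return A ggplot object.
#' @export
plot_map_histogram <- function(map, field = "E_fit_Pa", bins = 10L) {
  stopifnot(inherits(map, "map_grid"), field %in% names(map))
  df <- tibble::as_tibble(map)
  df <- df[df$status == "ok" & is.finite(df[[field]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[field]] / 1e3)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey55", colour = "white") +
    ggplot2::labs(x = paste(field, "(k-units)"), y = "count")
}
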