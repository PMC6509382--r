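#' Seasonal strength boxplot
#'
#' Box-and-point plot of per-animal graph strength by season (and source,
#' for ensembles), the standard display for seasonal association contrasts.
#'
#' @param x A `pbsn`, `spatial_network`, or `pbsn_ensemble` object.
#' @param log Log10 y scale (strengths are heavily right-skewed).
#' @return A ggplot object.
#' @export
plot_strength <- function(x, log = FALSE) {
  if (inherits(x, "pbsn")) {
    df <- dplyr::mutate(x$strength, value = .data$strength, source = "observed")
    ylab <- "social graph strength"
  } else if (inherits(x, "spatial_network")) {
    df <- dplyr::mutate(x$strength, value = .data$spatial_strength, source = "observed")
    ylab <- "spatial graph strength (UDOI sum)"
  } else if (inherits(x, "pbsn_ensemble")) {
    td <- tidy(x)
    df <- dplyr::bind_rows(
      dplyr::mutate(td, value = .data$observed, source = "observed"),
      dplyr::mutate(td, value = .data$null_mean, source = "random")
    )
    ylab <- "social graph strength"
  } else {
    rlang::abort("plot_strength() understands pbsn, spatial_network and pbsn_ensemble objects")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = interaction(.data$season, .data$source, sep = " / "),
                                        y = .data$value, fill = .data$season)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = ylab, fill = "season") +
    ggplot2::theme_minimal()
  if (log) p <- p + ggplot2::scale_y_log10()
  p
}

#' Interannual site-fidelity plot
#'
#' @param fidelity Tibble from [site_fidelity()].
#' @return A ggplot object: within-individual cross-year UDOI by season.
#' @export
plot_fidelity <- function(fidelity) {
  ggplot2::ggplot(fidelity, ggplot2::aes(x = .data$season, y = .data$udoi,
                                         fill = .data$season)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.9) +
    ggplot2::labs(x = NULL, y = "interannual UDOI (site fidelity)") +
    ggplot2::theme_minimal()
}

#' Null-coefficient distribution plot
#'
#' Histogram of the permutation null distribution of a model coefficient
#' with the observed estimate (solid line) and the null band (dashed lines).
#'
#' @param coefnull A `pbsn_coefnull` object.
#' @param term Coefficient to display (default the season contrast).
#' @return A ggplot object.
#' @export
plot_coefficient_null <- function(coefnull, term = "seasonwinter") {
  stopifnot(inherits(coefnull, "pbsn_coefnull"))
  if (!term %in% colnames(coefnull$draws)) {
    rlang::abort(glue::glue("unknown term '{term}'"))
  }
  df <- tibble::tibble(draw = coefnull$draws[, term])
  s <- coefnull$summary[coefnull$summary$term == term, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draw)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = s$observed, color = "red", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(s$null_lo, s$null_hi),
                        linetype = "dashed", color = "grey20") +
    ggplot2::labs(x = glue::glue("null coefficient: {term}"), y = "count") +
    ggplot2::theme_minimal()
}

#' Utilization distribution and home-range plot
#'
#' Raster of the UD probability mass with the home-range isopleth boundary.
#'
#' @param ud A `ud` object.
#' @param level Isopleth level drawn over the surface.
#' @return A ggplot object.
#' @export
plot_ud <- function(ud, level = 0.95) {
  stopifnot(inherits(ud, "ud"))
  cells <- isopleth_cells(ud, level)
  df <- expand.grid(x = ud$grid$xc, y = ud$grid$yc)
  df$mass <- as.vector(ud$mass)
  df$inside <- as.vector(cells)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$mass)) +
    ggplot2::geom_contour(ggplot2::aes(z = as.numeric(.data$inside)),
                          breaks = 0.5, color = "white", linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "mass") +
    ggplot2::theme_minimal()
}

#' @rdname plot_strength
#' @param object A supported result object.
#' @param ... Passed through.
#' @export
autoplot.pbsn <- function(object, ...) plot_strength(object, ...)

#' @rdname plot_strength
#' @export
autoplot.spatial_network <- function(object, ...) plot_strength(object, ...)

#' @rdname plot_strength
#' @export
autoplot.pbsn_ensemble <- function(object, ...) plot_strength(object, ...)

#' @rdname plot_coefficient_null
#' @param object A `pbsn_coefnull`.
#' @param ... Passed through.
#' @export
autoplot.pbsn_coefnull <- function(object, ...) plot_coefficient_null(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
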