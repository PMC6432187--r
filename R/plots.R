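#' @exportS3Method ggplot2::autoplot
autoplot.weight_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ep, y = .data$lnw)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(E[p]), y = "ln W",
                  title = "Generalised-ensemble weight function")
}

#' @exportS3Method ggplot2::autoplot
autoplot.density_of_states <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$ep,
                                            y = .data$ln_omega)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = expression(E[p]), y = expression(ln * Omega(E[p])),
                  title = "Conformational density of states")
}

#' @exportS3Method ggplot2::autoplot
autoplot.micro_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ep, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = expression(E[p]), y = NULL,
                  title = "Microcanonical inverse temperature and curvature")
}

#' @exportS3Method ggplot2::autoplot
autoplot.energy_hist2d <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$elj, y = .data$ebend,
                                   fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(E[LJ]), y = expression(E[Bend]),
                  title = "Two-dimensional energy distribution")
}

#' @exportS3Method ggplot2::autoplot
autoplot.mc_run <- function(object, ...) {
  ggplot2::ggplot(object$series, ggplot2::aes(x = .data$sweep,
                                              y = .data$ep)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "sweep", y = expression(E[p]),
                  title = "Potential-energy trace")
}

#' Plot reweighted observable curves
#'
#' @param series A tagged time series (from [run_weighted()] or
#'   [run_canonical()]).
#' @param temperature Temperature grid.
#' @param observables Series columns to reweight and draw.
#' @return A ggplot object; untrustworthy points (low effective sample
#'   size) are hollow.
#' @export
plot_reweighted <- function(series, temperature, observables = "ep") {
  rw <- reweight(series, temperature = temperature,
                 observables = observables)
  ggplot2::ggplot(rw, ggplot2::aes(x = .data$temperature,
                                   y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$flag)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "T", y = NULL)
}
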