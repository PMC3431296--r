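# ggplot2 visualizations for the main result types.

#' Plot a mean-field response curve
#'
#' Readout steady state against the flux-capacity ratio V+/V-; diverged grid
#' points are shown as a rug at the top.
#'
#' @param object a [response_curve()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot response_curve
#' @export
autoplot.response_curve <- function(object, ...) {
  ok <- dplyr::filter(object, !.data$diverged)
  p <- ggplot2::ggplot(ok, ggplot2::aes(x = .data$ratio, y = .data$output)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = expression(V^"+" / V^"-"),
                  y = paste0("steady-state ", attr(object, "readout"),
                             " (copies)"),
                  title = paste0("Response curve: ",
                                 attr(object, "module_class")))
  if (any(object$diverged))
    p <- p + ggplot2::geom_rug(data = dplyr::filter(object, .data$diverged),
                               ggplot2::aes(x = .data$ratio), sides = "t",
                               inherit.aes = FALSE)
  p
}

#' Plot per-species CV for a coupled/uncoupled comparison
#'
#' Bar chart of CV with bootstrap error bars, one panel per configuration.
#'
#' @param object a `comparison_report`.
#' @param species optional subset of species to show (default: module
#'   readout plus proteins A and B).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, species = NULL, ...) {
  species <- species %||% unique(c(object$readout, "A", "B"))
  df <- dplyr::bind_rows(
    dplyr::mutate(object$summary_coupled$species, configuration = "cotranscribed"),
    dplyr::mutate(object$summary_uncoupled$species, configuration = "uncoupled"))
  df <- dplyr::filter(df, .data$species %in% !!species)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$cv,
                                   fill = .data$configuration)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$cv - .data$sd_cv,
                   ymax = .data$cv + .data$sd_cv),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(y = "CV at stationarity", x = NULL,
                  title = paste0("Noise by configuration: ",
                                 object$config$cls))
}

#' Plot binned coupling fraction against copy number
#'
#' @param bins a [bin_errorbars()] tibble.
#' @return a ggplot.
#' @export
plot_coupling_bins <- function(bins) {
  df <- dplyr::filter(bins, !is.na(.data$fraction))
  df$mid <- sqrt(df$bin_low * df$bin_high)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$fraction)) +
    ggplot2::geom_col(width = 0.3) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$fraction - .data$sd, 0),
                                        ymax = .data$fraction + .data$sd),
                           width = 0.1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "average copies per cell",
                  y = "fraction of pairs in the same operon")
}

#' Plot a time cross-correlation
#'
#' @param object a [cross_correlation()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cross_correlation
#' @export
autoplot.cross_correlation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sem,
                                        ymax = .data$value + .data$sem),
                           width = 0) +
    ggplot2::labs(x = "lag (s)", y = "normalized cross-correlation")
}
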