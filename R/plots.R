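# ggplot2 visualizations for spectra, envelopes and LOQ analyses.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a mass spectrum
#'
#' Profile trace; pass `xlim` to zoom into the light/heavy pair region.
#'
#' @param object A [mass_spectrum()].
#' @param xlim Optional length-2 m/z window.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mass_spectrum
#' @export
autoplot.mass_spectrum <- function(object, xlim = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(xlim)) df <- df[df$mz >= xlim[1] & df$mz <= xlim[2], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "m/z (Da)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot an isotopologue envelope
#'
#' @param object An [isotope_pattern()].
#' @param ... Unused.
#' @return A ggplot of abundance vs exact m/z, one stick per offset k.
#' @method autoplot isotope_pattern
#' @export
autoplot.isotope_pattern <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0, yend = .data$abundance)
  ) +
    ggplot2::geom_segment(linewidth = 1) +
    ggplot2::labs(x = "neutral mass (Da)", y = "relative abundance") +
    ggplot2::theme_minimal()
}

#' Plot an LOQ analysis
#'
#' Member deviations (%) against concentration on a log axis, with the
#' two-sided threshold band and the called LOQ.
#'
#' @param object An `loq_result` from [loq_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot loq_result
#' @export
autoplot.loq_result <- function(object, ...) {
  df <- tibble::as_tibble(object$table)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$concentration_um, y = .data$deviation_pct)) +
    ggplot2::geom_hline(
      yintercept = c(-object$threshold, object$threshold),
      linetype = "dashed"
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$retained)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (uM)", y = "deviation from reference mean (%)",
      shape = "in reference mean"
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$loq_concentration_um)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$loq_concentration_um,
      linetype = "dotted"
    )
  }
  p
}
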