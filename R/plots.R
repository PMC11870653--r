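# ggplot2 views of the main result types.

#' Plot an FA kernel-density summary
#'
#' @param summary a `distribution_summary` from [fa_density()].
#' @return a ggplot.
#' @export
plot_fa_density <- function(summary) {
  stopifnot(inherits(summary, "distribution_summary"))
  if (summary$degenerate) stop("degenerate summary has no density curve")
  df <- data.frame(fa = summary$x, density = summary$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fa, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = summary$median, linetype = "dashed") +
    ggplot2::labs(x = "fractional anisotropy",
                  y = "density",
                  subtitle = sprintf("median/IQR: %.2f/%.2f (n = %d)",
                                     summary$median, summary$iqr, summary$n)) +
    ggplot2::theme_minimal()
}

#' Plot a fibre orientation distribution as a polar histogram
#'
#' Azimuth on the angular axis, elevation on the radius (pole at the centre),
#' fill mapped to probability density.
#'
#' @param fod a `spherical_histogram` from [build_fod()].
#' @return a ggplot.
#' @export
plot_fod <- function(fod) {
  stopifnot(inherits(fod, "spherical_histogram"))
  b <- fod$bins
  b$az_mid <- (b$az_lo + b$az_hi) / 2
  b$r_lo <- 90 - b$el_hi
  b$r_hi <- 90 - b$el_lo
  ggplot2::ggplot(b) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$az_lo, xmax = .data$az_hi,
                                    ymin = .data$r_lo, ymax = .data$r_hi,
                                    fill = .data$density)) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_fill_viridis_c(name = "p (1/sr)") +
    ggplot2::labs(x = "azimuth (deg)", y = "90 - elevation (deg)",
                  subtitle = sprintf("pole axis %s, %d directions",
                                     fod$pole_axis, fod$n)) +
    ggplot2::theme_minimal()
}

#' Plot streamlines projected onto a coordinate plane
#'
#' @param x a `streamline_set` or list of n x 3 matrices (um).
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param max_n plot at most this many streamlines (evenly subsampled).
#' @return a ggplot.
#' @export
plot_streamlines <- function(x, plane = "xy", max_n = 200) {
  sl <- if (inherits(x, "streamline_set")) x$streamlines else x
  if (!length(sl)) stop("no streamlines to plot")
  ax <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3),
               stop("`plane` must be 'xy', 'xz' or 'yz'"))
  if (length(sl) > max_n) {
    sl <- sl[unique(round(seq(1, length(sl), length.out = max_n)))]
  }
  df <- do.call(rbind, lapply(seq_along(sl), function(i) {
    data.frame(id = i, h = sl[[i]][, ax[1]], v = sl[[i]][, ax[2]])
  }))
  lab <- strsplit(plane, "")[[1]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v,
                                   group = .data$id)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(lab[1], " (um)"), y = paste0(lab[2], " (um)")) +
    ggplot2::theme_minimal()
}
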