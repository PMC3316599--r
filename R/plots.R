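# ggplot2 front-ends for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods for MSD curves (optionally log-log), calibration
#' maps (saturation MSD against Z, one line per beta), density curves,
#' trajectory records (position paths) and marginal fits (radial histogram
#' with the fitted curve).
#'
#' @param object the object to plot.
#' @param loglog draw an MSD curve on log-log axes.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @method autoplot msd_curve
autoplot.msd_curve <- function(object, loglog = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "MSD") +
    ggplot2::theme_minimal()
  if (loglog) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' @rdname autoplot.msd_curve
#' @export
#' @method autoplot calibration_map
autoplot.calibration_map <- function(object, ...) {
  g <- object$grid
  g$beta_f <- factor(signif(g$beta, 3))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$Z, y = .data$msd_sat,
                                  colour = .data$beta_f)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$msd_sat - .data$stderr,
                                        ymax = .data$msd_sat + .data$stderr),
                           width = 0) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Z = T_AS / diffusive time",
                  y = expression("saturation MSD / " * L^2),
                  colour = expression(beta)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.msd_curve
#' @export
#' @method autoplot density_curve
autoplot.density_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dimensionless position", y = "density",
                  title = attr(object, "which")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.msd_curve
#' @export
#' @method autoplot trajectory_record
autoplot.trajectory_record <- function(object, ...) {
  if (is.null(object$positions))
    stop("record was run with record_positions = FALSE", call. = FALSE)
  df <- object$positions
  df$animal_f <- factor(df$animal)
  if (object$config$dimension == 1) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$x,
                                     colour = .data$animal_f)) +
      ggplot2::geom_path() +
      ggplot2::labs(y = "position", colour = "animal") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$animal_f)) +
      ggplot2::geom_path(alpha = 0.6) +
      ggplot2::coord_equal() +
      ggplot2::labs(colour = "animal") +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.msd_curve
#' @param bins histogram bins.
#' @export
#' @method autoplot marginal_fit
autoplot.marginal_fit <- function(object, bins = 40, ...) {
  rg <- seq(1e-3, radius_cutoff(object$eps_hat), length.out = 300)
  fitc <- tibble::tibble(r = rg,
                         density = 2 * pi * rg *
                           marginal_pdf_2d(rg, object$params))
  ggplot2::ggplot(tibble::tibble(r = object$r), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = fitc,
                       ggplot2::aes(x = .data$r, y = .data$density),
                       colour = "red") +
    ggplot2::labs(x = "dimensionless radial distance r / L",
                  y = "radial density") +
    ggplot2::theme_minimal()
}
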