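#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: the boundary
#' curve (with its endpoint chord), the curvature profile, a Kaplan-Meier
#' fit, and the cross-validated calibration curve.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @returns A ggplot.
#' @name glioshape-autoplot
NULL

#' @rdname glioshape-autoplot
#' @export
autoplot.boundary_curve <- function(object, ...) {
  df <- tibble(x = object$x, y = object$y)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(linewidth = 0.6, color = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (mm)", y = "y (mm)",
      title = sprintf(
        "Boundary arc: L = %.1f mm%s", curve_length(object),
        if (is_closed(object)) " (closed)" else sprintf(", tortuosity = %.3f", tortuosity(object))
      )
    )
  if (!is_closed(object)) {
    chord <- df[c(1, nrow(df)), ]
    p <- p + ggplot2::geom_line(data = chord, linetype = "dashed", color = "grey50")
  }
  p
}

#' @rdname glioshape-autoplot
#' @export
autoplot.curvature_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s, y = .data$kappa)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_line(color = "#d95f02") +
    ggplot2::labs(x = "arc length s (mm)", y = expression(kappa ~ (mm^-1)))
}

#' @rdname glioshape-autoplot
#' @export
autoplot.km_fit <- function(object, ...) {
  tab <- tidy(object)
  steps <- dplyr::bind_rows(
    tibble(time = 0, surv = 1, lower = 1, upper = 1),
    tab[, c("time", "surv", "lower", "upper")]
  )
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step(color = "#1b9e77") +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower), linetype = "dotted", color = "#1b9e77") +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper), linetype = "dotted", color = "#1b9e77") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "progression-free survival")
}

#' @rdname glioshape-autoplot
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- dplyr::arrange(object$calibration, .data$predicted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed_smooth), color = "#7570b3") +
    ggplot2::geom_rug(sides = "b", alpha = 0.3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = sprintf("predicted P(event by %g months)", object$horizon),
      y = "smoothed observed probability",
      title = sprintf("ICI = %.3f, E50 = %.3f", object$ici, object$e50)
    )
}

#' Overlay a mask and its extracted medial arc
#'
#' @param mask A [mask_slice()].
#' @param angular_window Passed to [extract_medial_boundary()].
#' @returns A ggplot.
#' @export
plot_mask_arc <- function(mask, angular_window = 90) {
  px <- mask$pixels
  df <- tidyr::expand_grid(
    row = seq_len(nrow(px)), col = seq_len(ncol(px))
  )
  df$fg <- as.vector(t(px)) == 1 # expand_grid varies col fastest
  df$x <- (df$col - 1) * mask$spacing[2]
  df$y <- (df$row - 1) * mask$spacing[1]
  arc <- extract_medial_boundary(mask, angular_window)
  ggplot2::ggplot() +
    ggplot2::geom_raster(
      data = dplyr::filter(df, .data$fg),
      ggplot2::aes(x = .data$x, y = .data$y), fill = "grey80"
    ) +
    ggplot2::geom_path(
      data = arc, ggplot2::aes(x = .data$x, y = .data$y),
      color = "#e41a1c", linewidth = 0.8
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}
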