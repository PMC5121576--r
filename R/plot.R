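#' Plot IOP against altitude for each eye
#'
#' Scatter of the chosen tonometry channel against altitude, one colour per
#' eye, with the per-eye OLS line overlaid.
#'
#' @inheritParams fit_iop_altitude
#' @return A ggplot object.
#' @examples
#' plot_iop_altitude(rabbit_trips())
#' @export
plot_iop_altitude <- function(trips, method = c("applanation", "indentation")) {
  method <- match.arg(method)
  trips <- validate_trips(trips)
  col <- paste0("iop_", method, "_mmhg")
  ggplot2::ggplot(trips, ggplot2::aes(x = altitude_m, y = .data[[col]],
                                      colour = eye_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "Altitude (m above sea level)",
                  y = sprintf("IOP, %s (mmHg)", method), colour = "Eye") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.iop_fits <- function(object, ...) {
  d <- attr(object, "trip_data")
  ycol <- if (!is.null(d) && "human_iop_mmhg" %in% names(d)) {
    "human_iop_mmhg"
  } else {
    paste0("iop_", attr(object, "method"), "_mmhg")
  }
  p <- ggplot2::ggplot()
  if (!is.null(d)) {
    p <- p + ggplot2::geom_point(
      data = d, ggplot2::aes(x = altitude_m / 100, y = .data[[ycol]],
                             colour = eye_id))
  }
  p +
    ggplot2::geom_abline(
      data = as_tibble(object),
      ggplot2::aes(intercept = intercept, slope = slope, colour = eye_id)) +
    ggplot2::labs(x = "Altitude (hundreds of m)", y = "IOP (mmHg)",
                  colour = "Eye") +
    ggplot2::theme_minimal()
}
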