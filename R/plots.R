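#' Plot methods
#'
#' `autoplot()` methods give the standard diagnostic figures: the
#' \eqn{1 - G(\xi)} decay of a correlation profile, the chord length
#' histogram with its mean, a spectral table, and the ratio-versus-MCL
#' scatter of a study.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-darkfieldr
NULL

#' @rdname autoplot-darkfieldr
#' @export
autoplot.correlation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$xi_um, y = .data$one_minus_G)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(xi[corr] ~ "(" * mu * "m)"),
                  y = expression(1 - G(xi[corr]))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-darkfieldr
#' @export
autoplot.chord_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$chord_um)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mcl_um, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = expression("chord length (" * mu * "m)"), y = "count",
                  subtitle = sprintf("MCL = %.1f um (SE %.2f)",
                                     object$mcl_um, object$mcl_se_um)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-darkfieldr
#' @export
autoplot.spectral_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy_keV, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "energy (keV)", y = attr(object, "kind")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-darkfieldr
#' @export
autoplot.xdf_correlation <- function(object, ...) {
  ggplot2::ggplot(object$scatter, ggplot2::aes(x = .data$mcl_um, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::labs(x = expression("mean chord length (" * mu * "m)"),
                  y = expression(-ln(D)[low] / -ln(D)[high]),
                  subtitle = sprintf("Spearman rho = %.2f", object$spearman_rho)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-darkfieldr
#' @export
autoplot.xdf_study <- function(object, ...) autoplot(object$correlation, ...)
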