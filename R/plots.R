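#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot inferred tensions and pressures
#'
#' Column charts of the fitted membrane tensions (mean 1 by the gauge) and
#' cell pressures relative to the exterior.
#'
#' @param object a `force_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.force_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[!(df$type == "pressure" & df$entity == 0), ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$term, levels = .data$term),
                                   y = .data$estimate, fill = .data$type)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~type, scales = "free") +
    ggplot2::labs(x = NULL, y = "inferred value",
                  title = "Inferred membrane tensions and cell pressures") +
    ggplot2::theme_minimal()
}

#' Plot the sensitivity spectrum
#'
#' Amplification factors of the pseudoinverse on a log scale; values above 1
#' (dashed line) mark noise-amplifying directions.
#'
#' @param object a `sensitivity_spectrum`.
#' @param ... unused.
#' @export
autoplot.sensitivity_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$index, .data$lambda)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mode", y = expression(lambda),
                  title = "Sensitivity spectrum of the pseudoinverse") +
    ggplot2::theme_minimal()
}

#' Plot per-face Young-Laplace agreement
#'
#' Scatter of the pressure jump against `2 H T` per face, coloured by the
#' relative residual; points on the diagonal satisfy the Young-Laplace
#' relation exactly.
#'
#' @param fit a `force_fit`.
#' @return A ggplot object.
#' @export
plot_membrane_residuals <- function(fit) {
  df <- membrane_residuals(fit)
  ggplot2::ggplot(df, ggplot2::aes(.data$rhs, .data$lhs,
                                   colour = abs(.data$rel_residual),
                                   shape = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(2 * H[k] * T[k]),
                  y = expression(P[i] - P[j]),
                  colour = "|rel. residual|",
                  title = "Young-Laplace agreement per membrane face") +
    ggplot2::theme_minimal()
}
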