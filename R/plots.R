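# ggplot2 autoplot methods for the main result types.

#' Plot a scattering curve
#'
#' Log-intensity versus q, with error bars when uncertainties are present.
#'
#' @param object A `scattering_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scattering_curve <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ ("Å"^-1)), y = "I(q) (a.u.)") +
    ggplot2::theme_minimal()
  if ("sigma" %in% names(df)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$intensity - .data$sigma,
                   ymax = .data$intensity + .data$sigma),
      linewidth = 0.2, alpha = 0.4)
  }
  p
}

#' Plot a pair-distance distribution
#'
#' @param object A `distance_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_distribution <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "dmax"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "r (Å)", y = "P(r)",
                  subtitle = sprintf("Rg %.1f Å, Dmax %.1f Å",
                                     attr(object, "rg"), attr(object, "dmax"))) +
    ggplot2::theme_minimal()
}

#' Plot an entropy profile
#'
#' Per-column sequence entropy (log base 20); gap-flagged columns are
#' highlighted.
#'
#' @param object An `entropy_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.entropy_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$column, y = .data$entropy)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$gap_flagged), width = 0.9) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue4",
                                          `TRUE` = "orange2"),
                               name = "gap > threshold") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "alignment column", y = "entropy S (log20)") +
    ggplot2::theme_minimal()
}

#' Plot a model-to-data scattering fit
#'
#' @param object A `saxs_fit` from [fit_model_to_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saxs_fit <- function(object, ...) {
  df <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity),
                        size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ ("Å"^-1)), y = "I(q) (a.u.)",
                  subtitle = sprintf("reduced chi^2 = %.2f", object$chi_reduced)) +
    ggplot2::theme_minimal()
}
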