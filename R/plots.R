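#' Plot an absorbance-time trace
#'
#' @param object A `kin_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kin_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$absorbance)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "absorbance (AU)",
                  title = "Product-formation trace") +
    ggplot2::theme_minimal()
}

#' Plot a calibration line with its data
#'
#' @param object A `calibration_line` carrying its data.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_line <- function(object, ...) {
  if (is.null(object$data)) abort("calibration line carries no data to plot")
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "concentration (mol/L)", y = "response",
                  subtitle = sprintf("slope %.4g, R^2 %.4f",
                                     object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Pareto-style plot of factorial effects
#'
#' @param object A `doe_effects` tibble from [main_effects()].
#' @param ... Unused.
#' @return A ggplot with terms ordered by absolute effect.
#' @export
autoplot.doe_effects <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(term = stats::reorder(.data$term, abs(.data$effect)))
  ggplot2::ggplot(d, ggplot2::aes(x = abs(.data$effect), y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "|effect| (AU)", y = NULL,
                  title = "Factorial screening effects") +
    ggplot2::theme_minimal()
}

#' Contour plot of a fitted response surface
#'
#' @param object An `rsm_fit`.
#' @param n Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot with filled contours and the stationary point marked
#'   (when it exists).
#' @export
autoplot.rsm_fit <- function(object, n = 80, ...) {
  rng1 <- range(object$data$x1); rng2 <- range(object$data$x2)
  grid <- tidyr::expand_grid(
    x1 = seq(rng1[1], rng1[2], length.out = n),
    x2 = seq(rng2[1], rng2[2], length.out = n)
  ) |>
    dplyr::mutate(y = eval_quadratic(object$coefficients, .data$x1, .data$x2))
  gg <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x1, y = .data$x2)) +
    ggplot2::geom_contour_filled(ggplot2::aes(z = .data$y), bins = 12) +
    ggplot2::labs(x = object$factor_names[1], y = object$factor_names[2],
                  fill = "response (AU)",
                  title = "Fitted quadratic response surface") +
    ggplot2::theme_minimal()
  pt <- object$stationary$point
  if (!anyNA(pt)) {
    gg <- gg + ggplot2::annotate("point", x = pt[[1]], y = pt[[2]],
                                 colour = "red", size = 2)
  }
  gg
}

#' Recovery plot for a validation report
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot of per-level recoveries with confidence bars.
#' @export
autoplot.validation_report <- function(object, ...) {
  d <- object$levels |>
    dplyr::mutate(
      level = factor(format(.data$added, digits = 3)),
      rec_lo = recovery(.data$added, .data$found_mean - .data$ci_halfwidth),
      rec_hi = recovery(.data$added, .data$found_mean + .data$ci_halfwidth)
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$recovery_pct)) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rec_lo,
                                          ymax = .data$rec_hi)) +
    ggplot2::labs(x = "added (mol/L)", y = "recovery (%)",
                  title = "Spiked-sample recovery") +
    ggplot2::theme_minimal()
}
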