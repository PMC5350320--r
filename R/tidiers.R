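#' Tidy a calibration line
#'
#' @param x A `calibration_line`.
#' @param ... Unused.
#' @return One row per model term with `term`, `estimate`, `std.error`.
#' @export
tidy.calibration_line <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$se_slope)
  )
}

#' Glance at a calibration line
#'
#' @param x A `calibration_line`.
#' @param ... Unused.
#' @return One-row tibble with `r.squared`, `sigma` (typical error),
#'   `statistic` (correlation t), `nobs`.
#' @export
glance.calibration_line <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$se_regression,
                 statistic = x$t_corr, nobs = x$n_points)
}

#' Tidy a kinetic order/rate fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return Tibble with the reaction order and rate coefficient.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(term = c("order_n", "k_prime"),
                 estimate = c(x$order_n, x$k_prime))
}

#' @rdname tidy.kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$fit$r_squared, nobs = x$fit$n_points)
}

#' Tidy a stoichiometry result
#'
#' @param x A `stoich_result`.
#' @param ... Unused.
#' @return One-row tibble with both log-log slopes, the snapped integer
#'   ratio, and the snapping residual.
#' @export
tidy.stoich_result <- function(x, ...) {
  tibble::tibble(slope_analyte = x$slope_analyte,
                 slope_oxidant = x$slope_oxidant,
                 ratio_p = x$ratio$p, ratio_q = x$ratio$q,
                 residual = x$ratio$residual)
}

#' Tidy a response-surface fit
#'
#' @param x An `rsm_fit`.
#' @param ... Unused.
#' @return One row per quadratic coefficient.
#' @export
tidy.rsm_fit <- function(x, ...) {
  cf <- x$coefficients
  tibble::tibble(
    term = c("(Intercept)", x$factor_names,
             paste0("I(", x$factor_names, "^2)"),
             paste(x$factor_names, collapse = ":")),
    estimate = c(cf$b0, cf$b1, cf$b2, cf$b11, cf$b22, cf$b12)
  )
}

#' @rdname tidy.rsm_fit
#' @export
glance.rsm_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared,
                 stationary.kind = x$stationary$kind,
                 stationary.1 = x$stationary$point[[1]],
                 stationary.2 = x$stationary$point[[2]],
                 nobs = nrow(x$data))
}

#' Tidy a validation report (per spiked level)
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return The per-level accuracy/precision tibble.
#' @export
tidy.validation_report <- function(x, ...) {
  x$levels
}

#' @rdname tidy.validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(sigma.blanks = x$sigma_blanks, lod = x$lod, loq = x$loq,
                 range.lo = x$linear_range[["lo"]],
                 range.hi = x$linear_range[["hi"]],
                 slope = x$calibration$slope,
                 intercept = x$calibration$intercept,
                 r.squared = x$calibration$r_squared,
                 n.blanks = x$n_blanks)
}
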