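#' Fit a straight calibration line by ordinary least squares
#'
#' Shared OLS core for all calibration regressions: returns the slope,
#' intercept, coefficient of determination, typical (residual) error of the
#' estimate with an n - 2 denominator, the slope standard error, and the
#' correlation t statistic used to test H0 "no correlation" against a
#' two-tailed Student t with n - 2 degrees of freedom.
#'
#' When the response is constant (zero total sum of squares) the line is
#' flat by construction and carries no evidence of association; `r_squared`
#' and `t_corr` are reported as 0.
#'
#' @param xs,ys Numeric vectors of equal length >= 3; `xs` must not be
#'   constant.
#' @return An object of class `calibration_line` with fields `slope`,
#'   `intercept`, `r_squared`, `se_regression`, `se_slope`, `n_points`,
#'   `t_corr`, and the input `data`.
#' @examples
#' fit_line(1:5, 2 * (1:5) + 1)
#' @export
fit_line <- function(xs, ys) {
  stop_if_not_finite(xs, "xs"); stop_if_not_finite(ys, "ys")
  if (length(xs) != length(ys)) abort("`xs` and `ys` must have equal length")
  n <- length(xs)
  if (n < 3) abort("at least 3 points are required")
  if (sd(xs) == 0) abort("`xs` must not be constant")
  fit <- lm(ys ~ xs)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((ys - mean(ys))^2)
  sxx <- sum((xs - mean(xs))^2)
  sigma <- sqrt(sse / (n - 2))
  r2 <- if (sst == 0) 0 else max(0, min(1, 1 - sse / sst))
  new_calibration_line(
    slope = unname(coef(fit)[["xs"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    r_squared = r2,
    se_regression = sigma,
    se_slope = sigma / sqrt(sxx),
    n_points = n,
    data = tibble::tibble(x = as.numeric(xs), y = as.numeric(ys))
  )
}

new_calibration_line <- function(slope, intercept, r_squared, se_regression,
                                 se_slope, n_points, data = NULL) {
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         se_regression = se_regression, se_slope = se_slope,
         n_points = n_points,
         t_corr = correlation_t(r_squared, n_points),
         data = data),
    class = "calibration_line"
  )
}

#' @export
print.calibration_line <- function(x, ...) {
  cat("<calibration_line>\n")
  cat(sprintf("  y = %.6g x + %.6g   (n = %d)\n", x$slope, x$intercept,
              x$n_points))
  cat(sprintf("  R^2 %.4f | typical error %.4g | se(slope) %.4g | t_corr %.4g\n",
              x$r_squared, x$se_regression, x$se_slope, x$t_corr))
  invisible(x)
}

#' Correlation t statistic for a calibration line
#'
#' t = r sqrt(n - 2) / sqrt(1 - r^2) with r = +sqrt(r_squared), the statistic
#' of the two-tailed Student t-test (n - 2 degrees of freedom) of the null
#' hypothesis that concentration and signal are uncorrelated. Returns `Inf`
#' for a perfect fit.
#'
#' @param r_squared Coefficient of determination in \[0, 1\].
#' @param n_points Number of calibration points, >= 3.
#' @return The t statistic (non-negative).
#' @examples
#' correlation_t(0.9899, 5) # 17.15
#' @export
correlation_t <- function(r_squared, n_points) {
  stop_if_not_finite(r_squared, "r_squared")
  if (r_squared < 0 || r_squared > 1) abort("`r_squared` must be in [0, 1]")
  if (n_points < 3) abort("`n_points` must be >= 3")
  if (r_squared == 1) return(Inf)
  sqrt(r_squared) * sqrt(n_points - 2) / sqrt(1 - r_squared)
}

#' Initial-rate estimate from an absorbance-time trace
#'
#' Deterministic surrogate for the hand-drawn tangent of the initial-rate
#' method: the slope (AU/s) of a local OLS line over a symmetric window
#' centred at `t_tangent`.
#'
#' @param ts A `kin_curve` or data frame with columns `time_s`, `absorbance`.
#' @param t_tangent Centre of the tangent window (s).
#' @param window_halfwidth Half-width of the window (s).
#' @return The local slope K'' (AU/s).
#' @export
estimate_initial_rate <- function(ts, t_tangent = 250, window_halfwidth = 50) {
  ts <- as_kin_frame(ts)
  keep <- abs(ts$time_s - t_tangent) <= window_halfwidth
  if (sum(keep) < 3) abort("fewer than 3 points in the tangent window")
  unname(coef(lm(absorbance ~ time_s, data = ts[keep, ]))[["time_s"]])
}

#' Pseudo-first-order rate coefficient from log-absorbance slope
#'
#' Constant-rate (rate-constant) method: OLS slope of log10(absorbance)
#' against time over usable points, multiplied by 2.303 to convert the
#' decadic slope to the natural-log rate coefficient K'.
#'
#' @param ts A `kin_curve` or data frame with columns `time_s`, `absorbance`.
#' @param t_max Latest time used (s).
#' @param min_absorbance Points at or below this absorbance are excluded to
#'   keep logarithms finite (AU).
#' @return K' (s^-1).
#' @export
estimate_log_slope_rate <- function(ts, t_max = 1800, min_absorbance = 1e-3) {
  ts <- as_kin_frame(ts)
  keep <- ts$time_s <= t_max & ts$absorbance > min_absorbance
  if (sum(keep) < 3) abort("fewer than 3 usable points")
  sub <- ts[keep, ]
  2.303 * unname(coef(lm(log10(absorbance) ~ time_s, data = sub))[["time_s"]])
}

as_kin_frame <- function(ts) {
  ts <- tibble::as_tibble(ts)
  missing_cols <- setdiff(c("time_s", "absorbance"), names(ts))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ts
}

#' Absorbance at a fixed reaction time
#'
#' Reads the trace at `t_fixed`: exact at grid points, linear interpolation
#' between bracketing points otherwise.
#'
#' @param ts A `kin_curve` or data frame with columns `time_s`, `absorbance`.
#' @param t_fixed Time (s) within the measured range.
#' @return Absorbance (AU).
#' @export
fixed_time_absorbance <- function(ts, t_fixed) {
  ts <- as_kin_frame(ts)
  if (t_fixed < min(ts$time_s) || t_fixed > max(ts$time_s)) {
    abort("`t_fixed` outside the measured time range")
  }
  stats::approx(ts$time_s, ts$absorbance, xout = t_fixed, method = "linear",
                ties = "ordered")$y
}

#' Fixed-time calibration line
#'
#' Regresses fixed-time absorbance on standard concentration.
#'
#' @param pairs Data frame with columns `conc` and `absorbance` (replicates
#'   allowed as extra rows).
#' @return A `calibration_line`.
#' @export
fixed_time_calibration <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  missing_cols <- setdiff(c("conc", "absorbance"), names(pairs))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  fit_line(pairs$conc, pairs$absorbance)
}

#' Select the optimal fixed time
#'
#' Formal selection rule for the fixed-time method: among candidate times
#' whose correlation t statistic exceeds the two-tailed critical value at
#' `confidence` with n - 2 degrees of freedom, keep those whose slope is at
#' least `slope_fraction` of the maximum slope among significant candidates,
#' and return the earliest. Ties go to the earliest time.
#'
#' @param candidates Data frame with one row per candidate and columns
#'   `time_min` (candidate label, minutes), `slope`, `r_squared`, `n_points`;
#'   or a list-column `line` of `calibration_line` objects alongside
#'   `time_min`.
#' @param slope_fraction Fraction of the maximum significant slope a
#'   candidate must reach (default 0.95).
#' @param confidence Two-tailed confidence level for the correlation test.
#' @return The chosen `time_min` (scalar). Errors if no candidate is
#'   significant.
#' @export
select_fixed_time <- function(candidates, slope_fraction = 0.95,
                              confidence = 0.95) {
  cand <- tibble::as_tibble(candidates)
  if (nrow(cand) == 0) abort("`candidates` must be non-empty")
  if ("line" %in% names(cand) &&
      !all(c("slope", "r_squared", "n_points") %in% names(cand))) {
    cand <- cand |>
      dplyr::mutate(slope = purrr::map_dbl(.data$line, "slope"),
                    r_squared = purrr::map_dbl(.data$line, "r_squared"),
                    n_points = purrr::map_dbl(.data$line, "n_points"))
  }
  missing_cols <- setdiff(c("time_min", "slope", "r_squared", "n_points"),
                          names(cand))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  cand <- cand |>
    dplyr::mutate(
      t_corr = purrr::map2_dbl(.data$r_squared, .data$n_points, correlation_t),
      t_crit = purrr::map_dbl(.data$n_points,
                              function(n) t_critical(confidence, n - 2)),
      significant = .data$t_corr > .data$t_crit
    )
  sig <- dplyr::filter(cand, .data$significant)
  if (nrow(sig) == 0) abort("no candidate time has a significant calibration")
  max_slope <- max(sig$slope)
  chosen <- sig |>
    dplyr::filter(.data$slope >= slope_fraction * max_slope) |>
    dplyr::arrange(.data$time_min) |>
    dplyr::slice(1)
  chosen$time_min[[1]]
}

#' Reaction order and rate coefficient from rate-concentration pairs
#'
#' Fits the power rate law v = k' c^n by OLS of log10(rate) on
#' log10(concentration): the slope is the reaction order n and the intercept
#' gives k' = 10^intercept.
#'
#' @param rate_pairs Data frame with columns `conc` and `rate`, all > 0,
#'   >= 3 rows.
#' @return An object of class `kinetic_fit` with fields `order_n`,
#'   `k_prime`, `rates` (the input tibble) and `fit` (the log-log
#'   `calibration_line`).
#' @examples
#' d <- tibble::tibble(conc = c(1e-5, 2e-5, 4e-5), rate = 4.7 * conc)
#' estimate_order_and_rate(d)
#' @export
estimate_order_and_rate <- function(rate_pairs) {
  rp <- tibble::as_tibble(rate_pairs)
  missing_cols <- setdiff(c("conc", "rate"), names(rp))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(rp) < 3) abort("at least 3 (conc, rate) pairs are required")
  if (any(rp$conc <= 0) || any(rp$rate <= 0)) {
    abort("all concentrations and rates must be > 0")
  }
  fit <- fit_line(log10(rp$conc), log10(rp$rate))
  structure(
    list(order_n = fit$slope, k_prime = 10^fit$intercept,
         rates = rp, fit = fit),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit>\n")
  cat(sprintf("  order n %.4g | k' %.4g | log-log R^2 %.4f (n = %d)\n",
              x$order_n, x$k_prime, x$fit$r_squared, x$fit$n_points))
  invisible(x)
}
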