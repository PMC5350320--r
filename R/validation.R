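#' Blank standard deviation
#'
#' Sample SD (n - 1 denominator) of replicate reagent-blank absorbances,
#' the sigma of the LOD/LOQ formulas.
#'
#' @param blanks Numeric vector of blank absorbances (AU), length >= 2.
#' @return SD (AU).
#' @export
blank_sigma <- function(blanks) {
  stop_if_not_finite(blanks, "blanks")
  if (length(blanks) < 2) abort("at least 2 blanks are required")
  sd(blanks)
}

#' Detection and quantitation limits
#'
#' LOD = 3.3 sigma / S and LOQ = 10 sigma / S, with sigma the blank SD and
#' S the calibration slope.
#'
#' @param sigma Blank SD (AU), >= 0.
#' @param slope Calibration slope S (AU L mol^-1), > 0.
#' @return Named numeric vector `c(lod = , loq = )` (mol/L).
#' @examples
#' lod_loq(9.90e-3, 1.31e4) # 2.49e-6, 7.56e-6
#' @export
lod_loq <- function(sigma, slope) {
  stop_if_not_finite(sigma, "sigma"); stop_if_not_finite(slope, "slope")
  if (sigma < 0) abort("`sigma` must be >= 0")
  if (slope <= 0) abort("`slope` must be > 0")
  c(lod = 3.3 * sigma / slope, loq = 10 * sigma / slope)
}

#' Concentration from absorbance via a calibration line
#'
#' Inverts the calibration: (absorbance - intercept) / slope.
#'
#' @param absorbance Absorbance (AU); vectorised.
#' @param calibration A `calibration_line`, or a list with `slope` and
#'   `intercept`.
#' @return Concentration (mol/L).
#' @export
quantify <- function(absorbance, calibration) {
  if (is.null(calibration$slope) || is.null(calibration$intercept)) {
    abort("`calibration` must carry `slope` and `intercept`")
  }
  if (calibration$slope <= 0) abort("calibration slope must be > 0")
  (absorbance - calibration$intercept) / calibration$slope
}

#' Percent recovery of a spiked sample
#'
#' 100 x found / added; the accuracy metric of spiked-sample validation.
#'
#' @param added Added (true) concentration (mol/L), > 0; vectorised.
#' @param found_mean Mean found concentration (mol/L); vectorised.
#' @return Recovery (%).
#' @examples
#' recovery(8.00e-6, 7.52e-6) # 94.0
#' @export
recovery <- function(added, found_mean) {
  stop_if_not_finite(added, "added"); stop_if_not_finite(found_mean, "found_mean")
  if (any(added <= 0)) abort("`added` must be > 0")
  100 * found_mean / added
}

#' Replicate precision statistics
#'
#' Mean, SD (n - 1), standard error SD/sqrt(n), and the half-width of the
#' two-sided confidence interval t(1 - (1-confidence)/2, n - 1) x SE.
#'
#' @param found_replicates Numeric vector of replicate results, length >= 2.
#' @param confidence Confidence level (default 0.95).
#' @return Named list `mean`, `sd`, `se`, `ci_halfwidth`, `n`.
#' @export
precision_stats <- function(found_replicates, confidence = 0.95) {
  stop_if_not_finite(found_replicates, "found_replicates")
  n <- length(found_replicates)
  if (n < 2) abort("at least 2 replicates are required")
  s <- sd(found_replicates)
  se <- s / sqrt(n)
  list(mean = mean(found_replicates), sd = s, se = se,
       ci_halfwidth = t_critical(confidence, n - 1) * se, n = n)
}

#' One-sample bias t statistic
#'
#' t = |mean - added| / (sd / sqrt(n)), tested against the two-tailed
#' critical value with n - 1 degrees of freedom; zero SD with a nonzero
#' bias gives `Inf`.
#'
#' @param found_replicates Numeric vector of replicate results, length >= 2.
#' @param added True (spiked) concentration, > 0.
#' @return The t statistic (non-negative).
#' @export
bias_t <- function(found_replicates, added) {
  stop_if_not_finite(found_replicates, "found_replicates")
  if (added <= 0) abort("`added` must be > 0")
  n <- length(found_replicates)
  if (n < 2) abort("at least 2 replicates are required")
  m <- mean(found_replicates); s <- sd(found_replicates)
  if (s == 0) return(if (m == added) 0 else Inf)
  abs(m - added) / (s / sqrt(n))
}

#' Two-tailed Student t critical value
#'
#' @param confidence Confidence level (default 0.95).
#' @param df Degrees of freedom, >= 1.
#' @return The quantile t(1 - (1-confidence)/2, df).
#' @examples
#' t_critical(0.95, 3) # 3.18
#' t_critical(0.95, 5) # 2.571
#' @export
t_critical <- function(confidence = 0.95, df) {
  if (df < 1) abort("`df` must be >= 1")
  if (confidence <= 0 || confidence >= 1) abort("`confidence` must be in (0, 1)")
  qt(1 - (1 - confidence) / 2, df)
}

#' Assemble a full analytical validation report
#'
#' Combines the calibration line, blank sigma, LOD/LOQ, linear range
#' (LOQ up to the highest calibration standard) and per-level accuracy and
#' precision statistics of spiked samples.
#'
#' @param calibration A `calibration_line` (slope > 0).
#' @param blanks Numeric vector of blank absorbances, length >= 2.
#' @param spiked Data frame with columns `added` and `found` (mol/L), one
#'   row per replicate; optionally an `assay` label column (e.g.
#'   "intraday"/"interday") kept in the per-level table.
#' @param top_standard Highest calibration standard (mol/L); defaults to the
#'   largest x stored in the calibration line.
#' @param confidence Confidence level for CIs and bias tests.
#' @return Object of class `validation_report` with fields `sigma_blanks`,
#'   `lod`, `loq`, `linear_range`, `levels` (per-level tibble), and
#'   `calibration`.
#' @export
build_report <- function(calibration, blanks, spiked,
                         top_standard = NULL, confidence = 0.95) {
  stopifnot(inherits(calibration, "calibration_line"))
  sp <- tibble::as_tibble(spiked)
  missing_cols <- setdiff(c("added", "found"), names(sp))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (is.null(top_standard)) {
    if (is.null(calibration$data)) {
      abort("`top_standard` is required when the calibration carries no data")
    }
    top_standard <- max(calibration$data$x)
  }
  sigma <- blank_sigma(blanks)
  lims <- lod_loq(sigma, calibration$slope)
  grouping <- intersect(c("assay", "added"), names(sp))
  levels <- sp |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      found_mean = mean(.data$found),
      sd = sd(.data$found),
      se = sd(.data$found) / sqrt(dplyr::n()),
      ci_halfwidth = t_critical(confidence, dplyr::n() - 1) *
        sd(.data$found) / sqrt(dplyr::n()),
      t_bias = bias_t(.data$found, .data$added[[1]]),
      t_crit = t_critical(confidence, dplyr::n() - 1),
      recovery_pct = recovery(.data$added[[1]], mean(.data$found)),
      n = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(sigma_blanks = sigma, lod = unname(lims[["lod"]]),
         loq = unname(lims[["loq"]]),
         linear_range = c(lo = unname(lims[["loq"]]), hi = top_standard),
         levels = levels, calibration = calibration,
         confidence = confidence, n_blanks = length(blanks)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  calibration  A = %.4g C + %.4g (R^2 %.4f)\n",
              x$calibration$slope, x$calibration$intercept,
              x$calibration$r_squared))
  cat(sprintf("  sigma(blanks) %.4g AU (n = %d)\n", x$sigma_blanks, x$n_blanks))
  cat(sprintf("  LOD %.3g | LOQ %.3g mol/L\n", x$lod, x$loq))
  cat(sprintf("  linear range %.3g - %.3g mol/L\n",
              x$linear_range[["lo"]], x$linear_range[["hi"]]))
  cat("  spiked levels:\n")
  print(x$levels)
  invisible(x)
}

#' Round half-up at a number of decimal places
#'
#' Reporting-layer rounding used when mirroring printed tables (base R
#' `round()` rounds half to even). Internal computation is never rounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @examples
#' round_half_up(101.25, 1) # 101.3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
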