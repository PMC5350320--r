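#' Log-log slope for the limit-logarithmic method
#'
#' OLS slope of log10(absorbance) against log10(concentration), one arm of
#' the limit-logarithmic stoichiometry determination (the other reactant is
#' held constant).
#'
#' @param pairs Data frame with columns `conc` and `absorbance`, all > 0,
#'   >= 3 rows.
#' @return The log-log slope (dimensionless).
#' @examples
#' d <- tibble::tibble(conc = c(1e-5, 2e-5, 4e-5), absorbance = 30 * conc^0.723)
#' limit_log_slope(d)
#' @export
limit_log_slope <- function(pairs) {
  p <- tibble::as_tibble(pairs)
  missing_cols <- setdiff(c("conc", "absorbance"), names(p))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(p) < 3) abort("at least 3 pairs are required")
  if (any(p$conc <= 0) || any(p$absorbance <= 0)) {
    abort("all concentrations and absorbances must be > 0")
  }
  fit_line(log10(p$conc), log10(p$absorbance))$slope
}

#' Snap a slope ratio to a small-integer molar ratio
#'
#' Finds the coprime integer pair (p, q), with both components at most
#' `max_denominator`, whose ratio p/q is closest to `slope_a / slope_b` on
#' the log scale (equivalently, smallest relative error). The log-scale
#' criterion makes the result exactly reciprocal: swapping the slopes swaps
#' the pair. Ties go to the smaller p + q. The residual
#' |slope_a/slope_b - p/q| is carried so callers can flag poor fits; no
#' snapping tolerance is applied.
#'
#' @param slope_a Log-log slope with the analyte varied, > 0.
#' @param slope_b Log-log slope with the oxidant varied, > 0.
#' @param max_denominator Largest integer allowed in the pair.
#' @return Object of class `molar_ratio`: fields `p`, `q`, `ratio`
#'   (slope_a/slope_b), `residual`.
#' @examples
#' molar_ratio(0.723, 0.685) # 1:1
#' molar_ratio(0.70, 0.35)   # 2:1
#' @export
molar_ratio <- function(slope_a, slope_b, max_denominator = 4) {
  stop_if_not_finite(slope_a, "slope_a"); stop_if_not_finite(slope_b, "slope_b")
  if (slope_a <= 0 || slope_b <= 0) abort("slopes must be > 0")
  if (max_denominator < 1) abort("`max_denominator` must be >= 1")
  r <- slope_a / slope_b
  grid <- tidyr::expand_grid(p = seq_len(max_denominator),
                             q = seq_len(max_denominator)) |>
    dplyr::filter(purrr::map2_int(.data$p, .data$q, gcd2) == 1L) |>
    dplyr::mutate(log_err = abs(log(r) - log(.data$p / .data$q))) |>
    dplyr::arrange(.data$log_err, .data$p + .data$q)
  best <- grid[1, ]
  structure(
    list(p = best$p[[1]], q = best$q[[1]], ratio = r,
         residual = abs(r - best$p[[1]] / best$q[[1]])),
    class = "molar_ratio"
  )
}

gcd2 <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  as.integer(a)
}

#' @export
print.molar_ratio <- function(x, ...) {
  cat(sprintf("<molar_ratio> %d:%d (slope ratio %.4g, residual %.4g)\n",
              x$p, x$q, x$ratio, x$residual))
  invisible(x)
}

#' Limit-logarithmic stoichiometry from two signal blocks
#'
#' Convenience wrapper running [limit_log_slope()] on each block of a
#' two-block table (analyte varied at constant oxidant; oxidant varied at
#' constant analyte) and snapping the slope ratio with [molar_ratio()].
#'
#' @param blocks Data frame with columns `varied` ("analyte"/"oxidant"),
#'   `conc`, `absorbance`, e.g. from [simulate_stoich_blocks()].
#' @param max_denominator Passed to [molar_ratio()].
#' @return Object of class `stoich_result`: `slope_analyte`, `slope_oxidant`,
#'   `ratio` (a `molar_ratio`).
#' @export
stoichiometry <- function(blocks, max_denominator = 4) {
  b <- tibble::as_tibble(blocks)
  missing_cols <- setdiff(c("varied", "conc", "absorbance"), names(b))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  need <- setdiff(c("analyte", "oxidant"), unique(b$varied))
  if (length(need)) {
    abort(paste0("missing block(s): ", paste(need, collapse = ", ")))
  }
  sa <- limit_log_slope(dplyr::filter(b, .data$varied == "analyte"))
  so <- limit_log_slope(dplyr::filter(b, .data$varied == "oxidant"))
  structure(
    list(slope_analyte = sa, slope_oxidant = so,
         ratio = molar_ratio(sa, so, max_denominator)),
    class = "stoich_result"
  )
}

#' @export
print.stoich_result <- function(x, ...) {
  cat("<stoich_result>\n")
  cat(sprintf("  log-log slope, analyte varied: %.4g\n", x$slope_analyte))
  cat(sprintf("  log-log slope, oxidant varied: %.4g\n", x$slope_oxidant))
  cat(sprintf("  molar ratio %d:%d (residual %.4g)\n",
              x$ratio$p, x$ratio$q, x$ratio$residual))
  invisible(x)
}
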