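#' Factor specification for a designed experiment
#'
#' @param name Factor name (used as a column name in design tables).
#' @param low,high Natural-unit levels mapped to coded -1 and +1. `low` must
#'   be strictly below `high`.
#' @param center Natural-unit centre level; defaults to the midpoint and need
#'   not be the midpoint (screening designs sometimes use an off-centre
#'   reference level). Descriptive only: the coded-to-natural affine map is
#'   fixed by `low` and `high`.
#' @return Object of class `factor_spec`.
#' @examples
#' factor_spec("temperature", 50, 80)
#' factor_spec("alkali", 0.018, 0.18, center = 0.09)
#' @export
factor_spec <- function(name, low, high, center = (low + high) / 2) {
  stopifnot(is.character(name), length(name) == 1L)
  stop_if_not_finite(low, "low"); stop_if_not_finite(high, "high")
  if (low >= high) abort("`low` must be < `high`")
  if (center <= low || center >= high) {
    abort("`center` must lie strictly between `low` and `high`")
  }
  structure(list(name = name, low = low, center = center, high = high),
            class = "factor_spec")
}

coded_to_natural <- function(spec, coded) {
  mid <- (spec$low + spec$high) / 2
  half <- (spec$high - spec$low) / 2
  mid + half * coded
}

new_doe_design <- function(coded, natural, kind, factors, responses = NULL) {
  structure(
    list(coded = tibble::as_tibble(coded),
         natural = tibble::as_tibble(natural),
         kind = kind, factors = factors, responses = responses),
    class = "doe_design"
  )
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("<doe_design> %s, %d runs, factors: %s\n", x$kind,
              nrow(x$coded), paste(names(x$coded), collapse = ", ")))
  print(dplyr::bind_cols(x$natural,
                         if (!is.null(x$responses))
                           tibble::tibble(response = x$responses)))
  invisible(x)
}

#' Add responses to a design
#'
#' @param design A `doe_design`.
#' @param responses Numeric vector, one response per design row.
#' @return The design with responses attached.
#' @export
set_responses <- function(design, responses) {
  stopifnot(inherits(design, "doe_design"))
  if (length(responses) != nrow(design$coded)) {
    abort("`responses` must have one value per design row")
  }
  design$responses <- as.numeric(responses)
  design
}

#' Two-level full factorial design
#'
#' All 2^k combinations of coded -1/+1 levels in standard (Yates) order:
#' the first factor alternates fastest.
#'
#' @param factors List of [factor_spec()]s, 2 to 8 of them.
#' @return A `doe_design` with coded and natural-unit matrices.
#' @examples
#' d <- full_factorial(list(factor_spec("a", 0, 1), factor_spec("b", 10, 20)))
#' d$coded
#' @export
full_factorial <- function(factors) {
  if (!is.list(factors) || !all(purrr::map_lgl(factors, inherits, "factor_spec"))) {
    abort("`factors` must be a list of factor_spec objects")
  }
  k <- length(factors)
  if (k < 2 || k > 8) abort("between 2 and 8 factors are supported")
  nms <- purrr::map_chr(factors, "name")
  coded <- do.call(expand.grid,
                   c(setNames(rep(list(c(-1, 1)), k), nms),
                     KEEP.OUT.ATTRS = FALSE)) |>
    tibble::as_tibble()
  natural <- purrr::map2_dfc(factors, nms, function(f, nm) {
    tibble::tibble(!!nm := coded_to_natural(f, coded[[nm]]))
  })
  new_doe_design(coded, natural, "full-factorial", factors)
}

#' Main and two-factor interaction effects of a two-level design
#'
#' Each effect is the mean response at the +1 level of the contrast minus
#' the mean at the -1 level (interaction contrasts are products of coded
#' columns). Equivalently c'y / (N/2) for contrast vector c.
#'
#' @param design A `doe_design` with responses (see [set_responses()]), or a
#'   design plus a `responses` argument.
#' @param responses Optional numeric vector overriding stored responses.
#' @return Tibble of class `doe_effects` with columns `term`, `effect`, and
#'   `coefficient` (= effect / 2, the regression coefficient on the coded
#'   scale).
#' @export
main_effects <- function(design, responses = NULL) {
  stopifnot(inherits(design, "doe_design"))
  y <- responses %||% design$responses
  if (is.null(y)) abort("design has no responses")
  if (length(y) != nrow(design$coded)) {
    abort("`responses` must have one value per design row")
  }
  coded <- design$coded
  nms <- names(coded)
  terms <- c(as.list(nms), utils::combn(nms, 2, simplify = FALSE))
  eff <- purrr::map_dfr(terms, function(tm) {
    contrast <- if (length(tm) == 1) coded[[tm]] else coded[[tm[1]]] * coded[[tm[2]]]
    tibble::tibble(
      term = paste(tm, collapse = ":"),
      effect = mean(y[contrast > 0]) - mean(y[contrast < 0])
    )
  })
  out <- dplyr::mutate(eff, coefficient = .data$effect / 2)
  class(out) <- c("doe_effects", class(out))
  out
}

#' Circumscribed central composite design for two factors
#'
#' Four factorial points (+/-1, +/-1), four axial points at +/-`alpha` on
#' each axis, and `n_center` centre points. With the default
#' `alpha = sqrt(2)` the design is rotatable and the axial points sit
#' outside the factorial square (circumscribed); `alpha = 1` gives the
#' face-centred variant.
#'
#' @param f1,f2 [factor_spec()]s for the two factors.
#' @param alpha Axial distance in coded units, >= 1.
#' @param n_center Number of centre replicates.
#' @return A `doe_design` of kind "ccc".
#' @examples
#' ccc_design(factor_spec("temperature", 50, 80), factor_spec("alkali", 0.18, 0.34))
#' @export
ccc_design <- function(f1, f2, alpha = sqrt(2), n_center = 3) {
  stopifnot(inherits(f1, "factor_spec"), inherits(f2, "factor_spec"))
  if (alpha < 1) abort("`alpha` must be >= 1")
  if (n_center < 1) abort("`n_center` must be >= 1")
  coded <- dplyr::bind_rows(
    tidyr::expand_grid(x1 = c(-1, 1), x2 = c(-1, 1)),
    tibble::tibble(x1 = c(-alpha, alpha, 0, 0), x2 = c(0, 0, -alpha, alpha)),
    tibble::tibble(x1 = rep(0, n_center), x2 = rep(0, n_center))
  )
  names(coded) <- c(f1$name, f2$name)
  natural <- tibble::tibble(
    !!f1$name := coded_to_natural(f1, coded[[f1$name]]),
    !!f2$name := coded_to_natural(f2, coded[[f2$name]])
  )
  new_doe_design(coded, natural, "ccc", list(f1, f2))
}

#' Fit a full quadratic response surface to a two-factor design
#'
#' Least-squares fit of
#' y = b0 + b1 x1 + b2 x2 + b11 x1^2 + b22 x2^2 + b12 x1 x2
#' in natural factor units, as used to model a central composite experiment.
#'
#' @param design A `doe_design` with responses, or any data frame with two
#'   factor columns and a `response` column.
#' @param responses Optional response vector overriding stored responses.
#' @return Object of class `rsm_fit`: coefficient list (`b0` ... `b12`),
#'   factor names, `r_squared`, `stationary` (point, kind) and the
#'   underlying `lm` fit.
#' @export
fit_quadratic <- function(design, responses = NULL) {
  if (inherits(design, "doe_design")) {
    nat <- design$natural
    y <- responses %||% design$responses
    if (is.null(y)) abort("design has no responses")
  } else {
    nat <- tibble::as_tibble(design)
    if (!is.null(responses)) {
      y <- responses
    } else {
      if (!"response" %in% names(nat)) abort("no `response` column or argument")
      y <- nat$response
      nat <- dplyr::select(nat, -"response")
    }
  }
  if (ncol(nat) != 2) abort("exactly two factor columns are required")
  if (length(y) != nrow(nat)) abort("one response per design row is required")
  if (nrow(dplyr::distinct(nat)) < 6) {
    abort("at least 6 distinct design points are required for a quadratic")
  }
  nms <- names(nat)
  d <- tibble::tibble(x1 = nat[[1]], x2 = nat[[2]], y = as.numeric(y))
  fit <- lm(y ~ x1 + x2 + I(x1^2) + I(x2^2) + x1:x2, data = d)
  if (anyNA(coef(fit))) abort("rank-deficient design: quadratic not estimable")
  cf <- coef(fit)
  coefs <- list(b0 = unname(cf[["(Intercept)"]]), b1 = unname(cf[["x1"]]),
                b2 = unname(cf[["x2"]]), b11 = unname(cf[["I(x1^2)"]]),
                b22 = unname(cf[["I(x2^2)"]]), b12 = unname(cf[["x1:x2"]]))
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((d$y - mean(d$y))^2)
  r2 <- if (sst == 0) 1 else max(0, min(1, 1 - sse / sst))
  out <- structure(
    list(coefficients = coefs, factor_names = nms, r_squared = r2,
         data = d, lm_fit = fit),
    class = "rsm_fit"
  )
  out$stationary <- stationary_point(out)
  out
}

#' @export
print.rsm_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("<rsm_fit>\n")
  cat(sprintf("  y = %.4g + %.4g %s + %.4g %s + %.4g %s^2 + %.4g %s^2 + %.4g %s:%s\n",
              cf$b0, cf$b1, x$factor_names[1], cf$b2, x$factor_names[2],
              cf$b11, x$factor_names[1], cf$b22, x$factor_names[2],
              cf$b12, x$factor_names[1], x$factor_names[2]))
  cat(sprintf("  R^2 %.4f | stationary %s at (%.4g, %.4g)\n", x$r_squared,
              x$stationary$kind, x$stationary$point[1], x$stationary$point[2]))
  invisible(x)
}

#' Stationary point of a fitted quadratic surface
#'
#' Solves grad y = 0 for the fitted quadratic and classifies the stationary
#' point by the eigenvalue signs of the Hessian (maximum / minimum / saddle).
#' A singular Hessian (ridge system) is reported as kind "ridge" with an
#' `NA` point.
#'
#' @param model An `rsm_fit` or a coefficient list with `b1, b2, b11, b22,
#'   b12`.
#' @return List with `point` (named numeric length 2), `kind`, and
#'   `hessian_eigenvalues`.
#' @export
stationary_point <- function(model) {
  cf <- if (inherits(model, "rsm_fit")) model$coefficients else model
  nms <- if (inherits(model, "rsm_fit")) model$factor_names else c("x1", "x2")
  H <- matrix(c(2 * cf$b11, cf$b12, cf$b12, 2 * cf$b22), 2, 2)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (abs(det(H)) < .Machine$double.eps * max(abs(H), 1)^2 * 100) {
    return(list(point = setNames(c(NA_real_, NA_real_), nms), kind = "ridge",
                hessian_eigenvalues = ev))
  }
  pt <- solve(H, -c(cf$b1, cf$b2))
  kind <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum" else "saddle"
  list(point = setNames(pt, nms), kind = kind, hessian_eigenvalues = ev)
}

#' Constrained maximum of a fitted quadratic over a box
#'
#' Analytic argmax of the fitted quadratic over a rectangular region, with
#' optional pinned coordinates: considers the interior stationary point (if
#' it is a maximum inside the box), the four edges (1-D quadratics over an
#' interval) and the corners.
#'
#' @param model An `rsm_fit`.
#' @param box Named list mapping factor names to `c(lo, hi)` bounds.
#' @param fixed Optional named list pinning factors to fixed values.
#' @return List with `point` (named), `value` (predicted response), and
#'   `boundary` (logical: does the optimum sit on the box edge).
#' @examples
#' # pin temperature and maximize over alkali
#' @export
constrained_optimum <- function(model, box, fixed = NULL) {
  stopifnot(inherits(model, "rsm_fit"))
  cf <- model$coefficients
  nms <- model$factor_names
  lo <- c(NA_real_, NA_real_); hi <- c(NA_real_, NA_real_)
  for (i in 1:2) {
    b <- box[[nms[[i]]]]
    if (is.null(b)) abort(paste0("box is missing factor `", nms[[i]], "`"))
    if (b[[1]] > b[[2]]) abort("empty feasible set: lo > hi")
    lo[i] <- b[[1]]; hi[i] <- b[[2]]
  }
  if (!is.null(fixed)) {
    for (nm in names(fixed)) {
      i <- match(nm, nms)
      if (is.na(i)) abort(paste0("unknown fixed factor `", nm, "`"))
      lo[i] <- hi[i] <- fixed[[nm]]
    }
  }
  f <- function(x1, x2) eval_quadratic(cf, x1, x2)

  cand <- list()
  add <- function(x1, x2) cand[[length(cand) + 1]] <<- c(x1, x2)

  # interior stationary point
  st <- stationary_point(model)
  if (st$kind == "maximum" &&
      st$point[1] >= lo[1] && st$point[1] <= hi[1] &&
      st$point[2] >= lo[2] && st$point[2] <= hi[2]) {
    add(st$point[[1]], st$point[[2]])
  }
  # edges: x1 pinned at a bound, 1-D quadratic in x2 (and vice versa)
  clamp <- function(x, a, b) min(max(x, a), b)
  for (x1 in unique(c(lo[1], hi[1]))) {
    # y(x2) = (b22) x2^2 + (b2 + b12 x1) x2 + const
    if (cf$b22 < 0) add(x1, clamp(-(cf$b2 + cf$b12 * x1) / (2 * cf$b22),
                                  lo[2], hi[2]))
  }
  for (x2 in unique(c(lo[2], hi[2]))) {
    if (cf$b11 < 0) add(clamp(-(cf$b1 + cf$b12 * x2) / (2 * cf$b11),
                              lo[1], hi[1]), x2)
  }
  # corners
  for (x1 in unique(c(lo[1], hi[1]))) for (x2 in unique(c(lo[2], hi[2]))) {
    add(x1, x2)
  }
  vals <- purrr::map_dbl(cand, function(p) f(p[1], p[2]))
  best <- cand[[which.max(vals)]]
  on_edge <- any(abs(best - lo) < 1e-12 | abs(best - hi) < 1e-12)
  list(point = setNames(best, nms), value = max(vals), boundary = on_edge)
}
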