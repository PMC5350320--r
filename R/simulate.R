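#' Kinetic parameters of the simulated oxidation reaction
#'
#' Bundles the "true" parameters used by the synthetic-data generator:
#' the product chromophore's molar absorptivity times path length, the
#' pseudo-nth-order rate coefficient of analyte consumption, the reaction
#' order in the analyte, the blank (baseline) absorbance, the additive
#' Gaussian noise SD of the detector, and the product:analyte stoichiometric
#' ratio.
#'
#' The defaults describe an alkaline permanganate oxidation monitored through
#' the green manganate product at 610 nm: slope and intercept of the
#' standards calibration line (1.364e4 AU L mol^-1 and 5.20e-3 AU), a blank
#' SD of 9.90e-3 AU, first-order consumption of the analyte, and a rate
#' coefficient giving >= 95% conversion at 1800 s so that the fixed-time
#' response plateaus at 30 min.
#'
#' @param epsilon_l Molar absorptivity x path length (AU L mol^-1), > 0.
#' @param k_prime Rate coefficient (s^-1 (mol/L)^(1-n)), > 0.
#' @param order_n Reaction order in the analyte, > 0.
#' @param baseline Blank absorbance offset (AU).
#' @param noise_sd Additive Gaussian noise SD on absorbance (AU), >= 0.
#' @param stoich_ratio Moles of chromophore formed per mole of analyte
#'   consumed, > 0.
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' kinetic_params()
#' kinetic_params(order_n = 0.938, k_prime = 4.70)
#' @export
kinetic_params <- function(epsilon_l = 1.364e4,
                           k_prime = 1.7e-3,
                           order_n = 1,
                           baseline = 5.20e-3,
                           noise_sd = 9.90e-3,
                           stoich_ratio = 1) {
  for (nm in c("epsilon_l", "k_prime", "order_n", "baseline", "noise_sd",
               "stoich_ratio")) {
    stop_if_not_finite(get(nm), nm)
  }
  if (epsilon_l <= 0) abort("`epsilon_l` must be > 0")
  if (k_prime <= 0) abort("`k_prime` must be > 0")
  if (order_n <= 0) abort("`order_n` must be > 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (stoich_ratio <= 0) abort("`stoich_ratio` must be > 0")
  structure(
    list(epsilon_l = epsilon_l, k_prime = k_prime, order_n = order_n,
         baseline = baseline, noise_sd = noise_sd,
         stoich_ratio = stoich_ratio),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  epsilon*l  %.4g AU L/mol\n", x$epsilon_l))
  cat(sprintf("  k'         %.4g s^-1 (mol/L)^(1-n)\n", x$k_prime))
  cat(sprintf("  order n    %.4g\n", x$order_n))
  cat(sprintf("  baseline   %.4g AU\n", x$baseline))
  cat(sprintf("  noise sd   %.4g AU\n", x$noise_sd))
  cat(sprintf("  stoich     %.4g product/analyte\n", x$stoich_ratio))
  invisible(x)
}

#' Reaction conditions attached to a simulated trace
#'
#' @param analyte Analyte concentration (mol/L), >= 0.
#' @param oxidant Oxidant (permanganate) concentration (mol/L).
#' @param alkali Alkali (NaOH) concentration (mol/L).
#' @param salt Inert salt (ionic-strength) concentration (mol/L).
#' @param temperature Reaction temperature (degrees C).
#' @param wavelength Monitoring wavelength (nm).
#' @return A named list of class `reaction_conditions`.
#' @export
reaction_conditions <- function(analyte = 2.3e-5, oxidant = 9.0e-4,
                                alkali = 0.34, salt = 0.2,
                                temperature = 50, wavelength = 610) {
  if (analyte < 0) abort("`analyte` concentration must be >= 0")
  structure(
    list(analyte = analyte, oxidant = oxidant, alkali = alkali, salt = salt,
         temperature = temperature, wavelength = wavelength),
    class = "reaction_conditions"
  )
}

# Analyte concentration profile c(t) under dc/dt = -k' c^n, clamped at 0.
# Closed form for n = 1; deSolve RK4 on a mesh no coarser than 1 s otherwise.
analyte_profile <- function(c0, k_prime, order_n, times) {
  if (c0 == 0) return(rep(0, length(times)))
  if (order_n == 1) return(c0 * exp(-k_prime * times))
  mesh <- sort(unique(c(times, seq(min(times), max(times), by = 1))))
  rhs <- function(t, y, parms) {
    list(-parms$k * max(y[[1]], 0)^parms$n)
  }
  sol <- deSolve::ode(y = c(conc = c0), times = mesh, func = rhs,
                      parms = list(k = k_prime, n = order_n),
                      method = "rk4")
  pmax(sol[match(times, mesh), "conc"], 0)
}

#' Simulate one absorbance-time trace
#'
#' The analyte decays as dc/dt = -k' c^n (closed form for n = 1, fixed-step
#' RK4 with mesh <= 1 s otherwise, concentration clamped at zero); the
#' chromophore accumulates as p(t) = stoich_ratio (c0 - c(t)); the measured
#' absorbance is baseline + epsilon_l p(t) plus additive Gaussian noise.
#'
#' @param c0 Initial analyte concentration (mol/L), >= 0.
#' @param params A [kinetic_params()] object.
#' @param time_grid Strictly increasing measurement times (s), first >= 0,
#'   length >= 2.
#' @param seed Optional integer seed; identical inputs and seed give
#'   bitwise-identical output. The global RNG state is left untouched.
#' @param conditions A [reaction_conditions()] record stored with the trace.
#' @return A tibble of class `kin_curve` with columns `time_s` and
#'   `absorbance`, and attributes `params` and `conditions`.
#' @examples
#' curve <- simulate_curve(2.3e-5, kinetic_params(noise_sd = 0),
#'                         time_grid = seq(0, 3600, by = 60))
#' head(curve)
#' @export
simulate_curve <- function(c0,
                           params = kinetic_params(),
                           time_grid = seq(0, 3600, by = 30),
                           seed = NULL,
                           conditions = reaction_conditions(analyte = c0)) {
  stop_if_not_finite(c0, "c0")
  if (c0 < 0) abort("`c0` must be >= 0")
  stopifnot(inherits(params, "kinetic_params"))
  stop_if_not_finite(time_grid, "time_grid")
  if (length(time_grid) < 2) abort("`time_grid` must have length >= 2")
  if (any(diff(time_grid) <= 0)) abort("`time_grid` must be strictly increasing")
  if (time_grid[[1]] < 0) abort("`time_grid` must start at >= 0")

  conc <- analyte_profile(c0, params$k_prime, params$order_n, time_grid)
  product <- params$stoich_ratio * (c0 - conc)
  signal <- params$baseline + params$epsilon_l * product
  noise <- if (params$noise_sd > 0) {
    with_seed_if(seed, stats::rnorm(length(time_grid), 0, params$noise_sd))
  } else {
    rep(0, length(time_grid))
  }
  out <- tibble::tibble(time_s = as.numeric(time_grid),
                        absorbance = signal + noise)
  structure(out,
            params = params,
            conditions = conditions,
            analyte_conc = conc,
            class = c("kin_curve", class(out)))
}

#' Simulate independent reagent blanks
#'
#' Seeded Gaussian draws centred on the baseline absorbance, mimicking
#' repeated measurement of reagent blanks without analyte.
#'
#' @param n_blanks Number of blanks, >= 2.
#' @param baseline Mean blank absorbance (AU).
#' @param noise_sd Blank SD (AU), >= 0.
#' @param seed Optional integer seed.
#' @return Numeric vector of blank absorbances (AU).
#' @examples
#' simulate_blanks(11, seed = 1)
#' @export
simulate_blanks <- function(n_blanks = 11, baseline = 5.20e-3,
                            noise_sd = 9.90e-3, seed = NULL) {
  if (n_blanks < 2) abort("`n_blanks` must be >= 2")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (noise_sd == 0) return(rep(baseline, n_blanks))
  with_seed_if(seed, stats::rnorm(n_blanks, baseline, noise_sd))
}

#' Simulate a fixed-time calibration set
#'
#' Runs one simulated kinetic trace per replicate per standard concentration
#' and reads the absorbance at the fixed reaction time.
#'
#' @param concs Standard concentrations (mol/L), non-empty, >= 0. The default
#'   spans 6.0e-6 to 5.0e-5 mol/L, the working range of the assay.
#' @param params A [kinetic_params()] object.
#' @param fixed_time Reaction time at which absorbance is read (s).
#' @param replicates Replicates per concentration.
#' @param seed Optional integer seed.
#' @return A tibble with columns `conc`, `replicate`, `absorbance`.
#' @examples
#' simulate_calibration_set(seed = 7)
#' @export
simulate_calibration_set <- function(concs = c(6.0e-6, 1.0e-5, 2.0e-5,
                                               3.0e-5, 5.0e-5),
                                     params = kinetic_params(),
                                     fixed_time = 1800,
                                     replicates = 1,
                                     seed = NULL) {
  if (length(concs) == 0) abort("`concs` must be non-empty")
  stop_if_not_finite(concs, "concs")
  if (any(concs < 0)) abort("`concs` must be >= 0")
  grid <- kin_grid_for(fixed_time)
  with_seed_if(seed, {
    tidyr::expand_grid(conc = as.numeric(concs),
                       replicate = seq_len(replicates)) |>
      dplyr::mutate(absorbance = purrr::map_dbl(.data$conc, function(c0) {
        cur <- simulate_curve(c0, params, time_grid = grid, seed = NULL)
        fixed_time_absorbance(cur, fixed_time)
      }))
  })
}

# Measurement grid that contains 0 and t_fixed.
kin_grid_for <- function(t_fixed, by = 30) {
  sort(unique(c(seq(0, max(t_fixed, by), by = by), t_fixed)))
}

#' Quadratic response-surface "truth" for DoE simulation
#'
#' Constructs the coefficients of a two-factor quadratic response surface
#' (factors: temperature in degrees C and alkali concentration in mol/L)
#' whose *unconstrained* stationary maximum sits exactly at `opt` and whose
#' *conditional* maximum over alkali at the fixed temperature
#' `constrained_at[1]` is exactly `constrained_at[2]`. The interaction
#' coefficient is solved from the conditional-argmax identity
#' `alkali*(T) = opt_alkali - (b12 / (2 b22)) (T - opt_T)`.
#'
#' @param opt Unconstrained optimum `c(temperature, alkali)`.
#' @param constrained_at `c(fixed_temperature, expected_alkali)`: the alkali
#'   value at which the surface's conditional maximum must sit when the
#'   temperature is pinned.
#' @param peak_response Response (AU) at the unconstrained optimum.
#' @param b11,b22 Negative curvatures in temperature and alkali (natural
#'   units). The defaults give realistic absorbance variation over a
#'   50-86 degC x 0.18-0.34 mol/L region.
#' @param noise_sd Response noise SD (AU) used by [simulate_doe_responses()].
#' @return An object of class `doe_truth`: coefficients `b0, b1, b2, b11,
#'   b22, b12` (natural units), factor names, and `noise_sd`.
#' @examples
#' truth <- make_doe_scenario()
#' unlist(truth[c("b1", "b2", "b11", "b22", "b12")])
#' @export
make_doe_scenario <- function(opt = c(temperature = 86, alkali = 0.26),
                              constrained_at = c(temperature = 50,
                                                 alkali = 0.34),
                              peak_response = 0.32,
                              b11 = -2e-4, b22 = -8,
                              noise_sd = 0) {
  stop_if_not_finite(unname(opt), "opt")
  stop_if_not_finite(unname(constrained_at), "constrained_at")
  if (b11 >= 0 || b22 >= 0) abort("`b11` and `b22` must be negative")
  t0 <- opt[[1]]; s0 <- opt[[2]]
  tc <- constrained_at[[1]]; sc <- constrained_at[[2]]
  if (tc == t0 && sc != s0) {
    abort("inconsistent geometry: same temperature, different alkali optimum")
  }
  # conditional argmax over alkali: s*(T) = -(b2 + b12 T) / (2 b22),
  # a line through (t0, s0) with slope -b12/(2 b22)
  b12 <- if (tc == t0) 0 else -2 * b22 * (sc - s0) / (tc - t0)
  if (b12^2 >= 4 * b11 * b22) {
    abort("inconsistent geometry: no negative-definite surface satisfies both optima")
  }
  b1 <- -(2 * b11 * t0 + b12 * s0)
  b2 <- -(2 * b22 * s0 + b12 * t0)
  b0 <- peak_response -
    (b1 * t0 + b2 * s0 + b11 * t0^2 + b22 * s0^2 + b12 * t0 * s0)
  structure(
    list(b0 = b0, b1 = b1, b2 = b2, b11 = b11, b22 = b22, b12 = b12,
         factor_names = c("temperature", "alkali"),
         noise_sd = noise_sd),
    class = "doe_truth"
  )
}

# Evaluate a quadratic surface (doe_truth or plain coefficient list) at
# natural-unit factor values.
eval_quadratic <- function(coefs, x1, x2) {
  coefs$b0 + coefs$b1 * x1 + coefs$b2 * x2 +
    coefs$b11 * x1^2 + coefs$b22 * x2^2 + coefs$b12 * x1 * x2
}

#' Simulate responses of a design from a quadratic truth surface
#'
#' @param design A `doe_design` (see [ccc_design()], [full_factorial()]) or a
#'   data frame whose columns include the truth's factor names in natural
#'   units.
#' @param truth A `doe_truth` from [make_doe_scenario()].
#' @param seed Optional integer seed.
#' @return Numeric vector of responses (AU), one per design row.
#' @export
simulate_doe_responses <- function(design, truth, seed = NULL) {
  stopifnot(inherits(truth, "doe_truth"))
  nat <- if (inherits(design, "doe_design")) design$natural else
    tibble::as_tibble(design)
  missing_cols <- setdiff(truth$factor_names, names(nat))
  if (length(missing_cols)) {
    abort(paste0("design lacks factor column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  mu <- eval_quadratic(truth, nat[[truth$factor_names[[1]]]],
                       nat[[truth$factor_names[[2]]]])
  if (truth$noise_sd == 0) return(as.numeric(mu))
  as.numeric(mu + with_seed_if(seed, stats::rnorm(length(mu), 0, truth$noise_sd)))
}

#' Linear screening "truth" for a two-level factorial
#'
#' Coded-unit linear model used to emulate a screening experiment in which
#' temperature and alkali dominate the response.
#'
#' @param effects Named numeric vector of *effects* (response change from
#'   level -1 to +1) per factor, in coded units.
#' @param intercept Mean response (AU).
#' @param noise_sd Response noise SD (AU).
#' @return Object of class `screening_truth`.
#' @export
make_screening_scenario <- function(effects = c(oxidant = 0.010,
                                                salt = 0.004,
                                                alkali = 0.080,
                                                temperature = 0.120),
                                    intercept = 0.25,
                                    noise_sd = 0) {
  stopifnot(is.numeric(effects), !is.null(names(effects)))
  structure(list(effects = effects, intercept = intercept,
                 noise_sd = noise_sd),
            class = "screening_truth")
}

#' Simulate screening responses on a coded two-level design
#'
#' @param design A `doe_design` from [full_factorial()].
#' @param truth A `screening_truth` from [make_screening_scenario()].
#' @param seed Optional integer seed.
#' @return Numeric vector of responses, one per design row.
#' @export
simulate_screening_responses <- function(design, truth, seed = NULL) {
  stopifnot(inherits(design, "doe_design"), inherits(truth, "screening_truth"))
  coded <- design$coded
  missing_cols <- setdiff(names(truth$effects), names(coded))
  if (length(missing_cols)) {
    abort(paste0("design lacks factor column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  # coefficient on a coded +/-1 column is effect/2
  mu <- truth$intercept
  for (nm in names(truth$effects)) {
    mu <- mu + (truth$effects[[nm]] / 2) * coded[[nm]]
  }
  if (truth$noise_sd == 0) return(as.numeric(mu))
  as.numeric(mu + with_seed_if(seed, stats::rnorm(length(mu), 0, truth$noise_sd)))
}

#' Simulate the two signal blocks of a limit-logarithmic experiment
#'
#' Generates power-law signal blocks `A = scale * conc^exponent` (with
#' optional multiplicative log-normal noise) for the two arms of a
#' limit-logarithmic stoichiometry determination: analyte varied at constant
#' oxidant, and oxidant varied at constant analyte. The default exponents
#' are the empirical log-log slopes of the alkaline permanganate assay
#' (0.723 and 0.685), giving a 1:1 molar ratio.
#'
#' @param analyte_concs,oxidant_concs Concentration grids (mol/L), > 0.
#' @param exponents Named vector `c(analyte = , oxidant = )` of log-log
#'   slopes, > 0.
#' @param scales Named vector of proportionality constants, > 0.
#' @param noise_sd SD of Gaussian noise on log10(signal); 0 for exact
#'   power laws.
#' @param seed Optional integer seed.
#' @return A tibble with columns `varied` ("analyte"/"oxidant"), `conc`,
#'   `absorbance`.
#' @export
simulate_stoich_blocks <- function(analyte_concs = seq(6e-6, 5e-5,
                                                       length.out = 6),
                                   oxidant_concs = seq(5e-4, 9.1e-4,
                                                       length.out = 6),
                                   exponents = c(analyte = 0.723,
                                                 oxidant = 0.685),
                                   scales = c(analyte = 30, oxidant = 25),
                                   noise_sd = 0,
                                   seed = NULL) {
  if (any(analyte_concs <= 0) || any(oxidant_concs <= 0)) {
    abort("concentrations must be > 0")
  }
  if (any(exponents <= 0)) abort("`exponents` must be > 0")
  blocks <- dplyr::bind_rows(
    tibble::tibble(varied = "analyte", conc = as.numeric(analyte_concs),
                   mu = scales[["analyte"]] * analyte_concs^exponents[["analyte"]]),
    tibble::tibble(varied = "oxidant", conc = as.numeric(oxidant_concs),
                   mu = scales[["oxidant"]] * oxidant_concs^exponents[["oxidant"]])
  )
  log_noise <- if (noise_sd > 0) {
    with_seed_if(seed, stats::rnorm(nrow(blocks), 0, noise_sd))
  } else {
    rep(0, nrow(blocks))
  }
  blocks |>
    dplyr::mutate(absorbance = 10^(log10(.data$mu) + log_noise)) |>
    dplyr::select("varied", "conc", "absorbance")
}
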