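#' Instantaneous rate-concentration pairs from simulated traces
#'
#' For each starting concentration, simulates a short noiseless trace and
#' extracts one point of the rate law: the analyte concentration at
#' `t_eval` recovered from the absorbance (Beer-Lambert inversion) and the
#' reaction velocity -dc/dt at `t_eval` by a central finite difference of
#' step `h`. Because every (c(t), v(t)) point of a trajectory lies exactly
#' on v = k' c^n, feeding these pairs to [estimate_order_and_rate()]
#' recovers the generator order and rate coefficient.
#'
#' @param concs Starting concentrations (mol/L), > 0.
#' @param params A [kinetic_params()] object; its `noise_sd` is ignored
#'   (rates are extracted from noiseless signal).
#' @param t_eval Evaluation time (s), > 0.
#' @param h Finite-difference half-step (s), 0 < h <= t_eval.
#' @return Tibble with columns `conc` (mol/L) and `rate` (mol/L/s).
#' @export
rate_pairs_from_curves <- function(concs, params = kinetic_params(),
                                   t_eval = 1e-4, h = 1e-4) {
  if (any(concs <= 0)) abort("`concs` must be > 0")
  if (h <= 0 || h > t_eval) abort("need 0 < h <= t_eval")
  quiet <- kinetic_params(epsilon_l = params$epsilon_l,
                          k_prime = params$k_prime,
                          order_n = params$order_n,
                          baseline = params$baseline,
                          noise_sd = 0,
                          stoich_ratio = params$stoich_ratio)
  scale <- params$epsilon_l * params$stoich_ratio
  purrr::map_dfr(concs, function(c0) {
    grid <- sort(unique(c(0, t_eval - h, t_eval, t_eval + h)))
    cur <- simulate_curve(c0, quiet, time_grid = grid)
    a <- function(t) fixed_time_absorbance(cur, t)
    conc_t <- c0 - (a(t_eval) - quiet$baseline) / scale
    vel <- (a(t_eval + h) - a(t_eval - h)) / (2 * h) / scale
    tibble::tibble(conc = conc_t, rate = vel)
  })
}
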