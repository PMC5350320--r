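#' Configuration of an end-to-end assay pipeline run
#'
#' Collects every tunable of [run_pipeline()] with defaults matching the
#' assay's study conditions: five calibration standards between 6.0e-6 and
#' 3.0e-5 mol/L for the fixed-time study, candidate times 0-60 min, a
#' tap-water-style validation calibration from 2.3e-6 to 3.22e-5 mol/L,
#' 11 reagent blanks, and three spiked levels (8.0e-6, 1.0e-5, 3.0e-5
#' mol/L) with six replicates each.
#'
#' @param seed Integer root seed; all stage seeds derive from it.
#' @param params [kinetic_params()] describing the reaction and detector.
#' @param ft_concs Standards (mol/L) for the fixed-time study.
#' @param candidate_times_min Candidate fixed times (minutes).
#' @param slope_fraction,confidence Passed to [select_fixed_time()].
#' @param val_concs Standards (mol/L) for the validation calibration.
#' @param n_blanks Number of reagent blanks.
#' @param spiked_levels Spiked concentrations (mol/L).
#' @param spiked_replicates Replicates per spiked level.
#' @param stoich_noise_sd Noise SD on log10 signal for the stoichiometry
#'   blocks.
#' @param doe_truth A `doe_truth` for the response-surface stage.
#' @param doe_noise_sd Response noise SD (AU) for both DoE stages.
#' @param out_dir Optional directory; when set, [run_pipeline()] writes all
#'   artifacts there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            params = kinetic_params(),
                            ft_concs = c(6.0e-6, 1.2e-5, 1.8e-5, 2.4e-5, 3.0e-5),
                            candidate_times_min = seq(0, 60, by = 10),
                            slope_fraction = 0.95,
                            confidence = 0.95,
                            val_concs = c(2.3e-6, 8.0e-6, 1.5e-5, 2.4e-5, 3.22e-5),
                            n_blanks = 11,
                            spiked_levels = c(8.0e-6, 1.0e-5, 3.0e-5),
                            spiked_replicates = 6,
                            stoich_noise_sd = 0.01,
                            doe_truth = make_doe_scenario(),
                            doe_noise_sd = 2e-3,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Deterministic stage seeds below 2^31, all derived from the root seed.
stage_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Run the full kinetic-assay pipeline
#'
#' Executes, in order: simulation of the fixed-time study and selection of
#' the optimal fixed time; the initial-rate and rate-constant method
#' calibrations; reaction order and rate recovery; limit-logarithmic
#' stoichiometry; factorial screening and central-composite response-surface
#' optimization; and the spiked-sample validation report. Fully
#' deterministic under the config seed. If `config$out_dir` is set, all
#' tables and a plain-text report are written there.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `kin_pipeline` with components `fixed_time`
#'   (candidate table + selected time), `kinetic_methods` (initial-rate and
#'   rate-constant lines), `order_rate` (a `kinetic_fit`), `stoichiometry`
#'   (a `stoich_result`), `doe` (screening effects, RSM fit, optima), and
#'   `validation` (a `validation_report`).
#' @examples
#' res <- run_pipeline(pipeline_config(seed = 1))
#' res$fixed_time$selected_min
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  seed <- config$seed
  grid <- seq(0, max(config$candidate_times_min) * 60 + 60, by = 30)

  ## --- fixed-time study -------------------------------------------------
  curves <- purrr::imap(config$ft_concs, function(c0, i) {
    simulate_curve(c0, p, time_grid = grid, seed = stage_seed(seed, 100 + i))
  })
  candidates <- purrr::map_dfr(config$candidate_times_min, function(tm) {
    ab <- purrr::map_dbl(curves, fixed_time_absorbance, t_fixed = tm * 60)
    line <- fit_line(config$ft_concs, ab)
    tibble::tibble(time_min = tm, slope = line$slope,
                   intercept = line$intercept, r_squared = line$r_squared,
                   se_regression = line$se_regression,
                   t_corr = line$t_corr, n_points = line$n_points)
  })
  selected <- select_fixed_time(candidates,
                                slope_fraction = config$slope_fraction,
                                confidence = config$confidence)
  t_fixed_s <- selected * 60

  ## --- initial-rate and rate-constant method calibrations ---------------
  init_rates <- purrr::map_dbl(curves, estimate_initial_rate)
  eq_initial <- fit_line(config$ft_concs, init_rates)
  log_rates <- purrr::map_dbl(curves, estimate_log_slope_rate)
  eq_constant <- fit_line(config$ft_concs, log_rates)

  ## --- reaction order and rate ------------------------------------------
  order_rate <- estimate_order_and_rate(
    rate_pairs_from_curves(config$ft_concs, p)
  )

  ## --- stoichiometry ----------------------------------------------------
  blocks <- simulate_stoich_blocks(noise_sd = config$stoich_noise_sd,
                                   seed = stage_seed(seed, 300))
  stoich <- stoichiometry(blocks)

  ## --- DoE: screening then response surface -----------------------------
  screening_factors <- list(
    factor_spec("oxidant", 7e-4, 9e-4),
    factor_spec("salt", 0.2, 0.4),
    factor_spec("alkali", 0.018, 0.18, center = 0.09),
    factor_spec("temperature", 35, 65)
  )
  screen_design <- full_factorial(screening_factors)
  screen_truth <- make_screening_scenario(noise_sd = config$doe_noise_sd)
  screen_design <- set_responses(
    screen_design,
    simulate_screening_responses(screen_design, screen_truth,
                                 seed = stage_seed(seed, 400))
  )
  effects <- main_effects(screen_design)

  f_temp <- factor_spec("temperature", 50, 80)
  f_alk <- factor_spec("alkali", 0.18, 0.34)
  ccc <- ccc_design(f_temp, f_alk)
  truth <- config$doe_truth
  truth$noise_sd <- config$doe_noise_sd
  ccc <- set_responses(ccc, simulate_doe_responses(ccc, truth,
                                                   seed = stage_seed(seed, 410)))
  rsm <- fit_quadratic(ccc)
  box <- list(temperature = c(35, 90), alkali = c(0.018, 0.34))
  constrained <- constrained_optimum(rsm, box,
                                     fixed = list(temperature = 50))

  ## --- validation -------------------------------------------------------
  val_cal_tbl <- simulate_calibration_set(config$val_concs, p,
                                          fixed_time = t_fixed_s,
                                          seed = stage_seed(seed, 500))
  val_cal <- fixed_time_calibration(val_cal_tbl)
  blanks <- simulate_blanks(config$n_blanks, p$baseline, p$noise_sd,
                            seed = stage_seed(seed, 510))
  spiked <- purrr::imap_dfr(config$spiked_levels, function(lvl, i) {
    tbl <- simulate_calibration_set(lvl, p, fixed_time = t_fixed_s,
                                    replicates = config$spiked_replicates,
                                    seed = stage_seed(seed, 520 + i))
    tibble::tibble(added = lvl, found = quantify(tbl$absorbance, val_cal))
  })
  report <- build_report(val_cal, blanks, spiked,
                         top_standard = max(config$val_concs),
                         confidence = config$confidence)

  out <- structure(
    list(config = config,
         fixed_time = list(candidates = candidates, selected_min = selected),
         kinetic_methods = list(initial_rate = eq_initial,
                                rate_constant = eq_constant,
                                initial_rates = tibble::tibble(
                                  conc = config$ft_concs, rate = init_rates),
                                log_slope_rates = tibble::tibble(
                                  conc = config$ft_concs, rate = log_rates)),
         order_rate = order_rate,
         stoichiometry = stoich,
         doe = list(screening = screen_design, effects = effects,
                    rsm = rsm, stationary = rsm$stationary,
                    constrained = constrained),
         validation = report),
    class = "kin_pipeline"
  )
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

#' @export
print.kin_pipeline <- function(x, ...) {
  cat("<kin_pipeline>\n")
  cat(sprintf("  selected fixed time: %g min\n", x$fixed_time$selected_min))
  cat(sprintf("  order n %.3f, k' %.4g\n", x$order_rate$order_n,
              x$order_rate$k_prime))
  cat(sprintf("  stoichiometry %d:%d\n", x$stoichiometry$ratio$p,
              x$stoichiometry$ratio$q))
  cat(sprintf("  RSM stationary (%s): %s\n", x$doe$stationary$kind,
              paste(sprintf("%.4g", x$doe$stationary$point), collapse = ", ")))
  cat(sprintf("  LOD %.3g, LOQ %.3g mol/L\n", x$validation$lod,
              x$validation$loq))
  cat(sprintf("  recoveries %% : %s\n",
              paste(sprintf("%.1f", x$validation$levels$recovery_pct),
                    collapse = ", ")))
  invisible(x)
}

## ---------------------------------------------------------------------------
## File I/O

#' Write an absorbance-time trace as annotated CSV
#'
#' A header block of `# key: value` lines records the reaction conditions,
#' followed by CSV columns `time_s`, `absorbance`. The round trip through
#' [read_timeseries()] is lossless to full double precision.
#'
#' @param ts A `kin_curve` or data frame with `time_s`, `absorbance`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  ts_df <- as_kin_frame(ts)
  cond <- attr(ts, "conditions")
  header <- character()
  if (!is.null(cond)) {
    header <- sprintf("# %s: %.17g", names(cond), unlist(cond))
  }
  body <- c("time_s,absorbance",
            sprintf("%.17g,%.17g", ts_df$time_s, ts_df$absorbance))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an absorbance-time trace written by [write_timeseries()]
#'
#' @param path File path.
#' @return A `kin_curve` tibble; any `# key: value` header lines are parsed
#'   into the `conditions` attribute.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  cond <- NULL
  if (any(is_hdr)) {
    kv <- sub("^#\\s*", "", lines[is_hdr])
    keys <- sub(":.*$", "", kv)
    vals <- as.numeric(sub("^[^:]*:\\s*", "", kv))
    cond <- setNames(as.list(vals), keys)
  }
  tbl <- read_kin_table(I(lines[!is_hdr]), required = c("time_s", "absorbance"))
  structure(tbl, conditions = cond, class = c("kin_curve", class(tbl)))
}

#' Read a CSV table, checking required columns
#'
#' Thin wrapper over `readr::read_csv` (locale-independent: dot decimal
#' separator) that errors naming any missing required column.
#'
#' @param path File path (or literal `I(lines)`).
#' @param required Character vector of required column names.
#' @return A tibble.
#' @export
read_kin_table <- function(path, required = character()) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  tbl
}

#' Write all pipeline artifacts to a directory
#'
#' Writes the fixed-time candidate table, kinetic-method rate tables, DoE
#' design/response and effect tables, per-level validation table (CSV), and
#' a plain-text summary report. Output is byte-identical across runs with
#' the same config and seed.
#'
#' @param result A `kin_pipeline` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(result, out_dir) {
  stopifnot(inherits(result, "kin_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, name), progress = FALSE)
  }
  wcsv(result$fixed_time$candidates, "fixed_time_candidates.csv")
  wcsv(result$kinetic_methods$initial_rates, "initial_rates.csv")
  wcsv(result$kinetic_methods$log_slope_rates, "log_slope_rates.csv")
  wcsv(dplyr::bind_cols(result$doe$screening$natural,
                        tibble::tibble(response = result$doe$screening$responses)),
       "screening_design.csv")
  wcsv(tibble::as_tibble(result$doe$effects), "screening_effects.csv")
  wcsv(dplyr::bind_cols(result$doe$rsm$data |>
                          setNames(c(result$doe$rsm$factor_names, "response"))),
       "ccc_design.csv")
  wcsv(result$validation$levels, "validation_levels.csv")

  v <- result$validation
  st <- result$doe$stationary
  lines <- c(
    "kinetic assay pipeline report",
    sprintf("seed: %s", format(result$config$seed)),
    sprintf("selected fixed time (min): %g", result$fixed_time$selected_min),
    sprintf("initial-rate line: K'' = %.6g C + %.6g (R^2 %.4f)",
            result$kinetic_methods$initial_rate$slope,
            result$kinetic_methods$initial_rate$intercept,
            result$kinetic_methods$initial_rate$r_squared),
    sprintf("rate-constant line: K' = %.6g C + %.6g (R^2 %.4f)",
            result$kinetic_methods$rate_constant$slope,
            result$kinetic_methods$rate_constant$intercept,
            result$kinetic_methods$rate_constant$r_squared),
    sprintf("reaction order n: %.6g ; k': %.6g", result$order_rate$order_n,
            result$order_rate$k_prime),
    sprintf("stoichiometry slopes: %.6g (analyte), %.6g (oxidant) -> %d:%d",
            result$stoichiometry$slope_analyte,
            result$stoichiometry$slope_oxidant,
            result$stoichiometry$ratio$p, result$stoichiometry$ratio$q),
    sprintf("RSM stationary point (%s): %s = %.6g, %s = %.6g", st$kind,
            result$doe$rsm$factor_names[1], st$point[1],
            result$doe$rsm$factor_names[2], st$point[2]),
    sprintf("constrained optimum at %s: %s = %.6g",
            "temperature = 50", "alkali",
            result$doe$constrained$point[["alkali"]]),
    sprintf("calibration: A = %.6g C + %.6g (R^2 %.5f)",
            v$calibration$slope, v$calibration$intercept,
            v$calibration$r_squared),
    sprintf("sigma(blanks): %.6g AU (n = %d)", v$sigma_blanks, v$n_blanks),
    sprintf("LOD: %.6g mol/L ; LOQ: %.6g mol/L", v$lod, v$loq),
    sprintf("linear range: %.6g - %.6g mol/L", v$linear_range[["lo"]],
            v$linear_range[["hi"]]),
    sprintf("recoveries (%%): %s",
            paste(sprintf("%.6g", v$levels$recovery_pct), collapse = ", "))
  )
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
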