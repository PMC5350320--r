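test_that("noiseless curve starts at baseline and plateaus at full conversion", {
  p <- quiet_params()
  cur <- simulate_curve(2.3e-5, p, time_grid = c(0, 600, 1e6, 2e6))
  expect_equal(cur$absorbance[[1]], p$baseline)
  expect_equal(cur$absorbance[[4]], p$baseline + p$epsilon_l * 2.3e-5,
               tolerance = 1e-9)
  # zero analyte: flat at baseline
  cur0 <- simulate_curve(0, p, time_grid = c(0, 600, 1200))
  expect_true(all(cur0$absorbance == p$baseline))
})

test_that("first-order closed form matches an independent ODE solver", {
  p <- quiet_params(k_prime = 1.5e-3)
  grid <- seq(0, 1800, by = 60)
  cur <- simulate_curve(2.3e-5, p, time_grid = grid)
  sol <- deSolve::ode(y = c(conc = 2.3e-5), times = grid,
                      func = function(t, y, parms) list(-1.5e-3 * y),
                      method = "lsoda", rtol = 1e-12, atol = 1e-18)
  oracle <- p$baseline + p$epsilon_l * (2.3e-5 - sol[, "conc"])
  expect_equal(cur$absorbance, unname(oracle), tolerance = 1e-9)
})

test_that("non-unit orders integrate to the analytic power-law solution", {
  for (n in c(0.7, 0.938, 1.5)) {
    k <- 2e-3; c0 <- 2.3e-5
    p <- quiet_params(k_prime = k, order_n = n)
    grid <- seq(0, 900, by = 30)
    cur <- simulate_curve(c0, p, time_grid = grid)
    # analytic solution, clamped at extinction for n < 1
    base <- pmax(c0^(1 - n) - (1 - n) * k * grid, 0)
    conc <- base^(1 / (1 - n))
    oracle <- p$baseline + p$epsilon_l * (c0 - conc)
    expect_equal(cur$absorbance, oracle, tolerance = 1e-7)
  }
})

test_that("analyte concentration clamps at zero for sub-unit orders", {
  # n < 1 reaches extinction in finite time: t_ext = c0^(1-n) / ((1-n) k)
  c0 <- 1e-5; n <- 0.5; k <- 1e-3
  t_ext <- c0^(1 - n) / ((1 - n) * k)
  p <- quiet_params(k_prime = k, order_n = n)
  cur <- simulate_curve(c0, p, time_grid = seq(0, ceiling(t_ext) + 100, by = 1))
  plateau <- p$baseline + p$epsilon_l * c0
  expect_equal(cur$absorbance[cur$time_s > t_ext + 5],
               rep(plateau, sum(cur$time_s > t_ext + 5)), tolerance = 1e-6)
  expect_true(all(attr(cur, "analyte_conc") >= 0))
})

test_that("noiseless curves are monotone in time and in starting concentration", {
  p <- quiet_params()
  grid <- seq(0, 3600, by = 120)
  prev <- NULL
  for (c0 in c(6e-6, 1.2e-5, 3e-5, 5e-5)) {
    cur <- simulate_curve(c0, p, time_grid = grid)
    expect_true(all(diff(cur$absorbance) >= -1e-15))
    if (!is.null(prev)) expect_true(all(cur$absorbance - prev >= -1e-15))
    prev <- cur$absorbance
  }
})

test_that("curve simulation is bitwise reproducible under a seed", {
  p <- kinetic_params()
  a <- simulate_curve(2e-5, p, seed = 42)
  b <- simulate_curve(2e-5, p, seed = 42)
  expect_identical(a$absorbance, b$absorbance)
  c <- simulate_curve(2e-5, p, seed = 43)
  expect_false(identical(a$absorbance, c$absorbance))
  # seeded simulation leaves the global RNG untouched
  set.seed(7); before <- .Random.seed
  invisible(simulate_curve(2e-5, p, seed = 1))
  expect_identical(before, .Random.seed)
})

test_that("curve generator rejects invalid inputs", {
  expect_error(simulate_curve(-1e-6, kinetic_params()), ">= 0")
  expect_error(simulate_curve(1e-5, kinetic_params(), time_grid = c(5, 5, 10)),
               "increasing")
  expect_error(simulate_curve(1e-5, kinetic_params(), time_grid = c(0)), "length")
  expect_error(kinetic_params(epsilon_l = -1))
  expect_error(kinetic_params(k_prime = Inf))
})

test_that("blank simulation honours its contracts", {
  expect_equal(simulate_blanks(5, baseline = 0.01, noise_sd = 0),
               rep(0.01, 5))
  expect_identical(simulate_blanks(11, seed = 3), simulate_blanks(11, seed = 3))
  expect_error(simulate_blanks(1), ">= 2")
  # sample SD of 11 seeded blanks falls in the exact chi-square 99% interval
  b <- simulate_blanks(11, baseline = 5.2e-3, noise_sd = 9.9e-3, seed = 11)
  bounds <- 9.9e-3 * sqrt(qchisq(c(0.005, 0.995), df = 10) / 10)
  expect_gt(sd(b), bounds[1])
  expect_lt(sd(b), bounds[2])
})

test_that("noiseless calibration sets are affine in concentration", {
  p <- quiet_params()
  concs <- c(6e-6, 1e-5, 2e-5, 3e-5, 5e-5)
  # >= 99% conversion: t with 1 - exp(-k t) >= 0.99
  t99 <- -log(0.01) / p$k_prime
  tbl <- simulate_calibration_set(concs, p, fixed_time = ceiling(t99) + 60)
  o <- ols_oracle(tbl$conc, tbl$absorbance)
  expect_equal(o$slope, p$epsilon_l, tolerance = 0.01)
  # OLS on the noiseless set recovers the generated line exactly
  expect_equal(o$r_squared, 1, tolerance = 1e-12)
  expect_error(simulate_calibration_set(numeric(0), p), "non-empty")
})

test_that("calibration sets are seed-reproducible with replicates", {
  a <- simulate_calibration_set(c(1e-5, 2e-5), replicates = 3, seed = 5)
  b <- simulate_calibration_set(c(1e-5, 2e-5), replicates = 3, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 6)
})

test_that("the DoE scenario surface has the requested optima by construction", {
  truth <- make_doe_scenario(opt = c(86, 0.26), constrained_at = c(50, 0.34))
  # stationary point solves the analytic gradient system
  H <- matrix(c(2 * truth$b11, truth$b12, truth$b12, 2 * truth$b22), 2)
  st <- solve(H, -c(truth$b1, truth$b2))
  expect_equal(st, c(86, 0.26), tolerance = 1e-10)
  expect_true(all(eigen(H)$values < 0))
  # conditional argmax over alkali at 50 C is exactly 0.34
  s_star <- -(truth$b2 + truth$b12 * 50) / (2 * truth$b22)
  expect_equal(s_star, 0.34, tolerance = 1e-10)
  # grid-search oracle agrees with the analytic stationary point
  g <- grid_argmax_oracle(truth, lo = c(80, 0.2), hi = c(92, 0.32), n = 241)
  expect_equal(g[1], 86, tolerance = 0.06)
  expect_equal(g[2], 0.26, tolerance = 0.001)
})

test_that("a symmetric scenario has no interaction and a constant conditional optimum", {
  truth <- make_doe_scenario(opt = c(70, 0.25), constrained_at = c(70, 0.25))
  expect_equal(truth$b12, 0)
  for (temp in c(40, 60, 90)) {
    expect_equal(-(truth$b2 + truth$b12 * temp) / (2 * truth$b22), 0.25)
  }
})

test_that("impossible scenario geometry is rejected", {
  expect_error(make_doe_scenario(opt = c(86, 0.26),
                                 constrained_at = c(86, 0.34)),
               "inconsistent")
  # a steep conditional line needs |b12| too large for negative definiteness
  expect_error(make_doe_scenario(opt = c(86, 0.26),
                                 constrained_at = c(85.9, 0.34)),
               "negative-definite")
})

test_that("DoE responses are exact without noise and refit to the truth", {
  truth <- make_doe_scenario()
  d <- ccc_design(factor_spec("temperature", 50, 80),
                  factor_spec("alkali", 0.18, 0.34))
  y <- simulate_doe_responses(d, truth)
  mu <- truth$b0 + truth$b1 * d$natural$temperature +
    truth$b2 * d$natural$alkali + truth$b11 * d$natural$temperature^2 +
    truth$b22 * d$natural$alkali^2 +
    truth$b12 * d$natural$temperature * d$natural$alkali
  expect_equal(y, mu)
  fit <- fit_quadratic(d, responses = y)
  expect_equal(unlist(fit$coefficients),
               unlist(truth[c("b0", "b1", "b2", "b11", "b22", "b12")]),
               tolerance = 1e-7)
  expect_error(simulate_doe_responses(tibble::tibble(a = 1), truth), "factor")
})

test_that("screening responses rank temperature and alkali on top", {
  des <- full_factorial(list(
    factor_spec("oxidant", 7e-4, 9e-4), factor_spec("salt", 0.2, 0.4),
    factor_spec("alkali", 0.018, 0.18, center = 0.09),
    factor_spec("temperature", 35, 65)
  ))
  y <- simulate_screening_responses(des, make_screening_scenario(noise_sd = 1e-3),
                                    seed = 2)
  eff <- main_effects(des, y)
  mains <- eff[!grepl(":", eff$term), ]
  top2 <- mains$term[order(-abs(mains$effect))][1:2]
  expect_setequal(top2, c("temperature", "alkali"))
})

test_that("stoichiometry blocks follow exact power laws when noiseless", {
  b <- simulate_stoich_blocks()
  an <- b[b$varied == "analyte", ]
  ox <- b[b$varied == "oxidant", ]
  expect_equal(ols_oracle(log10(an$conc), log10(an$absorbance))$slope, 0.723,
               tolerance = 1e-12)
  expect_equal(ols_oracle(log10(ox$conc), log10(ox$absorbance))$slope, 0.685,
               tolerance = 1e-12)
  expect_identical(simulate_stoich_blocks(noise_sd = 0.01, seed = 9),
                   simulate_stoich_blocks(noise_sd = 0.01, seed = 9))
})
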