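four_factors <- function() {
  list(factor_spec("a", 0, 1), factor_spec("b", 10, 20),
       factor_spec("c", -1, 1), factor_spec("d", 100, 200))
}

test_that("full factorials are balanced, ordered and orthogonal", {
  d4 <- full_factorial(four_factors())
  expect_equal(nrow(d4$coded), 16)
  expect_equal(nrow(dplyr::distinct(d4$coded)), 16)
  for (nm in names(d4$coded)) {
    expect_equal(sum(d4$coded[[nm]] == 1), 8)
    expect_equal(sum(d4$coded[[nm]] == -1), 8)
  }
  d2 <- full_factorial(list(factor_spec("x", 0, 1), factor_spec("y", 0, 1)))
  expect_equal(d2$coded$x, c(-1, 1, -1, 1))
  expect_equal(d2$coded$y, c(-1, -1, 1, 1))
  # orthogonality of all main and two-factor contrast columns
  nms <- names(d4$coded)
  cols <- c(lapply(nms, function(n) d4$coded[[n]]),
            utils::combn(nms, 2, function(p) d4$coded[[p[1]]] * d4$coded[[p[2]]],
                         simplify = FALSE))
  for (i in seq_along(cols)) for (j in seq_along(cols)) {
    if (i < j) expect_equal(sum(cols[[i]] * cols[[j]]), 0)
  }
  expect_error(full_factorial(list(factor_spec("x", 0, 1))), "2 and 8")
})

test_that("natural units are the affine image of the coded matrix", {
  d <- full_factorial(list(factor_spec("x", 2, 6), factor_spec("y", -4, 0)))
  expect_equal(d$natural$x, 4 + 2 * d$coded$x)
  expect_equal(d$natural$y, -2 + 2 * d$coded$y)
})

test_that("main effects isolate the generating factor and match the contrast oracle", {
  d <- full_factorial(four_factors())
  y <- 2 * d$coded$c
  eff <- main_effects(d, y)
  expect_equal(eff$effect[eff$term == "c"], 4)
  expect_equal(eff$effect[eff$term != "c"], rep(0, nrow(eff) - 1))
  expect_equal(eff$coefficient, eff$effect / 2)
  set.seed(31)
  y <- rnorm(16)
  eff <- main_effects(d, y)
  for (i in seq_len(nrow(eff))) {
    parts <- strsplit(eff$term[i], ":")[[1]]
    contrast <- if (length(parts) == 1) d$coded[[parts]] else
      d$coded[[parts[1]]] * d$coded[[parts[2]]]
    expect_equal(eff$effect[i], sum(contrast * y) / 8, tolerance = 1e-12)
  }
  expect_error(main_effects(d), "no responses")
})

test_that("central composite designs have the right geometry", {
  f1 <- factor_spec("temperature", 50, 80)
  f2 <- factor_spec("alkali", 0.18, 0.34)
  d <- ccc_design(f1, f2, alpha = sqrt(2), n_center = 3)
  expect_equal(nrow(d$coded), 4 + 4 + 3)
  # axial high temperature: 65 + 15 sqrt(2) ~ 86.2 C
  expect_equal(max(d$natural$temperature), 65 + 15 * sqrt(2), tolerance = 1e-12)
  # rotatability: non-centre points on at most 2 distinct radii {sqrt(2), alpha}
  r <- sqrt(d$coded$temperature^2 + d$coded$alkali^2)
  expect_equal(sort(unique(round(r[r > 0], 10))), round(sqrt(2), 10))
  # alpha = 1 gives the face-centred variant
  fc <- ccc_design(f1, f2, alpha = 1, n_center = 1)
  expect_true(all(abs(fc$coded$temperature) <= 1 & abs(fc$coded$alkali) <= 1))
  expect_error(ccc_design(f1, f2, alpha = 0.5), ">= 1")
})

test_that("quadratic fits interpolate noiseless surfaces and match normal equations", {
  cf_true <- list(b0 = 1, b1 = 0.5, b2 = -2, b11 = -0.1, b22 = -3, b12 = 0.2)
  d <- ccc_design(factor_spec("x1", -1, 1), factor_spec("x2", -1, 1))
  y <- eval_q <- with(cf_true, b0 + b1 * d$natural$x1 + b2 * d$natural$x2 +
                        b11 * d$natural$x1^2 + b22 * d$natural$x2^2 +
                        b12 * d$natural$x1 * d$natural$x2)
  fit <- fit_quadratic(d, responses = y)
  expect_equal(unlist(fit$coefficients), unlist(cf_true), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  # noisy case against the closed-form least-squares solution
  set.seed(12)
  yn <- y + rnorm(length(y), 0, 0.1)
  fitn <- fit_quadratic(d, responses = yn)
  X <- cbind(1, d$natural$x1, d$natural$x2, d$natural$x1^2, d$natural$x2^2,
             d$natural$x1 * d$natural$x2)
  beta <- solve(crossprod(X), crossprod(X, yn))
  expect_equal(unname(unlist(fitn$coefficients)), as.numeric(beta),
               tolerance = 1e-9)
})

test_that("stationary points are located and classified correctly", {
  # y = -(x1 - 1)^2 - (x2 - 2)^2
  d <- ccc_design(factor_spec("x1", 0, 2), factor_spec("x2", 1, 3))
  y <- -(d$natural$x1 - 1)^2 - (d$natural$x2 - 2)^2
  fit <- fit_quadratic(d, responses = y)
  st <- stationary_point(fit)
  expect_equal(unname(st$point), c(1, 2), tolerance = 1e-8)
  expect_equal(st$kind, "maximum")
  # saddle
  ys <- (d$natural$x1 - 1)^2 - (d$natural$x2 - 2)^2
  expect_equal(stationary_point(fit_quadratic(d, responses = ys))$kind, "saddle")
  # seeded negative-definite quadratics vs dense-grid argmax
  set.seed(5)
  for (i in 1:10) {
    cf <- list(b0 = rnorm(1), b11 = -runif(1, 0.5, 2), b22 = -runif(1, 0.5, 2))
    cf$b12 <- runif(1, -0.9, 0.9) * 2 * sqrt(cf$b11 * cf$b22)
    opt <- runif(2, -0.5, 0.5)
    cf$b1 <- -(2 * cf$b11 * opt[1] + cf$b12 * opt[2])
    cf$b2 <- -(2 * cf$b22 * opt[2] + cf$b12 * opt[1])
    g <- grid_argmax_oracle(cf, lo = c(-1, -1), hi = c(1, 1), n = 201)
    st <- stationary_point(cf)
    expect_lt(max(abs(unname(st$point) - g)), 2 / 200 + 1e-12)
    expect_equal(st$kind, "maximum")
  }
})

test_that("ridge systems are reported rather than solved", {
  cf <- list(b1 = 1, b2 = 0, b11 = -1, b22 = 0, b12 = 0)
  st <- stationary_point(cf)
  expect_equal(st$kind, "ridge")
  expect_true(anyNA(st$point))
})

test_that("box-constrained optima match a dense-grid oracle", {
  set.seed(23)
  d <- ccc_design(factor_spec("x1", -1, 1), factor_spec("x2", -1, 1))
  for (i in 1:50) {
    cf <- list(b0 = rnorm(1), b1 = rnorm(1, 0, 2), b2 = rnorm(1, 0, 2),
               b11 = rnorm(1, 0, 1.5), b22 = rnorm(1, 0, 1.5),
               b12 = rnorm(1, 0, 1))
    y <- cf$b0 + cf$b1 * d$natural$x1 + cf$b2 * d$natural$x2 +
      cf$b11 * d$natural$x1^2 + cf$b22 * d$natural$x2^2 +
      cf$b12 * d$natural$x1 * d$natural$x2
    fit <- fit_quadratic(d, responses = y)
    box <- list(x1 = c(-0.8, 0.9), x2 = c(-0.7, 1))
    got <- constrained_optimum(fit, box)
    g <- grid_argmax_oracle(cf, lo = c(-0.8, -0.7), hi = c(0.9, 1), n = 201)
    cell <- c(1.7 / 200, 1.7 / 200) * 1.5
    expect_true(all(abs(unname(got$point) - g) <= cell))
  }
})

test_that("pinning a factor reduces to the 1-D conditional optimum", {
  truth <- make_doe_scenario()
  d <- ccc_design(factor_spec("temperature", 50, 80),
                  factor_spec("alkali", 0.18, 0.34))
  fit <- fit_quadratic(d, responses = simulate_doe_responses(d, truth))
  # unconstrained optimum inside a wide box equals the stationary point
  wide <- list(temperature = c(0, 150), alkali = c(0, 1))
  free <- constrained_optimum(fit, wide)
  expect_equal(unname(free$point), unname(fit$stationary$point),
               tolerance = 1e-6)
  # pinned temperature pushes the alkali optimum to the box edge
  pinned <- constrained_optimum(fit, list(temperature = c(35, 90),
                                          alkali = c(0.018, 0.34)),
                                fixed = list(temperature = 50))
  expect_equal(pinned$point[["alkali"]], 0.34, tolerance = 1e-9)
  expect_true(pinned$boundary)
  expect_error(constrained_optimum(fit, list(temperature = c(2, 1),
                                             alkali = c(0, 1))),
               "empty")
})
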