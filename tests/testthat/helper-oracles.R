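# Shared fixtures and independent oracles used across test files.

# Published fixed-time calibration summary (one row per candidate time):
# R^2, correlation t, intercept and slope (slope in the table's x1e3 units;
# only relative slope magnitudes matter for selection).
published_candidates <- tibble::tibble(
  time_min = c(0, 10, 20, 30, 40, 50, 60),
  r_squared = c(0.9899, 0.8744, 0.9161, 0.9544, 0.9345, 0.9426, 0.9619),
  typical_error = c(0.00462, 0.0587, 0.0595, 0.0538, 0.0812, 0.0617, 0.0490),
  t_printed = c(17.15, 4.570, 5.726, 7.926, 5.114, 7.019, 8.709),
  intercept = c(0.00250, 0.0461, 0.0562, 0.0472, 0.0838, 0.1124, 0.1550),
  slope = c(2.244, 7.600, 9.655, 12.09, 11.77, 12.27, 12.10),
  n_points = 5
)

# Closed-form simple-OLS oracle (normal equations), independent of fit_line.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (sst == 0) 0 else 1 - sse / sst,
       sigma = sqrt(sse / (n - 2)))
}

# Dense-grid argmax oracle for a quadratic surface over a box.
grid_argmax_oracle <- function(cf, lo, hi, n = 201) {
  xs <- seq(lo[1], hi[1], length.out = n)
  ys <- seq(lo[2], hi[2], length.out = n)
  g <- expand.grid(x1 = xs, x2 = ys)
  v <- cf$b0 + cf$b1 * g$x1 + cf$b2 * g$x2 + cf$b11 * g$x1^2 +
    cf$b22 * g$x2^2 + cf$b12 * g$x1 * g$x2
  i <- which.max(v)
  c(g$x1[i], g$x2[i])
}

# Independent brute-force rational snap (log metric, ties by p + q).
ratio_oracle <- function(r, max_den = 4) {
  best <- NULL; best_err <- Inf; best_sum <- Inf
  for (p in 1:max_den) for (q in 1:max_den) {
    g <- p; b <- q
    while (b != 0) { t <- b; b <- g %% b; g <- t }
    if (g != 1) next
    err <- abs(log(r) - log(p / q))
    if (err < best_err - 1e-15 ||
        (abs(err - best_err) <= 1e-15 && p + q < best_sum)) {
      best <- c(p, q); best_err <- err; best_sum <- p + q
    }
  }
  best
}

# Default generator parameters without detector noise.
quiet_params <- function(...) {
  args <- list(...)
  args$noise_sd <- 0
  do.call(kinetic_params, args)
}
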