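# Shared fixtures built in code at test time.

# tiny constant-trend availability panel
flat_series <- function(years = 2000:2002, grams = c(100, 100, 100, 100, 100)) {
  validate_nutrient_series(tibble::tibble(
    year = years,
    carbohydrates = grams[1], protein = grams[2], sat_fat = grams[3],
    mono_fat = grams[4], poly_fat = grams[5]
  ))
}

# smooth deterministic panel with enough per-year structure that lags are
# distinguishable without random noise
wiggly_series <- function(years) {
  t0 <- years - years[1]
  validate_nutrient_series(tibble::tibble(
    year = years,
    carbohydrates = 300 + 0.5 * t0 + 12 * sin(t0 / 2.1) + 3 * cos(t0 / 0.7),
    protein = 90 + 0.2 * t0 + 6 * sin(t0 / 3.3 + 1) + 2 * sin(t0 / 0.9),
    sat_fat = 40 + 0.1 * t0 + 5 * cos(t0 / 2.7) + 1.5 * sin(t0 / 1.1 + 2),
    mono_fat = 55 + 0.25 * t0 + 4 * sin(t0 / 4.1 + 3) + 2 * cos(t0 / 1.3),
    poly_fat = 15 + 0.1 * t0 + 2 * cos(t0 / 1.9 + 1) + sin(t0 / 0.8)
  ))
}

# response generated exactly by the linear calculator equation
exact_response <- function(series, lags, alpha, betas, years) {
  mu <- rep(alpha, length(years))
  for (i in seq_along(nutrient_names())) {
    x <- series[[nutrient_names()[i]]][match(years - lags[i], series$year)]
    mu <- mu + betas[i] * x
  }
  validate_r_series(tibble::tibble(year = years, r = pmin(1, pmax(-1, mu))))
}

# independent normal-equations oracle for the least-squares calculator fit
normal_equations_oracle <- function(x, y) {
  X <- cbind(1, as.matrix(x))
  coefs <- solve(crossprod(X), crossprod(X, y))
  fitted <- X %*% coefs
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(alpha = coefs[1], betas = as.numeric(coefs[-1]),
       r_fit = sqrt(max(0, min(1, r2))))
}

# brute-force scan oracle: refit with fit_calculator at every lag combination
scan_oracle <- function(series, r, period, config) {
  L <- config$max_lag
  grid <- expand.grid(k5 = 0:L, k4 = 0:L, k3 = 0:L, k2 = 0:L, k1 = 0:L)
  grid <- grid[, 5:1]
  r_fit <- vapply(seq_len(nrow(grid)), function(i) {
    lags <- as.integer(grid[i, ])
    tryCatch({
      d <- shift_alignment(series, r, lags, period, config)
      fit_calculator(d)$r_fit
    }, error = function(e) NA_real_)
  }, numeric(1))
  cbind(as.matrix(grid), r_fit = r_fit)
}
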