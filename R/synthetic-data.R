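## Synthetic availability panels and correlation series with known ground
## truth.  All generators draw through R's default Mersenne-Twister /
## Inversion generator under a caller-supplied seed (withr::with_seed), so a
## fixed seed reproduces bit-identical data on any platform.

#' Default ground truth for synthetic correlation series
#'
#' Bundles the generative parameters of [synth_roriginal()]: the true
#' precedence period (lag, years) per nutrient, the intercept, the linear
#' coefficients (correlation units per gram), the noise level on the
#' correlation scale and a seed.  The defaults give a response oscillating
#' roughly between -0.2 and 0.6 — the magnitude of the historical
#' income-mortality correlation series — with effect sizes a 77-year series
#' can resolve.
#'
#' @param true_lags Integer vector of 5 non-negative lags (canonical order).
#' @param alpha Intercept of the generative equation.
#' @param betas Linear coefficients, correlation units per gram (length 5).
#' @param noise_sd Gaussian noise SD on the correlation scale.
#' @param seed Integer seed.
#' @return A list of class `dietlag_truth`.
#' @export
synthetic_truth <- function(true_lags = c(3L, 0L, 1L, 2L, 4L),
                            alpha = -1.64,
                            betas = c(0.008, -0.010, 0.012, -0.008, 0.020),
                            noise_sd = 0.05,
                            seed = 1L) {
  true_lags <- as.integer(true_lags)
  stopifnot(length(true_lags) == 5L, all(true_lags >= 0L),
            length(betas) == 5L, noise_sd >= 0)
  structure(list(true_lags = stats::setNames(true_lags, nutrient_names()),
                 alpha = alpha,
                 betas = stats::setNames(as.numeric(betas), nutrient_names()),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dietlag_truth")
}

default_trend_spec <- function() {
  # Slow multi-decade drift plus one sinusoid, on the gram scale of US
  # per-capita daily availabilities: large carbohydrate base, tens of grams
  # for the fat classes.
  tibble(
    nutrient = nutrient_names(),
    baseline = c(300, 90, 40, 55, 15),
    slope = c(0.5, 0.15, 0.10, 0.25, 0.10),
    amplitude = c(15, 5, 4, 5, 2),
    period = c(40, 28, 22, 34, 18),
    phase = c(0, 1, 2, 3, 4)
  )
}

#' Generate a synthetic availability panel
#'
#' Each nutrient follows a linear trend plus a single sinusoid plus i.i.d.
#' Gaussian noise, clipped at zero — a structural stand-in for the slow
#' multi-decade drifts of historical food-supply series.
#'
#' @param years Integer vector of contiguous calendar years.
#' @param trend_spec Tibble with columns `nutrient`, `baseline` (g),
#'   `slope` (g/year), `amplitude` (g), `period` (years), `phase` (radians);
#'   defaults emulate US-scale availabilities.
#' @param noise_sd SD of the additive gram noise (default 3 g).
#' @param seed Integer seed.
#' @return A validated availability tibble (see [validate_nutrient_series()]).
#' @export
#' @examples
#' head(synth_availability(1909:2005, seed = 42))
synth_availability <- function(years, trend_spec = default_trend_spec(),
                               noise_sd = 3, seed = 1L) {
  years <- as.integer(years)
  validate_years(years, "requested span")
  stopifnot(noise_sd >= 0)
  t0 <- years - years[1]
  cols <- withr::with_seed(seed, {
    purrr::map(seq_len(nrow(trend_spec)), function(i) {
      s <- trend_spec[i, ]
      mu <- s$baseline + s$slope * t0 + s$amplitude * sin(2 * pi * t0 / s$period + s$phase)
      pmax(0, mu + stats::rnorm(length(years), 0, noise_sd))
    })
  })
  names(cols) <- trend_spec$nutrient
  validate_nutrient_series(tibble(year = years, !!!cols))
}

#' Generate a synthetic correlation series from an availability panel
#'
#' Builds the response as intercept plus a linear combination of lag-shifted
#' availabilities plus Gaussian noise, clamped to \[-1, 1\]:
#' `r(t) = alpha + sum_i beta_i * x_i(t - lag_i) + eps(t)`.
#' This is the linear generative counterpart of the calculator equation, so
#' with zero noise the lag optimizer must recover the truth exactly.
#'
#' @param series Availability panel covering every lagged year needed.
#' @param truth A [synthetic_truth()].
#' @param years Response years (default: all years of `series` for which
#'   every lagged predictor is available).
#' @return A validated correlation tibble (`year`, `r`).
#' @export
synth_roriginal <- function(series, truth = synthetic_truth(), years = NULL) {
  series <- validate_nutrient_series(series)
  max_true <- max(truth$true_lags)
  if (is.null(years)) {
    years <- seq.int(series$year[1] + max_true, series$year[nrow(series)])
  }
  years <- as.integer(years)
  validate_years(years, "response span")
  first_needed <- years[1] - max_true
  if (first_needed < series$year[1]) {
    abort(paste0("availability series starts at ", series$year[1],
                 " but lagged coverage of response year ", years[1],
                 " needs year ", first_needed))
  }
  if (years[length(years)] > series$year[nrow(series)]) {
    abort("response span extends past the availability series")
  }
  mu <- rep(truth$alpha, length(years))
  for (i in seq_along(nutrient_names())) {
    x <- series[[nutrient_names()[i]]][match(years - truth$true_lags[i], series$year)]
    mu <- mu + truth$betas[i] * x
  }
  eps <- if (truth$noise_sd > 0) {
    withr::with_seed(truth$seed, stats::rnorm(length(years), 0, truth$noise_sd))
  } else {
    numeric(length(years))
  }
  validate_r_series(tibble(year = years, r = pmin(1, pmax(-1, mu + eps))))
}

#' Generate a synthetic state-level income/mortality panel
#'
#' Emulates the construction behind the ecological correlation series: a
#' panel of per-capita personal income (PCPI) by state and year, and one
#' age-adjusted death rate (AADR) per state.  The AADR is built as
#' `coupling` times the standardized PCPI of the final year plus
#' `sqrt(1 - coupling^2)` independent noise, so `coupling` is the expected
#' cross-state correlation in the final year.
#'
#' @param n_states Number of states (>= 3).
#' @param years Contiguous panel years.
#' @param coupling Target correlation between AADR and final-year PCPI,
#'   in \[-1, 1\].
#' @param seed Integer seed.
#' @return List of class `dietlag_panel` with tibbles `pcpi`
#'   (`state`, `year`, `pcpi`) and `aadr` (`state`, `aadr`).
#' @export
synth_state_panel <- function(n_states = 48L, years = 1929:2005,
                              coupling = 0.5, seed = 1L) {
  stopifnot(n_states >= 3L, abs(coupling) <= 1)
  years <- as.integer(years)
  validate_years(years, "panel span")
  states <- sprintf("S%02d", seq_len(n_states))
  withr::with_seed(seed, {
    base <- stats::rnorm(n_states, 10000, 2500)          # persistent state wealth
    growth <- stats::rnorm(n_states, 150, 40)            # per-year growth
    pcpi <- tidyr::expand_grid(state = states, year = years)
    pcpi$pcpi <- base[match(pcpi$state, states)] +
      growth[match(pcpi$state, states)] * (pcpi$year - years[1]) +
      stats::rnorm(nrow(pcpi), 0, 500)
    final <- pcpi$pcpi[pcpi$year == years[length(years)]]
    z <- as.numeric(scale(final))
    noise <- if (abs(coupling) < 1) stats::rnorm(n_states) else numeric(n_states)
    a <- coupling * z + sqrt(max(0, 1 - coupling^2)) * noise
    aadr <- tibble(state = states, aadr = 25 + 8 * a)    # deaths per 100,000
    structure(list(pcpi = pcpi, aadr = aadr), class = "dietlag_panel")
  })
}

#' Per-year cross-state correlation of income with mortality
#'
#' For each panel year, the Pearson correlation across states between that
#' year's PCPI and the single per-state AADR.  This reproduces, on synthetic
#' panels, the construction of the yearly ecological correlation series.
#'
#' @param panel A [synth_state_panel()], or a list with tibbles `pcpi`
#'   (`state`, `year`, `pcpi`) and `aadr` (`state`, `aadr`).
#' @return Tibble (`year`, `r`); years with cross-state constant PCPI give
#'   `NA` with a warning.
#' @export
compute_roriginal <- function(panel) {
  pcpi <- as_tibble(panel$pcpi)
  aadr <- as_tibble(panel$aadr)
  if (nrow(aadr) < 3L) abort("need at least 3 states")
  a <- stats::setNames(aadr$aadr, aadr$state)
  out <- pcpi |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(r = {
      x <- .data$pcpi
      y <- a[.data$state]
      if (stats::sd(x) == 0) NA_real_ else stats::cor(x, y)
    }, .groups = "drop") |>
    dplyr::arrange(.data$year)
  if (anyNA(out$r)) {
    warn(paste0("PCPI constant across states in year(s) ",
                paste(out$year[is.na(out$r)], collapse = ", "),
                "; correlation undefined"))
  }
  out
}
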