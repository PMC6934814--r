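## Exhaustive "global optimization" over per-nutrient precedence periods:
## the calculator equation is refitted at every lag combination on the
## (max_lag + 1)^5 grid and the combination with the highest multiple
## correlation R is selected.

#' Number of lag combinations on the search grid
#'
#' `(max_lag + 1)^n_nutrients` — with the default 20-year maximum lag and
#' five nutrients this is 4,084,101 combinations.
#'
#' @param max_lag Largest lag searched (years).
#' @param n_nutrients Number of nutrients (default 5).
#' @return Combination count (double, exact for any practical grid).
#' @export
#' @examples
#' count_lag_combinations(20, 5)
count_lag_combinations <- function(max_lag, n_nutrients = 5L) {
  stopifnot(max_lag >= 0, n_nutrients >= 1)
  (as.double(max_lag) + 1)^n_nutrients
}

as_lag_vector <- function(lags, max_lag = NULL) {
  if (!is.null(names(lags)) && all(nutrient_names() %in% names(lags))) {
    lags <- lags[nutrient_names()]
  }
  lags <- as.integer(lags)
  if (length(lags) != 5L || anyNA(lags) || any(lags < 0L)) {
    abort("a lag vector is 5 non-negative integers (canonical nutrient order)")
  }
  if (!is.null(max_lag) && any(lags > max_lag)) {
    abort(paste0("lag exceeds max_lag = ", max_lag))
  }
  stats::setNames(lags, nutrient_names())
}

# lexicographic combination index (0-based, first nutrient most significant)
lag_index <- function(lags, max_lag) {
  lags <- as_lag_vector(lags, max_lag)
  Reduce(function(acc, k) acc * (max_lag + 1) + k, as.double(lags), accumulate = FALSE)
}

# inverse of lag_index; `idx` may be a vector
lag_unindex <- function(idx, max_lag) {
  L1 <- max_lag + 1
  out <- matrix(0L, nrow = length(idx), ncol = 5L,
                dimnames = list(NULL, nutrient_names()))
  rem <- as.double(idx)
  for (i in 5:1) {
    out[, i] <- as.integer(rem %% L1)
    rem <- rem %/% L1
  }
  out
}

#' Align lagged availabilities with the correlation series
#'
#' Builds the paired design for one lag combination and one life period:
#' each retained response year `t` in `[start_year, end_year]` is paired
#' with `x_i(t - lag_i)` for every nutrient.  Years whose lagged predictors
#' precede the start of the availability series are dropped.
#'
#' @param series Availability panel (validated tibble).
#' @param r Correlation series (validated tibble).
#' @param lags Lag vector: 5 non-negative integers, canonical order.
#' @param period Life period name or one-row data frame
#'   (`start_year`, `end_year`).
#' @param config Analysis configuration (for `min_rows` and period lookup).
#' @return Tibble with columns `year`, `r` and the five lagged nutrient
#'   columns, one row per usable year.
#' @export
shift_alignment <- function(series, r, lags, period, config = analysis_config()) {
  series <- validate_nutrient_series(series)
  r <- validate_r_series(r)
  lags <- as_lag_vector(lags)
  p <- resolve_period(period, config)
  years <- seq.int(p$start_year, p$end_year)
  years <- years[years %in% r$year]
  # a year is usable only if every lagged predictor year is in the series
  ok <- (years - max(lags)) >= series$year[1] & years <= series$year[nrow(series)]
  years <- years[ok]
  if (length(years) < config$min_rows) {
    abort(paste0("only ", length(years), " usable year(s) in period ",
                 p$period, " at lags (", paste(lags, collapse = ", "),
                 "); need at least ", config$min_rows))
  }
  out <- tibble(year = years, r = r$r[match(years, r$year)])
  for (i in seq_along(nutrient_names())) {
    nm <- nutrient_names()[i]
    out[[nm]] <- series[[nm]][match(years - lags[i], series$year)]
  }
  out
}

#' Fit the calculator equation on an aligned design
#'
#' Ordinary least squares of the correlation response on an intercept plus
#' the five lagged availability terms; the additive model's smooth terms are
#' linearized, so each term contributes `beta_i * grams_i`.  The fit
#' statistic is the non-negative multiple correlation `sqrt(R^2)`
#' (unadjusted), defined as 0 for a constant response.
#'
#' @param design Tibble from [shift_alignment()] (columns `year`, `r`,
#'   nutrients), or a list with elements `x` (matrix) and `y`.
#' @param lags Lag vector recorded in the fit (metadata).
#' @param period Period recorded in the fit (metadata).
#' @return Object of class `calculator_fit`: `alpha`, `betas` (named),
#'   `r_fit`, `lags`, `period`, `n_obs`, `years`.
#' @export
fit_calculator <- function(design, lags = NULL, period = NULL) {
  if (is.data.frame(design)) {
    x <- as.matrix(design[, nutrient_names()])
    y <- design$r
    years <- design$year
  } else {
    x <- as.matrix(design$x)
    colnames(x) <- nutrient_names()
    y <- design$y
    years <- design$years %||% seq_along(y)
  }
  n <- length(y)
  if (n < 7L) abort("need at least 7 observations to fit the calculator")
  if (stats::sd(y) == 0) {
    fit <- list(alpha = y[1], betas = stats::setNames(numeric(5), nutrient_names()),
                r_fit = 0)
  } else {
    lmfit <- stats::lm.fit(cbind(`(Intercept)` = 1, x), y)
    if (lmfit$rank < 6L) {
      bad <- names(which(is.na(lmfit$coefficients)))
      abort(paste0("rank-deficient design; collinear column(s): ",
                   paste(bad, collapse = ", ")))
    }
    coefs <- lmfit$coefficients
    r2 <- 1 - sum(lmfit$residuals^2) / sum((y - mean(y))^2)
    fit <- list(alpha = unname(coefs[1]),
                betas = stats::setNames(unname(coefs[-1]), nutrient_names()),
                r_fit = sqrt(min(1, max(0, r2))))
  }
  structure(c(fit, list(
    lags = if (is.null(lags)) NULL else as_lag_vector(lags),
    period = period, n_obs = n, years = years)), class = "calculator_fit")
}

#' @export
print.calculator_fit <- function(x, ...) {
  cat("Calculator equation", if (!is.null(x$period)) paste0(" [", x$period, "]"), "\n", sep = "")
  cat(sprintf("  r_fit = %.4f on %d years\n", x$r_fit, x$n_obs))
  cat(sprintf("  alpha = %.6g\n", x$alpha))
  for (nm in nutrient_names()) {
    cat(sprintf("  %-14s beta = %+.3e", nm, x$betas[nm]))
    if (!is.null(x$lags)) cat(sprintf("  lag = %d", x$lags[nm]))
    cat("\n")
  }
  invisible(x)
}

# Build, per distinct usable-row window, the centred cross-products of all
# 5*(max_lag+1) lagged predictor columns needed by the C++ scanner.
build_scan_inputs <- function(series, r, period, config) {
  L <- config$max_lag
  p <- resolve_period(period, config)
  s_start <- series$year[1]
  s_end <- series$year[nrow(series)]
  if (p$end_year > s_end || p$end_year > r$year[nrow(r)] || p$start_year < r$year[1]) {
    abort(paste0("series/response do not cover period ", p$period))
  }
  win_start <- pmax(p$start_year, s_start + 0:L)
  if (config$coverage == "common_window") win_start[] <- max(win_start)
  starts <- sort(unique(win_start))
  group_of_k <- match(win_start, starts) - 1L
  gram <- vector("list", length(starts))
  gxy <- vector("list", length(starts))
  syy <- numeric(length(starts))
  nrows <- integer(length(starts))
  for (g in seq_along(starts)) {
    years <- seq.int(starts[g], p$end_year)
    nrows[g] <- length(years)
    ncol_total <- 5L * (L + 1L)
    X <- matrix(0, nrow = length(years), ncol = ncol_total)
    kmax_valid <- starts[g] - s_start  # columns with lag <= this are in-range
    for (i in 0:4) {
      xi <- series[[nutrient_names()[i + 1]]]
      for (k in 0:min(L, kmax_valid)) {
        X[, i * (L + 1L) + k + 1L] <- xi[match(years - k, series$year)]
      }
    }
    y <- r$r[match(years, r$year)]
    if (nrows[g] >= 2L) {
      Xc <- sweep(X, 2, colMeans(X))
      yc <- y - mean(y)
      gram[[g]] <- crossprod(Xc)
      gxy[[g]] <- as.numeric(crossprod(Xc, yc))
      syy[g] <- sum(yc^2)
    } else {
      gram[[g]] <- matrix(0, ncol_total, ncol_total)
      gxy[[g]] <- numeric(ncol_total)
      syy[g] <- 0
    }
  }
  list(gram = gram, gxy = gxy, syy = syy, nrows = nrows,
       group_of_k = group_of_k, period = p)
}

#' Exhaustive lag-grid optimization of the calculator equation
#'
#' Fits the calculator at every lag combination on the
#' `(max_lag + 1)^5` grid for one life period and selects the combination
#' with the highest multiple correlation.  Combinations with fewer usable
#' rows than `config$min_rows`, or with a rank-deficient design, are counted
#' as unusable rather than silently skipped.  Ties on the fit statistic are
#' broken toward the lexicographically smallest lag vector, so the result is
#' deterministic and independent of evaluation order.
#'
#' @inheritParams shift_alignment
#' @param config Analysis configuration; `config$max_lag` sets the grid.
#' @param keep_grid Keep the full per-combination vector of fit statistics
#'   (lexicographic order, `NA` for unusable combinations).  Default: kept
#'   for grids up to 10^6 combinations.
#' @param combinations Optional subset to evaluate instead of the full grid:
#'   an integer matrix of lag vectors (5 columns) or a vector of 0-based
#'   lexicographic indices.  Subset runs return per-combination statistics
#'   only (no optimum bookkeeping is reused downstream).
#' @return For full runs, an object of class `lag_scan`: `optimal_lags`,
#'   `r_optimal`, `optimal_fit` (a [fit_calculator()] object), per-nutrient
#'   per-lag aggregate `profiles`, usable/unusable counts, and `r_grid`
#'   when kept.  For subset runs, a tibble with the five lag columns and
#'   `r_fit`.
#' @export
global_optimize <- function(series, r, period, config = analysis_config(),
                            keep_grid = NULL, combinations = NULL) {
  series <- validate_nutrient_series(series)
  r <- validate_r_series(r)
  L <- config$max_lag
  inp <- build_scan_inputs(series, r, period, config)

  subset <- numeric(0)
  if (!is.null(combinations)) {
    subset <- if (is.matrix(combinations)) {
      apply(combinations, 1L, lag_index, max_lag = L)
    } else {
      as.double(combinations)
    }
    if (any(subset < 0 | subset >= count_lag_combinations(L))) {
      abort("combination index out of range")
    }
  }
  n_eval <- if (length(subset)) length(subset) else count_lag_combinations(L)
  if (is.null(keep_grid)) keep_grid <- n_eval <= 1e6 || length(subset) > 0

  res <- scan_lag_grid_cpp(inp$gram, inp$gxy, inp$syy, inp$nrows,
                           inp$group_of_k, L, config$min_rows,
                           keep_grid, subset)

  if (length(subset)) {
    lags <- lag_unindex(subset, L)
    return(dplyr::bind_cols(as_tibble(lags), tibble(r_fit = res$r)))
  }

  if (res$best_index < 0) {
    abort(paste0("no usable lag combination in period ", inp$period$period))
  }
  optimal_lags <- drop(lag_unindex(res$best_index, L))
  design <- shift_alignment(series, r, optimal_lags, period, config)
  optimal_fit <- fit_calculator(design, lags = optimal_lags,
                                period = inp$period$period)

  prof <- tibble(
    nutrient = rep(nutrient_names(), each = L + 1L),
    lag = rep(0:L, times = 5L),
    n = as.integer(t(res$prof_n)),
    r_sum = as.numeric(t(res$prof_sum)),
    r_sumsq = as.numeric(t(res$prof_sumsq))
  )
  prof$r_mean <- ifelse(prof$n > 0, prof$r_sum / prof$n, NA_real_)
  prof$r_sd <- ifelse(
    prof$n > 1,
    sqrt(pmax(0, (prof$r_sumsq - prof$n * prof$r_mean^2) / (prof$n - 1))),
    ifelse(prof$n == 1, 0, NA_real_)
  )
  prof <- prof[, c("nutrient", "lag", "n", "r_mean", "r_sd")]

  structure(list(
    period = inp$period$period,
    period_years = c(inp$period$start_year, inp$period$end_year),
    max_lag = L,
    optimal_lags = optimal_lags,
    r_optimal = res$best_r,
    optimal_fit = optimal_fit,
    profiles = prof,
    n_usable = res$n_usable,
    n_unusable = res$n_unusable,
    r_grid = if (keep_grid) res$r else NULL,
    config = config
  ), class = "lag_scan")
}

#' @export
print.lag_scan <- function(x, ...) {
  cat(sprintf("Lag scan [%s %d-%d], max_lag = %d: %s combinations (%s usable)\n",
              x$period, x$period_years[1], x$period_years[2], x$max_lag,
              format(x$n_usable + x$n_unusable, big.mark = ","),
              format(x$n_usable, big.mark = ",")))
  cat(sprintf("  r_optimal = %.4f at lags (%s)\n", x$r_optimal,
              paste(x$optimal_lags, collapse = ", ")))
  invisible(x)
}
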