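#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import Rcpp
#' @useDynLib dietlag, .registration = TRUE
NULL

# Canonical nutrient order used everywhere in the package.  All tabular I/O,
# lag vectors, diets and model coefficients follow this order.
.NUTRIENTS <- c("carbohydrates", "protein", "sat_fat", "mono_fat", "poly_fat")
.KCAL <- c(carbohydrates = 4, protein = 4, sat_fat = 9, mono_fat = 9, poly_fat = 9)

#' Canonical macronutrient names and energy densities
#'
#' The five macronutrients tracked by the calculator, in the canonical order
#' used by every function in the package: carbohydrates, protein, saturated
#' fat, monounsaturated fat, polyunsaturated fat.  Energy densities are the
#' standard Atwater-style factors: 4 kcal/g for carbohydrates and protein,
#' 9 kcal/g for each fat class.
#'
#' @return `nutrient_names()` returns a character vector of length 5;
#'   `kcal_per_gram()` a named numeric vector of energy densities (kcal/g).
#' @export
#' @examples
#' nutrient_names()
#' kcal_per_gram()
nutrient_names <- function() .NUTRIENTS

#' @rdname nutrient_names
#' @export
kcal_per_gram <- function() .KCAL

#' Life periods over which calculator equations are fitted
#'
#' The default calendar windows partitioning the 1929--2005 span into four
#' periods of life.  Boundary years are shared between adjacent periods
#' (1949 belongs to both youth and early middle age), matching the printed
#' ranges of the source analysis.
#'
#' @return A tibble with columns `period`, `start_year`, `end_year`.
#' @export
#' @examples
#' life_periods()
life_periods <- function() {
  tibble(
    period = c("youth", "early_middle_age", "late_middle_age", "late_age"),
    start_year = c(1929L, 1949L, 1970L, 1990L),
    end_year = c(1949L, 1970L, 1990L, 2005L)
  )
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline: the maximum precedence
#' period searched, the life periods, the diet-grid gram steps, the selection
#' tolerance on the predicted correlation, the kcal scale used in reports,
#' and the lagged-coverage policy.
#'
#' @param max_lag Largest precedence period (years back) searched per
#'   nutrient; the lag grid is `0:max_lag` for each nutrient. Default 20.
#' @param periods Tibble of life periods as from [life_periods()].
#' @param grid_steps Gram step per nutrient for the diet grid, canonical
#'   order. Default 5 g for all but polyunsaturated fat, which uses 1 g
#'   because its historical range is narrower than a single 5 g step.
#' @param grid_span Multiplicative bounds of the default diet grid relative
#'   to the observed per-period min/max grams, `c(low, high)`.
#' @param r_tolerance Tolerance band above the grid minimum of the predicted
#'   correlation within which diets compete on energy difference.
#' @param report_kcal Energy scale of reported diets (kcal/day). Default 2000.
#' @param coverage `"per_combination"` drops, separately for each lag
#'   combination, response years whose lagged predictors precede the series;
#'   `"common_window"` restricts every combination to the window valid at
#'   `max_lag` so all fits share identical rows.
#' @param min_rows Minimum usable rows for a fit to be attempted (intercept +
#'   five slopes + 1). Default 7.
#' @param max_grid_size Guard on the number of candidate diets enumerated.
#' @param seed Integer seed recorded in run manifests and used by any
#'   stochastic stage.
#' @return A list of class `dietlag_config`.
#' @export
analysis_config <- function(max_lag = 20L,
                            periods = life_periods(),
                            grid_steps = c(5, 5, 5, 5, 1),
                            grid_span = c(0.5, 1.5),
                            r_tolerance = 0.01,
                            report_kcal = 2000,
                            coverage = c("per_combination", "common_window"),
                            min_rows = 7L,
                            max_grid_size = 2e7,
                            seed = 1L) {
  coverage <- match.arg(coverage)
  max_lag <- as.integer(max_lag)
  stopifnot(max_lag >= 0L, all(grid_steps > 0), length(grid_steps) == 5L,
            r_tolerance >= 0, report_kcal > 0, min_rows >= 7L)
  structure(
    list(max_lag = max_lag, periods = periods,
         grid_steps = stats::setNames(as.numeric(grid_steps), .NUTRIENTS),
         grid_span = grid_span, r_tolerance = r_tolerance,
         report_kcal = report_kcal, coverage = coverage,
         min_rows = as.integer(min_rows), max_grid_size = max_grid_size,
         seed = as.integer(seed)),
    class = "dietlag_config"
  )
}

#' Round half away from zero
#'
#' Report tables round 16.5 up to 17; base `round()` uses banker's rounding,
#' so the reporting layer uses this helper instead.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

resolve_period <- function(period, config = analysis_config()) {
  periods <- config$periods
  if (is.character(period)) {
    row <- periods[periods$period == period, ]
    if (nrow(row) != 1L) {
      abort(paste0("unknown life period '", period, "'; expected one of: ",
                   paste(periods$period, collapse = ", ")))
    }
    return(row)
  }
  if (is.data.frame(period)) {
    stopifnot(all(c("start_year", "end_year") %in% names(period)), nrow(period) == 1L)
    if (is.null(period$period)) period$period <- "custom"
    return(as_tibble(period))
  }
  abort("`period` must be a period name or a one-row data frame")
}

## ---- diets -------------------------------------------------------------

#' Construct a diet composition
#'
#' A diet is a tibble with one row per macronutrient (canonical order) and a
#' `grams` column of non-negative daily amounts.  All diet arithmetic
#' ([energy_of()], [scale_to_energy()], [percent_energy()],
#' [energy_difference()]) operates on this shape.
#'
#' @param grams Numeric vector of length 5 (canonical nutrient order), or a
#'   named vector naming all five nutrients.
#' @return A tibble of class `dietlag_diet` with columns `nutrient`, `grams`.
#' @export
#' @examples
#' d <- diet_composition(c(269, 57, 33, 30, 14))
#' energy_of(d)
#' percent_energy(d)
diet_composition <- function(grams) {
  if (is.data.frame(grams)) grams <- stats::setNames(grams$grams, grams$nutrient)
  if (!is.null(names(grams)) && all(.NUTRIENTS %in% names(grams))) {
    grams <- grams[.NUTRIENTS]
  }
  grams <- as.numeric(grams)
  if (length(grams) != 5L) abort("a diet needs exactly 5 gram values")
  if (anyNA(grams) || any(grams < 0)) abort("diet grams must be non-negative and non-missing")
  structure(tibble(nutrient = .NUTRIENTS, grams = grams),
            class = c("dietlag_diet", "tbl_df", "tbl", "data.frame"))
}

diet_grams <- function(diet) {
  if (inherits(diet, "dietlag_diet") || is.data.frame(diet)) {
    stats::setNames(diet$grams, diet$nutrient)[.NUTRIENTS]
  } else {
    diet_grams(diet_composition(diet))
  }
}

#' Energy content of a diet
#'
#' Total energy in kcal/day: 4 kcal per gram of carbohydrates and protein,
#' 9 kcal per gram of each fat.
#'
#' @param diet A [diet_composition()] (or 5-vector of grams).
#' @return Energy in kcal (scalar).
#' @export
energy_of <- function(diet) {
  g <- diet_grams(diet)
  if (any(g < 0)) abort("diet grams must be non-negative")
  sum(.KCAL * g)
}

#' Rescale a diet to a target energy
#'
#' Multiplies every gram amount by `target_kcal / energy_of(diet)`, so the
#' scaled diet has exactly the target energy and unchanged energy shares.
#'
#' @inheritParams energy_of
#' @param target_kcal Positive target energy (kcal/day).
#' @return A `dietlag_diet` at the target energy.
#' @export
scale_to_energy <- function(diet, target_kcal) {
  stopifnot(target_kcal > 0)
  e <- energy_of(diet)
  if (e <= 0) abort("cannot scale a zero-energy diet")
  diet_composition(diet_grams(diet) * target_kcal / e)
}

#' Energy shares of a diet
#'
#' Percentage of total energy contributed by each macronutrient; the shares
#' sum to 100 for any positive-energy diet.
#'
#' @inheritParams energy_of
#' @return Tibble with columns `nutrient`, `grams`, `kcal`, `percent`.
#' @export
percent_energy <- function(diet) {
  g <- diet_grams(diet)
  e <- sum(.KCAL * g)
  if (e <= 0) abort("percent energy undefined for a zero-energy diet")
  tibble(nutrient = .NUTRIENTS, grams = unname(g), kcal = unname(.KCAL * g),
         percent = unname(100 * .KCAL * g / e))
}

#' Energy distance between two diets
#'
#' Sum over nutrients of the per-nutrient gram difference weighted by energy
#' density.  The default takes absolute per-nutrient differences, which makes
#' the quantity a metric on diets; `signed = TRUE` lets surpluses and
#' deficits cancel.
#'
#' @param a,b Diets as from [diet_composition()].
#' @param signed Use signed differences instead of absolute values.
#' @return Energy difference in kcal (scalar).
#' @export
energy_difference <- function(a, b, signed = FALSE) {
  d <- diet_grams(a) - diet_grams(b)
  if (!signed) d <- abs(d)
  sum(.KCAL * d)
}

## ---- tabular I/O -------------------------------------------------------

validate_years <- function(years, what = "series") {
  if (length(years) == 0L) abort(paste(what, "is empty"))
  if (anyNA(years)) abort(paste(what, "has missing years"))
  if (any(diff(years) != 1L)) {
    gap <- years[which(diff(years) != 1L)[1]]
    abort(paste0(what, " years must be contiguous with step 1; gap after year ", gap))
  }
  invisible(years)
}

#' Validate a nutrient availability table
#'
#' Checks that a data frame is a well-formed availability panel: a `year`
#' column of contiguous integers and one non-negative, complete column per
#' macronutrient.  Columns may arrive in any order; the result is normalised
#' to canonical order.
#'
#' @param df Data frame with columns `year` and the five nutrient columns.
#' @return A validated tibble (`year` then nutrients in canonical order).
#' @export
validate_nutrient_series <- function(df) {
  df <- as_tibble(df)
  missing <- setdiff(c("year", .NUTRIENTS), names(df))
  if (length(missing)) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  df <- df[, c("year", .NUTRIENTS)]
  df$year <- as.integer(df$year)
  df <- df[order(df$year), ]
  validate_years(df$year, "availability series")
  for (n in .NUTRIENTS) {
    v <- df[[n]]
    if (anyNA(v)) {
      abort(paste0("missing value in column '", n, "' at year ",
                   df$year[which(is.na(v))[1]]))
    }
    if (any(v < 0)) {
      abort(paste0("negative value in column '", n, "' at year ",
                   df$year[which(v < 0)[1]]))
    }
  }
  df
}

#' Validate a yearly correlation series
#'
#' @param df Data frame with columns `year` and `r`; `r` must lie in
#'   \[-1, 1\] and years must be contiguous.
#' @return A validated tibble.
#' @export
validate_r_series <- function(df) {
  df <- as_tibble(df)
  missing <- setdiff(c("year", "r"), names(df))
  if (length(missing)) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  df <- df[, c("year", "r")]
  df$year <- as.integer(df$year)
  df <- df[order(df$year), ]
  validate_years(df$year, "correlation series")
  if (anyNA(df$r)) abort("missing r value")
  bad <- which(abs(df$r) > 1)
  if (length(bad)) {
    abort(paste0("|r| > 1 at year ", df$year[bad[1]],
                 " (r = ", format(df$r[bad[1]]), ")"))
  }
  df
}

#' Read yearly tables from CSV
#'
#' Comma-separated, UTF-8, header row with canonical column names
#' (`year`, `carbohydrates`, `protein`, `sat_fat`, `mono_fat`, `poly_fat`
#' for availability panels; `year`, `r` for correlation series).  Column
#' order in the file is free.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble; see [validate_nutrient_series()] /
#'   [validate_r_series()].
#' @export
read_nutrient_series <- function(path) {
  validate_nutrient_series(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
}

#' @rdname read_nutrient_series
#' @export
read_r_series <- function(path) {
  validate_r_series(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Write yearly tables to CSV
#'
#' Writes the standard CSV dialect read back by [read_nutrient_series()] and
#' [read_r_series()]; numeric values keep full double precision so a
#' write/read round trip is lossless.
#'
#' @param df A validated series tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nutrient_series <- function(df, path) {
  readr::write_csv(validate_nutrient_series(df), path)
  invisible(path)
}

#' @rdname write_nutrient_series
#' @export
write_r_series <- function(df, path) {
  readr::write_csv(validate_r_series(df), path)
  invisible(path)
}
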