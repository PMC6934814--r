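## End-to-end pipeline: per-period lag optimization -> confidence summary ->
## diet optimization -> comparison table, with an optional on-disk run
## manifest for reproducibility.

#' Run the full calculator pipeline
#'
#' For each configured life period: exhaustively optimize the precedence
#' periods ([global_optimize()]), summarise their confidence
#' ([confidence_summary()]), compute the period's mean availability, build
#' the candidate diet grid and select the optimal predicted diet
#' ([optimize_diet()]); finally assemble the cross-period comparison table
#' ([build_report()]).
#'
#' @param series Availability panel (tibble or CSV path).
#' @param r Correlation series (tibble or CSV path).
#' @param config Analysis configuration.
#' @param periods Period names to run (default: all configured).
#' @param output_dir Optional directory: writes JSON/CSV artifacts and a
#'   run manifest.
#' @return Object of class `calculator_run`: `scans`, `confidence`,
#'   `diets` (per period), `table`, `config`, `manifest`.
#' @export
run_calculator <- function(series, r, config = analysis_config(),
                           periods = NULL, output_dir = NULL) {
  t_start <- Sys.time()
  series_path <- if (is.character(series)) series else NA_character_
  r_path <- if (is.character(r)) r else NA_character_
  if (is.character(series)) series <- read_nutrient_series(series)
  if (is.character(r)) r <- read_r_series(r)
  series <- validate_nutrient_series(series)
  r <- validate_r_series(r)
  periods <- periods %||% config$periods$period

  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  scans <- list(); conf <- list(); diets <- list()
  for (p in periods) {
    scans[[p]] <- stage(paste0("optimize_lags:", p),
                        global_optimize(series, r, p, config))
    conf[[p]] <- stage(paste0("confidence:", p), confidence_summary(scans[[p]]))
    diets[[p]] <- stage(paste0("optimize_diet:", p), {
      mean_diet <- mean_availability(series, p, config)
      grid <- default_grid(series, p, config)
      optimize_diet(scans[[p]]$optimal_fit, mean_diet, grid,
                    selection_policy(r_tolerance = config$r_tolerance), config)
    })
  }
  table <- stage("report", build_report(diets))
  confidence <- dplyr::bind_rows(conf)

  manifest <- list(
    package_version = as.character(utils::packageVersion("dietlag")),
    seed = config$seed,
    config = list(max_lag = config$max_lag, coverage = config$coverage,
                  grid_steps = as.list(config$grid_steps),
                  grid_span = config$grid_span,
                  r_tolerance = config$r_tolerance,
                  report_kcal = config$report_kcal,
                  min_rows = config$min_rows,
                  periods = as.data.frame(config$periods)),
    inputs = list(
      series_path = series_path, r_path = r_path,
      series_md5 = if (!is.na(series_path)) unname(tools::md5sum(series_path)) else NA_character_,
      r_md5 = if (!is.na(r_path)) unname(tools::md5sum(r_path)) else NA_character_,
      series_span = range(series$year), r_span = range(r$year)
    ),
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  run <- structure(list(scans = scans, confidence = confidence, diets = diets,
                        table = table, config = config, manifest = manifest),
                   class = "calculator_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

# serialise a run's artifacts; numeric JSON at full precision so reruns are
# byte-comparable
write_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  js <- function(x, file) {
    jsonlite::write_json(x, file.path(output_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  fits <- purrr::map(run$scans, function(s) {
    list(period = s$period, optimal_lags = as.list(s$optimal_lags),
         r_optimal = s$r_optimal, alpha = s$optimal_fit$alpha,
         betas = as.list(s$optimal_fit$betas), n_obs = s$optimal_fit$n_obs,
         n_usable = s$n_usable, n_unusable = s$n_unusable)
  })
  js(fits, "fits.json")
  readr::write_csv(run$confidence, file.path(output_dir, "confidence.csv"))
  diets <- purrr::map(run$diets, function(d) {
    list(period = d$period, r_predicted = d$r_predicted,
         r_predicted_min = d$r_predicted_min,
         energy_difference_kcal = d$energy_difference_kcal,
         predicted_grams = as.list(diet_grams(d$diet)),
         predicted_grams_scaled = as.list(diet_grams(d$diet_scaled)),
         mean_grams_scaled = as.list(diet_grams(d$mean_diet_scaled)),
         report_kcal = d$report_kcal, n_candidates = d$n_candidates)
  })
  js(diets, "diets.json")
  readr::write_csv(run$table, file.path(output_dir, "report.csv"))
  js(run$manifest, "manifest.json")
  invisible(output_dir)
}

#' @export
print.calculator_run <- function(x, ...) {
  cat("Calculator run over", length(x$scans), "life period(s)\n")
  for (s in x$scans) {
    cat(sprintf("  %-18s r_optimal = %.4f at lags (%s)\n", s$period,
                s$r_optimal, paste(s$optimal_lags, collapse = ", ")))
  }
  cat("\nComparison table (percent of energy, rounded):\n")
  print(report_wide(x$table, "percent"), n = Inf)
  invisible(x)
}

## ---- broom-style methods ----------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted calculator equation
#'
#' @param x A `calculator_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` and, when recorded, the `lag`
#'   applied to each term.
#' @export
#' @exportS3Method generics::tidy
tidy.calculator_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", nutrient_names()),
         estimate = c(x$alpha, unname(x$betas)),
         lag = c(NA_integer_, if (is.null(x$lags)) rep(NA_integer_, 5)
                 else unname(x$lags)))
}

#' @rdname tidy.calculator_fit
#' @export
#' @exportS3Method generics::glance
glance.calculator_fit <- function(x, ...) {
  tibble(r_fit = x$r_fit, r_squared = x$r_fit^2, n_obs = x$n_obs,
         period = x$period %||% NA_character_)
}

#' Tidy a lag scan
#'
#' @param x A `lag_scan`.
#' @param ... Unused.
#' @return The per-nutrient per-lag profile tibble (`nutrient`, `lag`, `n`,
#'   `r_mean`, `r_sd`).
#' @export
#' @exportS3Method generics::tidy
tidy.lag_scan <- function(x, ...) x$profiles

#' @rdname tidy.lag_scan
#' @export
#' @exportS3Method generics::glance
glance.lag_scan <- function(x, ...) {
  tibble(period = x$period, max_lag = x$max_lag, r_optimal = x$r_optimal,
         n_usable = x$n_usable, n_unusable = x$n_unusable,
         !!!stats::setNames(as.list(x$optimal_lags),
                            paste0("lag_", nutrient_names())))
}

#' Tidy a diet report
#'
#' @param x A `diet_report`.
#' @param ... Unused.
#' @return Long tibble of predicted and mean diets at the report energy.
#' @export
#' @exportS3Method generics::tidy
tidy.diet_report <- function(x, ...) build_report(list(x), rounded = FALSE)

#' @rdname tidy.diet_report
#' @export
#' @exportS3Method generics::glance
glance.diet_report <- function(x, ...) {
  tibble(period = x$period %||% NA_character_, r_predicted = x$r_predicted,
         r_predicted_min = x$r_predicted_min,
         energy_difference_kcal = x$energy_difference_kcal,
         n_candidates = x$n_candidates, report_kcal = x$report_kcal)
}

#' Tidy a full calculator run
#'
#' @param x A `calculator_run`.
#' @param ... Unused.
#' @return The cross-period comparison table.
#' @export
#' @exportS3Method generics::tidy
tidy.calculator_run <- function(x, ...) x$table

#' @rdname tidy.calculator_run
#' @export
#' @exportS3Method generics::glance
glance.calculator_run <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$scans, glance))
}
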