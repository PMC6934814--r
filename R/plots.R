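## ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_col facet_wrap labs position_dodge
#' @export
ggplot2::autoplot

#' Plot an availability panel and (optionally) the correlation series
#'
#' Yearly gram availabilities, one facet per macronutrient; when a
#' correlation series is supplied it is drawn in its own facet on the
#' correlation scale.
#'
#' @param series Availability panel.
#' @param r Optional correlation series.
#' @return A ggplot object.
#' @export
plot_series <- function(series, r = NULL) {
  long <- tidyr::pivot_longer(validate_nutrient_series(series),
                              -"year", names_to = "series", values_to = "value")
  if (!is.null(r)) {
    long <- dplyr::bind_rows(long, tibble(year = validate_r_series(r)$year,
                                          series = "r", value = r$r))
  }
  long$series <- factor(long$series, levels = c(nutrient_names(), "r"))
  ggplot(long, aes(x = .data$year, y = .data$value)) +
    geom_line() +
    facet_wrap(~series, scales = "free_y") +
    labs(x = "year", y = "grams/day (r for the correlation facet)")
}

#' @describeIn lag_profile Plot method: per-lag mean fit statistic with a
#'   +/- 1 SD ribbon, one facet per nutrient, optimum marked.
#' @param object A `lag_scan`.
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.lag_scan <- function(object, ...) {
  prof <- object$profiles
  opt <- tibble(nutrient = nutrient_names(),
                lag = unname(object$optimal_lags))
  opt$r_mean <- prof$r_mean[match(paste(opt$nutrient, opt$lag),
                                  paste(prof$nutrient, prof$lag))]
  ggplot(prof, aes(x = .data$lag, y = .data$r_mean)) +
    geom_ribbon(aes(ymin = .data$r_mean - .data$r_sd,
                    ymax = .data$r_mean + .data$r_sd), alpha = 0.25) +
    geom_line() +
    geom_point(data = opt, colour = "red") +
    facet_wrap(~nutrient) +
    labs(title = paste0("Per-lag fit profile [", object$period, "]"),
         x = "precedence period (years)", y = "mean R over the grid")
}

#' @describeIn build_report Plot method: predicted vs mean energy shares per
#'   period.
#' @param object A `calculator_table`.
#' @param ... Unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.calculator_table <- function(object, ...) {
  df <- as_tibble(object)
  df$nutrient <- factor(df$nutrient, levels = nutrient_names())
  ggplot(df, aes(x = .data$nutrient, y = .data$percent, fill = .data$diet)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~period) +
    labs(x = NULL, y = "percent of energy", fill = NULL)
}
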