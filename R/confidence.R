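## "Relative sequence of confidence" for the selected precedence periods.
## For each nutrient, the fit statistics of all grid combinations are
## regrouped by that nutrient's lag; the lag of the global optimum, the lag
## maximising the per-lag mean R and the lag minimising its SD give three
## criterion lags, whose spread maps to a star level.

#' Per-lag aggregate profile of the fit statistic for one nutrient
#'
#' For each lag `k` of the chosen nutrient, aggregates the fit statistic
#' over every usable grid combination whose component for that nutrient
#' equals `k`: count, mean (`r_mean`) and sample SD (`r_sd`, 0 when a single
#' combination contributes).  Unusable combinations carry no statistic and
#' are excluded.
#'
#' @param result A [global_optimize()] result.
#' @param nutrient One of [nutrient_names()].
#' @return Tibble with columns `nutrient`, `lag`, `n`, `r_mean`, `r_sd`.
#' @export
lag_profile <- function(result, nutrient) {
  stopifnot(inherits(result, "lag_scan"))
  if (!nutrient %in% nutrient_names()) {
    abort(paste0("unknown nutrient '", nutrient, "'"))
  }
  result$profiles[result$profiles$nutrient == nutrient, ]
}

#' Confidence star level for a precedence-period SD
#'
#' Maps the SD of the mean precedence period to the relative confidence
#' scale: `[0, 2)` highest (`***`), `[2, 5)` high (`**`), `[5, 8)` lower
#' (`*`), `[8, Inf)` lowest (`none`).  Ranges are half-open and
#' lower-inclusive so the mapping is total and non-overlapping.
#'
#' @param sd_precedence Non-negative SD in years (vectorised).
#' @return Character vector of star levels.
#' @export
star_level <- function(sd_precedence) {
  dplyr::case_when(
    sd_precedence < 2 ~ "***",
    sd_precedence < 5 ~ "**",
    sd_precedence < 8 ~ "*",
    TRUE ~ "none"
  )
}

#' Three-criterion confidence for one nutrient's precedence period
#'
#' The criterion lags are (1) the nutrient's lag at the global optimum,
#' (2) the lag maximising the per-lag mean fit statistic and (3) the lag
#' minimising its SD (ties toward the smallest lag).  Their mean is the mean
#' precedence period; their sample SD maps to a star level:
#' `[0, 2)` three stars, `[2, 5)` two, `[5, 8)` one, `[8, Inf)` none.
#'
#' @param profile A [lag_profile()] tibble.
#' @param optimal_lag This nutrient's component of the optimal lag vector.
#' @return One-row tibble: `nutrient`, `lag_at_r_optimal`,
#'   `lag_at_max_rmean`, `lag_at_min_sd`, `mean_precedence`,
#'   `sd_precedence`, `stars`.
#' @export
precedence_confidence <- function(profile, optimal_lag) {
  usable <- profile[!is.na(profile$r_mean), ]
  if (nrow(usable) == 0L) abort("profile has no usable lags")
  lag_mean <- usable$lag[which.max(usable$r_mean)]   # which.max: first = smallest lag
  lag_sd <- usable$lag[which.min(usable$r_sd)]
  crit <- c(optimal_lag, lag_mean, lag_sd)
  m <- mean(crit)
  s <- stats::sd(crit)
  tibble(
    nutrient = profile$nutrient[1],
    lag_at_r_optimal = as.integer(optimal_lag),
    lag_at_max_rmean = as.integer(lag_mean),
    lag_at_min_sd = as.integer(lag_sd),
    mean_precedence = m,
    sd_precedence = s,
    stars = star_level(s)
  )
}

#' Confidence summary for every nutrient of a lag scan
#'
#' Applies [precedence_confidence()] to each nutrient's [lag_profile()],
#' producing the table behind the star annotations: optimal precedence
#' period and confidence level per nutrient.
#'
#' @param result A [global_optimize()] result.
#' @return Tibble with one row per nutrient (see [precedence_confidence()]),
#'   plus the `period` of the scan.
#' @export
confidence_summary <- function(result) {
  stopifnot(inherits(result, "lag_scan"))
  out <- purrr::map_dfr(nutrient_names(), function(nm) {
    precedence_confidence(lag_profile(result, nm), result$optimal_lags[nm])
  })
  dplyr::bind_cols(tibble(period = result$period), out)
}
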