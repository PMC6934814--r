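## Diet-composition grid search: score every candidate diet with the fitted
## calculator equation (Rpredicted), keep the diets within a tolerance band
## of the minimum, and among those choose the one energetically closest to
## the period's historical mean availability.

#' Mean availability over a life period
#'
#' Per-nutrient arithmetic mean of the availability grams over the period's
#' years, with no lag shifting — the historical "mean diet" every predicted
#' diet is compared against.
#'
#' @inheritParams shift_alignment
#' @return A [diet_composition()].
#' @export
mean_availability <- function(series, period, config = analysis_config()) {
  series <- validate_nutrient_series(series)
  p <- resolve_period(period, config)
  years <- seq.int(p$start_year, p$end_year)
  if (!all(years %in% series$year)) {
    abort(paste0("series does not cover period ", p$period,
                 " (", p$start_year, "-", p$end_year, ")"))
  }
  rows <- series[series$year %in% years, nutrient_names()]
  diet_composition(colMeans(rows))
}

#' Predicted correlation for a diet
#'
#' Evaluates the fitted calculator equation at a diet:
#' `alpha + sum_i beta_i * grams_i`.  The value is a model extrapolation and
#' is deliberately not clamped to \[-1, 1\].
#'
#' @param fit A [fit_calculator()] object.
#' @param diet A [diet_composition()] (or 5-vector of grams).
#' @return Predicted correlation (scalar).
#' @export
rpredicted <- function(fit, diet) {
  stopifnot(inherits(fit, "calculator_fit"))
  unname(fit$alpha + sum(fit$betas * diet_grams(diet)))
}

#' Diet grid specification
#'
#' Per-nutrient candidate gram values `seq(low, high, by = step)`; the grid
#' is their Cartesian product.
#'
#' @param low,high Numeric length-5 bounds (grams, canonical order).
#' @param step Numeric length-5 steps (grams).
#' @return Tibble of class `diet_grid` with columns `nutrient`, `low`,
#'   `high`, `step`, `n_values`.
#' @export
diet_grid <- function(low, high, step) {
  low <- as.numeric(low); high <- as.numeric(high); step <- as.numeric(step)
  stopifnot(length(low) == 5L, length(high) == 5L, length(step) == 5L,
            all(step > 0), all(low <= high), all(low >= 0))
  structure(tibble(nutrient = nutrient_names(), low = low, high = high,
                   step = step,
                   n_values = floor((high - low) / step + 1e-9) + 1L),
            class = c("diet_grid", "tbl_df", "tbl", "data.frame"))
}

grid_values <- function(grid) {
  purrr::pmap(grid[, c("low", "step", "n_values")],
              function(low, step, n_values) low + step * (seq_len(n_values) - 1))
}

#' Number of candidate diets on a grid
#'
#' @param grid A [diet_grid()].
#' @return Product of the per-nutrient value counts.
#' @export
grid_size <- function(grid) prod(as.double(grid$n_values))

#' Default diet grid from observed availabilities
#'
#' Per nutrient, bounds span `grid_span[1]` times the period minimum to
#' `grid_span[2]` times the period maximum of the observed grams, snapped
#' outward to the step (and floored at 0); steps come from the
#' configuration.
#'
#' @inheritParams mean_availability
#' @return A [diet_grid()].
#' @export
default_grid <- function(series, period, config = analysis_config()) {
  series <- validate_nutrient_series(series)
  p <- resolve_period(period, config)
  rows <- series[series$year >= p$start_year & series$year <= p$end_year, ]
  if (nrow(rows) == 0L) abort(paste0("series does not cover period ", p$period))
  lo <- config$grid_span[1] * vapply(rows[nutrient_names()], min, 0)
  hi <- config$grid_span[2] * vapply(rows[nutrient_names()], max, 0)
  step <- config$grid_steps
  diet_grid(pmax(0, floor(lo / step) * step), ceiling(hi / step) * step, step)
}

#' Diet selection policy
#'
#' Two-stage rule: diets whose predicted-correlation score is within
#' `r_tolerance` of the grid minimum compete on energy difference from the
#' mean diet; remaining ties go to the lexicographically smallest gram
#' vector.  `objective = "signed"` minimises the predicted correlation
#' itself (most negative wins); `"absolute"` drives it toward zero.
#'
#' @param objective `"signed"` or `"absolute"`.
#' @param r_tolerance Non-negative tolerance band.
#' @param signed_energy Use signed instead of absolute per-nutrient energy
#'   differences (see [energy_difference()]).
#' @return A list of class `selection_policy`.
#' @export
selection_policy <- function(objective = c("signed", "absolute"),
                             r_tolerance = 0.01, signed_energy = FALSE) {
  objective <- match.arg(objective)
  stopifnot(r_tolerance >= 0)
  structure(list(objective = objective, r_tolerance = r_tolerance,
                 signed_energy = signed_energy), class = "selection_policy")
}

# decode chunk of lexicographic grid indices (0-based; first nutrient most
# significant) into a 5-column matrix of per-axis value indices (1-based)
decode_grid_indices <- function(idx, n_values) {
  out <- matrix(0L, nrow = length(idx), ncol = 5L)
  rem <- as.double(idx)
  for (i in 5:1) {
    out[, i] <- as.integer(rem %% n_values[i]) + 1L
    rem <- rem %/% n_values[i]
  }
  out
}

#' Optimal predicted diet on a gram grid
#'
#' Enumerates every diet on the grid, scores each with the calculator
#' equation, then applies the selection policy: among diets with score
#' within `r_tolerance` of the grid minimum, pick the minimum energy
#' difference from `mean_diet`; break ties lexicographically by gram
#' vector.  Enumeration is chunked so large grids never materialise at
#' once, and the result is independent of enumeration order.
#'
#' @param fit A [fit_calculator()] object.
#' @param mean_diet The period's [mean_availability()] diet.
#' @param grid A [diet_grid()].
#' @param policy A [selection_policy()].
#' @param config Analysis configuration (`report_kcal`, `max_grid_size`).
#' @return Object of class `diet_report`: chosen diet (raw and scaled to
#'   `report_kcal`), the mean diet scaled likewise, `r_predicted`,
#'   `r_predicted_min`, `energy_difference_kcal` and grid bookkeeping.
#' @export
optimize_diet <- function(fit, mean_diet, grid, policy = selection_policy(),
                          config = analysis_config()) {
  stopifnot(inherits(fit, "calculator_fit"), inherits(grid, "diet_grid"))
  mean_g <- diet_grams(mean_diet)
  total <- grid_size(grid)
  if (total < 1) abort("empty diet grid")
  if (total > config$max_grid_size) {
    abort(paste0("diet grid has ", format(total, big.mark = ","),
                 " candidates, above max_grid_size; coarsen the steps"))
  }
  vals <- grid_values(grid)
  nv <- grid$n_values
  kcal <- kcal_per_gram()
  # per-axis contributions to the score and to the energy difference
  contrib <- purrr::map2(vals, fit$betas, function(v, b) b * v)
  edif_axis <-purrr::map2(vals, seq_len(5), function(v, i) {
    d <- v - mean_g[i]
    if (policy$signed_energy) kcal[i] * d else kcal[i] * abs(d)
  })

  chunk <- 1e6
  starts <- seq(0, total - 1, by = chunk)
  score_of <- function(idx_mat) {
    s <- rep(fit$alpha, nrow(idx_mat))
    for (i in 1:5) s <- s + contrib[[i]][idx_mat[, i]]
    if (policy$objective == "absolute") abs(s) else s
  }
  # pass 1: grid minimum of the score
  min_score <- Inf
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1, total - 1)
    m <- decode_grid_indices(idx, nv)
    min_score <- min(min_score, min(score_of(m)))
  }
  # pass 2: among the tolerance band, minimise energy difference
  best <- list(edif = Inf, idx = Inf)
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1, total - 1)
    m <- decode_grid_indices(idx, nv)
    sc <- score_of(m)
    keep <- which(sc <= min_score + policy$r_tolerance)
    if (!length(keep)) next
    ed <- rep(0, length(keep))
    mk <- m[keep, , drop = FALSE]
    for (i in 1:5) ed <- ed + edif_axis[[i]][mk[, i]]
    j <- which.min(ed)  # first minimum = lexicographically smallest in-chunk
    if (ed[j] < best$edif || (ed[j] == best$edif && idx[keep[j]] < best$idx)) {
      best <- list(edif = ed[j], idx = idx[keep[j]])
    }
  }
  chosen_idx <- decode_grid_indices(best$idx, nv)
  chosen <- diet_composition(purrr::map2_dbl(vals, as.integer(chosen_idx), `[`))
  r_pred <- rpredicted(fit, chosen)

  structure(list(
    period = fit$period,
    fit = fit,
    diet = chosen,
    diet_scaled = scale_to_energy(chosen, config$report_kcal),
    mean_diet = diet_composition(mean_g),
    mean_diet_scaled = scale_to_energy(diet_composition(mean_g), config$report_kcal),
    r_predicted = r_pred,
    r_predicted_min = min_score,
    energy_difference_kcal = best$edif,
    report_kcal = config$report_kcal,
    grid = grid,
    n_candidates = total,
    policy = policy
  ), class = "diet_report")
}

#' @export
print.diet_report <- function(x, ...) {
  cat(sprintf("Optimal predicted diet%s (%s candidates)\n",
              if (!is.null(x$period)) paste0(" [", x$period, "]") else "",
              format(x$n_candidates, big.mark = ",")))
  cat(sprintf("  r_predicted = %.4f (grid minimum %.4f), energy difference = %.1f kcal\n",
              x$r_predicted, x$r_predicted_min, x$energy_difference_kcal))
  pe <- percent_energy(x$diet_scaled)
  pm <- percent_energy(x$mean_diet_scaled)
  cat(sprintf("  at %g kcal:\n", x$report_kcal))
  for (i in 1:5) {
    cat(sprintf("  %-14s predicted %3.0f g (%2.0f%%)   mean %3.0f g (%2.0f%%)\n",
                pe$nutrient[i], round_half_up(pe$grams[i]),
                round_half_up(pe$percent[i]), round_half_up(pm$grams[i]),
                round_half_up(pm$percent[i])))
  }
  invisible(x)
}

#' Comparison table of predicted and mean diets across life periods
#'
#' Assembles the report table: for each period and each macronutrient, the
#' predicted and the historical mean diet at the common report energy, as
#' percent of energy and grams per day.  Values are rounded half-up to
#' integers only at this reporting stage; pass `rounded = FALSE` for full
#' precision.
#'
#' @param reports List of [optimize_diet()] results (one per period).
#' @param rounded Round percent and grams to integers (default TRUE).
#' @return Tibble of class `calculator_table` in long form: `period`,
#'   `diet` (`predicted` / `mean`), `nutrient`, `percent`, `grams`.
#' @export
build_report <- function(reports, rounded = TRUE) {
  rows <- purrr::map_dfr(reports, function(rep) {
    stopifnot(inherits(rep, "diet_report"))
    pred <- percent_energy(rep$diet_scaled)
    mn <- percent_energy(rep$mean_diet_scaled)
    dplyr::bind_rows(
      tibble(period = rep$period %||% "custom", diet = "predicted",
             nutrient = pred$nutrient, percent = pred$percent, grams = pred$grams),
      tibble(period = rep$period %||% "custom", diet = "mean",
             nutrient = mn$nutrient, percent = mn$percent, grams = mn$grams)
    )
  })
  if (rounded) {
    rows$percent <- round_half_up(rows$percent)
    rows$grams <- round_half_up(rows$grams)
  }
  structure(rows, class = c("calculator_table", class(tibble())))
}

#' Widen a report table for printing
#'
#' @param table A [build_report()] tibble.
#' @param value `"percent"` or `"grams"`.
#' @return Wide tibble: one row per diet x nutrient, one column per period.
#' @export
report_wide <- function(table, value = c("percent", "grams")) {
  value <- match.arg(value)
  tidyr::pivot_wider(
    table[, c("period", "diet", "nutrient", value)],
    names_from = "period", values_from = dplyr::all_of(value)
  ) |>
    dplyr::arrange(dplyr::desc(.data$diet),
                   match(.data$nutrient, nutrient_names()))
}
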