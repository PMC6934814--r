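---
title: "Lagged macronutrient calculator: model, procedure and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lagged macronutrient calculator: model, procedure and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietlag)
```

## The problem

Across US states, the per-year Pearson correlation between historical
per-capita personal income (PCPI, 1929–2005) and the state's 2005
age-adjusted Alzheimer's death rate (AADR) forms a yearly series that
oscillates over the century.  The working hypothesis behind this package is
that those oscillations track the changing macronutrient composition of the
average diet, with a nutrient-specific delay — a *precedence period* —
between consumption and effect.  The package estimates those delays, fits a
linear "calculator" equation at the best delays, and then inverts the
equation: it searches for a diet composition that minimises the predicted
correlation while staying energetically close to what the population
actually ate.

## The model

For a life period (a calendar window), the response $r(t)$ is modelled as an
additive equation in the five availabilities, each shifted back by its own
lag $\ell_i$:

$$ r(t) = \alpha + \sum_{i=1}^{5} \beta_i \, x_i(t - \ell_i) + \varepsilon(t), $$

with nutrients ordered (carbohydrates, protein, saturated fat,
monounsaturated fat, polyunsaturated fat).  The additive smooth terms of the
general formulation are *linearized*, so each term is an ordinary linear
coefficient in grams and the equation can be evaluated at any hypothetical
diet.  A fit's quality is the non-negative multiple correlation
$R = \sqrt{R^2}$, unadjusted, defined as 0 for a constant response.  Sign is
meaningless for a multivariate fit and the search ranks by the highest $R$.

Lag selection is exhaustive: every vector $(\ell_1,\dots,\ell_5) \in
\{0,\dots,L\}^5$ is fitted and the maximiser ($R_{optimal}$) is kept.  With
the default $L = 20$ this is $21^5 = 4{,}084{,}101$ fits per life period.
The scan is exact, not heuristic: because every fit within one usable-row
window shares the same predictor columns, the implementation precomputes the
centred cross-products of all $5(L+1)$ lagged columns once per window and
reduces each combination to a $5\times 5$ normal-equations solve (in
compiled code).  This reproduces ordinary least squares exactly — tests
compare it, combination by combination, to refits with `lm`-style code and
to an independent normal-equations oracle — and completes the full default
grid in seconds on one CPU.

## Confidence in the selected lags

For each nutrient, the grid of fits is regrouped by that nutrient's lag:
each lag level aggregates the $R$ values of all combinations of the other
nutrients' lags ($R_{mean}$ and its SD per level).  Three criterion lags —
the nutrient's lag at the global optimum, the lag maximising $R_{mean}$, and
the lag minimising the SD — are averaged into a *mean precedence period*;
their sample SD maps to a star level through half-open, lower-inclusive
ranges: $[0,2)$ `***`, $[2,5)$ `**`, $[5,8)$ `*`, $[8,\infty)$ none.

Three choices here were genuinely open and are resolved as follows:

* **Boundary convention.** The published ranges ("from 0 to 2", "from 2 to
  5", …) are ambiguous at 2, 5 and 8; a total, non-overlapping mapping
  requires a convention, and lower-inclusive half-open intervals are used
  (so an SD of exactly 2 earns `**`).
* **SD normalisation.** Sample ($n-1$) SD over the three criterion lags; the
  source procedure does not state the normalisation, and the sample version
  is the conservative choice, consistent with that procedure's own remark
  that its SD is overestimated.
* **Ties.** `argmax`/`argmin` ties in the profiles resolve toward the
  smallest lag, for reproducibility.

A property worth knowing: the idealised expectation that, on noiseless
synthetic data, all three criteria coincide at the true lag holds under this
package's default generator settings, but it is not universal.  The two
auxiliary criteria are aggregates over mostly-wrong lag combinations of the
other nutrients, and on some data draws they sit 2–4 years away from the
truth even with zero response noise, dropping one nutrient to `**`.  They
should be read as confidence heuristics, not as consistent estimators of the
lag.

## Diet optimization

The optimal fit per period becomes a scoring function
$R_{pred}(d) = \alpha + \sum_i \beta_i d_i$ over candidate diets $d$ (grams
per day).  The value is a model extrapolation and is deliberately not
clamped to $[-1, 1]$.  Candidates live on a per-nutrient gram grid; by
default the bounds span 0.5× the period minimum to 1.5× the period maximum
of observed availability, snapped outward to the step.  Steps default to
5 g, except polyunsaturated fat at 1 g — its historical range is narrower
than a single 5 g step, so a 5 g grid would barely probe it.

Selection is two-stage: diets whose score is within `r_tolerance` (default
0.01, in correlation units) of the grid minimum compete on *energy
difference* from the period's mean availability, computed as
$\sum_i k_i\,|d_i - m_i|$ with $k = (4,4,9,9,9)$ kcal/g; remaining ties go
to the lexicographically smallest gram vector.  Two conventions here are
documented package choices:

* The published criterion is bi-objective ("minimize predicted correlation"
  and "minimum energy difference") without a stated trade-off; the tolerance
  band makes it deterministic, and `r_tolerance = 0` recovers the pure
  grid-minimum rule.
* "Sum of differences" for the energy difference is read as a sum of
  *absolute* per-nutrient terms, which makes it a metric and prevents
  surpluses cancelling deficits; a signed mode exists
  (`energy_difference(..., signed = TRUE)`, `selection_policy(signed_energy
  = TRUE)`).
* The score is minimised as a signed value (the most negative predicted
  correlation wins), since a lower income–mortality correlation is the
  stated goal; `selection_policy(objective = "absolute")` instead drives the
  prediction toward zero.

The mean availability diet is computed *without* lag shifting over the
period's years.  Both the chosen and the mean diet are reported scaled to a
common energy (default 2000 kcal/day); scaling happens after optimization,
and percent/gram rounding (half away from zero) happens only at the
reporting edge.

## Life periods and coverage

The four default windows are youth 1929–1949, early middle age 1949–1970,
late middle age 1970–1990 and late age 1990–2005, inclusive at both ends
(boundary years belong to both adjacent periods, exactly as the printed
ranges overlap — the source does not state the convention, so inclusivity is
a documented choice).  A response year $t$ is usable for a lag vector only
if $x_i(t-\ell_i)$ exists for every nutrient.  By default, years with
incomplete lagged coverage are dropped per combination (complete case
within combination), which maximises data use; `coverage = "common_window"`
instead restricts every combination to the window valid at the maximum lag
so all fits share identical rows.  Combinations left with fewer than 7
usable rows (one more than the number of coefficients) are counted as
unusable, never silently skipped, and rank-deficient designs are likewise
recorded as unusable during the scan (and raise an explicit error in the
single-fit interface).

## The synthetic-data generator

Because the historical availability panel is not redistributable, every
stage is exercised against generated data with known ground truth:

* **Availability** (`synth_availability()`): per nutrient, a linear trend
  plus one sinusoid plus i.i.d. Gaussian gram noise, clipped at zero.
  Baselines (300, 90, 40, 55, 15 g) and slopes emulate US-scale per-capita
  supply; sinusoid periods differ per nutrient (40, 28, 22, 34, 18 years) —
  with a shared period the noise-free panel would be rank-deficient by
  construction (five columns in the span of one trend and one sinusoid), so
  distinct cycle lengths are both more realistic and necessary for a
  well-posed noiseless limit.  Default gram noise is 3 g.
* **Response** (`synth_roriginal()`): the linear equation above evaluated at
  known true lags, plus Gaussian noise on the correlation scale, clamped to
  $[-1,1]$ (noise on the $r$ scale keeps the series valid while staying a
  simple additive model).  Default truth: lags (3, 0, 1, 2, 4), coefficients
  (0.008, −0.010, 0.012, −0.008, 0.020) per gram, intercept −1.64, noise SD
  0.05.  The coefficients follow an explicit identifiability rule — each
  $|\beta_i|$ times the 3 g gram noise is of the same order as the response
  noise (0.02–0.06 vs 0.05) — so the lags the generator plants are
  resolvable from a 77-year series, and the intercept re-centres the
  response near the 0.2 level of the historical series (range roughly −0.1
  to 0.7, clear of the clamp).
* **State panel** (`synth_state_panel()` / `compute_roriginal()`): a
  structural stand-in for the construction behind the response series —
  per-state income trajectories and one mortality value per state, with a
  `coupling` parameter setting the expected final-year cross-state
  correlation; `compute_roriginal()` is a per-year Pearson correlation
  across states.

All generators draw from R's default Mersenne-Twister/Inversion RNG under
`withr::with_seed`, so a fixed seed reproduces bit-identical data on any
platform.  What the generator does *not* emulate: the statistical texture of
the real US series (measurement revisions, autocorrelated noise, policy
shocks), state-level heterogeneity in diet, or any nonlinearity in the
diet–mortality link.  Passing tests therefore demonstrate that the
machinery recovers a truth *of the assumed linear-plus-noise form*; they are
not evidence about the real data-generating process.

## Numerical choices and problem sizes

* The compiled scan solves each 5×5 system by Gaussian elimination with
  partial pivoting; pivots below $10^{-12}$ times the matrix scale mark the
  combination rank-deficient.  $R^2$ is clipped to $[0,1]$ before the square
  root.
* Ties on $R$ across lag vectors resolve to the lexicographically smallest
  vector (iteration order is lexicographic and replacement requires strict
  improvement), so results are independent of evaluation order, and a
  subsample run evaluates to bit-identical statistics wherever it overlaps
  the full grid.
* Diet grids are enumerated in chunks of at most $10^6$ candidates in two
  passes (minimum, then band selection), so memory stays flat; a guard
  (`max_grid_size`, default $2\times 10^7$) rejects grids that would make
  interactive use unpleasant.
* Test and example problem sizes are chosen so the whole suite runs in well
  under a minute of compute for the module tests plus a few tens of seconds
  for the end-to-end checks: lag grids of $6^5$–$11^5$ for recovery studies,
  one full $21^5$ scan, diet grids up to $\approx 10^5$ for oracle
  comparisons.  These sizes already exercise every code path of the
  full-scale analysis.

## Known limitations

* The calculator equation is linear in grams; any true nonlinearity or
  interaction between nutrients is outside the model family.
* The confidence stars are relative, procedure-internal heuristics (see
  above); they are not frequentist coverage statements.
* The diet optimizer trusts the fitted equation far from the observed data
  range (its default grid deliberately extends 50% beyond); predicted
  correlations there can leave $[-1,1]$, which is reported as-is.
* With availability series that begin at the fitting window, large lags
  leave few usable years and per-combination windows differ in length, so
  $R$ values across combinations are not strictly comparable sample sizes;
  the `common_window` mode exists for analyses where that matters.
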