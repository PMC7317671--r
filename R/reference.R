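#' Published group-level annual-change estimates
#'
#' Group-level annual-change summaries from the six-year memory-clinic
#' study that motivates this package, bundled as inputs: they calibrate the
#' synthetic-cohort generator and drive the progression-time arithmetic in
#' [full_score_time()] and [threshold_crossing_time()]. Rates are means of
#' per-subject least-squares slopes, reported per hemisphere:
#' `avra_dmta_yr` is the automated continuous MTA rating change (scale
#' units/year) and `hc_dmm3_yr` the hippocampal volume change (mm^3/year,
#' negative = loss).
#'
#' @return Tibble with columns `at_group`, `hemisphere`, `avra_dmta_yr`,
#'   `hc_dmm3_yr`.
#' @seealso [reference_thresholds()]
#' @export
reference_rates <- function() {
  tibble::tibble(
    at_group = factor(rep(c("AnTn", "ApTn", "ApTp"), each = 2),
                      levels = at_group_levels()),
    hemisphere = rep(c("left", "right"), 3),
    avra_dmta_yr = c(0.04, 0.04, 0.07, 0.08, 0.13, 0.11),
    hc_dmm3_yr = c(-36.3, -39.3, -53.4, -55.4, -93.4, -99.3)
  )
}

#' Published rating-crossover volume thresholds
#'
#' The hippocampal volume change at which a follow-up image becomes more
#' likely to receive a higher MTA score than an unchanged one, as estimated
#' for each of two radiologists in the motivating study (mm^3 of loss,
#' reported as magnitudes). Used as inputs to [threshold_crossing_time()].
#'
#' @return Named numeric vector, one entry per radiologist.
#' @export
reference_thresholds <- function() c(rad1 = 238, rad2 = 235)
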