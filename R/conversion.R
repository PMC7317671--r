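#' Years to progress one full MTA score from a continuous rate
#'
#' With a continuous rating advancing at `mean_rate` scale units per year,
#' a full one-point progression (e.g. 1.0 to 2.0) takes `1 / mean_rate`
#' years. Non-positive rates yield `Inf` (no progression) rather than an
#' error, since fitted group rates can be negative in small samples.
#'
#' @param mean_rate Mean annual rating change, scale units/year.
#' @return Years (possibly `Inf`).
#' @examples
#' full_score_time(0.04) # 25 years
#' @export
full_score_time <- function(mean_rate) {
  stopifnot(is.finite(mean_rate))
  if (mean_rate <= 0) return(Inf)
  1 / mean_rate
}

#' Years until a volume-change threshold is crossed
#'
#' Combines a rating-crossover volume threshold (the volume change at
#' which a higher discrete rating becomes more likely, see
#' [crossover_threshold()]) with a group's mean annual volume change:
#' the expected time until a follow-up image is more likely to be rated
#' higher is `|threshold| / |rate|`. Signs are ignored; both arguments
#' are treated as magnitudes of the same directional change.
#'
#' @param threshold Volume-change threshold, mm^3.
#' @param rate Mean annual volume change, mm^3/year.
#' @return Years (`Inf` for a zero rate).
#' @examples
#' threshold_crossing_time(236.5, 37.8) # ~6.3 years
#' @export
threshold_crossing_time <- function(threshold, rate) {
  stopifnot(is.finite(threshold), is.finite(rate))
  if (rate == 0) return(Inf)
  abs(threshold) / abs(rate)
}

#' Expected continuous score behind an integer rating
#'
#' Under the latent-uniform assumption — subjects rated with integer score
#' `k` have an underlying continuous score uniform on `[k, k + 1)` — the
#' group's expected continuous score is `k + 0.5`. The top category is
#' closed in practice (continuous scores cannot exceed 4), so `k = 4`
#' returns 4.5 with a warning.
#'
#' @param integer_score Integer rating in `{0,...,4}`.
#' @return `integer_score + 0.5`.
#' @export
latent_uniform_mean <- function(integer_score) {
  if (!integer_score %in% 0:4) {
    stop("integer_score must lie in {0,...,4}", call. = FALSE)
  }
  if (integer_score == 4) {
    warning("top rating category is closed in practice; the uniform ",
            "assumption overstates its mean", call. = FALSE)
  }
  integer_score + 0.5
}

#' Ratio of full-score time to threshold-crossing time
#'
#' Under the latent-uniform assumption an average subject sits half a
#' category below the next rating boundary, so progressing one full
#' continuous score should take roughly twice as long as crossing into
#' the next discrete rating; this ratio makes the comparison explicit.
#'
#' @param full_time Years for one full continuous score
#'   ([full_score_time()]).
#' @param threshold_time Years to the rating-crossover threshold
#'   ([threshold_crossing_time()]).
#' @return `full_time / threshold_time` (expected near 2 under the
#'   latent-uniform assumption).
#' @export
reconciliation_ratio <- function(full_time, threshold_time) {
  if (!is.finite(full_time) || !is.finite(threshold_time) ||
      full_time <= 0 || threshold_time <= 0) {
    stop("both times must be positive and finite", call. = FALSE)
  }
  full_time / threshold_time
}

#' Per-group progression-time estimates
#'
#' Applies the two progression-time estimators to per-group inputs:
#' `continuous_rate` (reciprocal of the mean continuous rating rate,
#' hemispheres averaged arithmetically before division) and
#' `threshold_rate` (mean crossover threshold over raters divided by the
#' hemisphere-averaged mean annual hippocampal volume loss), plus their
#' reconciliation ratio. Defaults take the published summaries in
#' [reference_rates()] and [reference_thresholds()] as inputs.
#'
#' @param rates Tibble like [reference_rates()]: `at_group`, `hemisphere`,
#'   `avra_dmta_yr`, `hc_dmm3_yr`.
#' @param thresholds Named numeric vector of per-rater crossover
#'   thresholds (mm^3 magnitudes), averaged arithmetically.
#' @return Tibble: `at_group`, `rating_rate`, `hc_rate`,
#'   `full_score_years`, `threshold_years`, `ratio`.
#' @export
conversion_summary <- function(rates = reference_rates(),
                               thresholds = reference_thresholds()) {
  thr <- mean(abs(thresholds))
  rates |>
    dplyr::group_by(.data$at_group) |>
    dplyr::summarise(rating_rate = mean(.data$avra_dmta_yr),
                     hc_rate = mean(abs(.data$hc_dmm3_yr)),
                     .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      full_score_years = full_score_time(.data$rating_rate),
      threshold_years = threshold_crossing_time(thr, .data$hc_rate),
      ratio = .data$full_score_years / .data$threshold_years
    ) |>
    dplyr::ungroup()
}
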