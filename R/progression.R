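#' Per-subject least-squares annual change
#'
#' Fits an ordinary least-squares line to one subject's measure against age
#' and returns the closed-form slope
#' `sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)`,
#' the average annual change of the measure. Pairs with a missing value
#' are dropped.
#'
#' @param ages Ages at scan in years.
#' @param values Measure values (same length as `ages`).
#' @return A list of class `slope_estimate`: `slope` (units/year),
#'   `intercept` (units at age 0), `n_points`, `baseline_value` (value at
#'   the earliest age).
#' @examples
#' fit_subject_slope(c(70, 72, 74, 76), c(0, 1, 1, 1))$slope # 0.15
#' @export
fit_subject_slope <- function(ages, values) {
  keep <- !is.na(ages) & !is.na(values)
  x <- ages[keep]; y <- values[keep]
  if (length(x) < 2L || length(unique(x)) < 2L) {
    stop("need >= 2 points with distinct ages", call. = FALSE)
  }
  xc <- x - mean(x)
  slope <- sum(xc * (y - mean(y))) / sum(xc^2)
  structure(
    list(slope = slope, intercept = mean(y) - slope * mean(x),
         n_points = length(x), baseline_value = y[which.min(x)]),
    class = "slope_estimate"
  )
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("slope %.4g /year (n = %d, baseline %.4g)\n",
              x$slope, x$n_points, x$baseline_value))
  invisible(x)
}

#' Per-subject slopes for a cohort measure
#'
#' Vectorised [fit_subject_slope()] across a cohort: one ordinary
#' least-squares annual change per subject for the given measure (and
#' hemisphere, for per-hemisphere measures). Subjects with fewer than two
#' non-missing observations are dropped; the dropped count is attached as
#' attribute `n_dropped`. Pass the QC-filtered volume view for volume
#' measures.
#'
#' @param cohort An [mta_cohort()].
#' @param measure Measure identifier as in [independent_spearman()].
#' @param hemisphere `"left"` or `"right"` for per-hemisphere measures.
#' @return Tibble: `subject_id`, `measure`, `hemisphere`, `slope`,
#'   `intercept`, `n_points`, `baseline_value`.
#' @export
subject_slopes <- function(cohort, measure, hemisphere = NULL) {
  mv <- measure_values(cohort, measure, hemisphere) |>
    dplyr::filter(!is.na(.data$value))
  fits <- mv |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      slope = if (dplyr::n() >= 2) {
        sum((.data$age_at_scan - mean(.data$age_at_scan)) *
              (.data$value - mean(.data$value))) /
          sum((.data$age_at_scan - mean(.data$age_at_scan))^2)
      } else NA_real_,
      intercept = mean(.data$value) - .data$slope * mean(.data$age_at_scan),
      baseline_value = .data$value[which.min(.data$age_at_scan)],
      .groups = "drop"
    )
  n_dropped <- sum(is.na(fits$slope))
  out <- fits |>
    dplyr::filter(!is.na(.data$slope)) |>
    dplyr::mutate(measure = measure,
                  hemisphere = hemisphere %||% NA_character_) |>
    dplyr::select("subject_id", "measure", "hemisphere", "slope",
                  "intercept", "n_points", "baseline_value")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Achievable annual-change values of a discrete rating
#'
#' A bounded integer rating followed over a handful of fixed visits can
#' only realise a small set of least-squares slopes. This enumerates the
#' admissible non-decreasing rating sequences over the visit offsets
#' (`single_step`: 0 before, 1 after a single step, or never stepping;
#' `monotone_nondecreasing_max2`: every non-decreasing sequence with
#' values in `{0, 1, 2}`), fits each by OLS, and returns the deduplicated
#' slope set — the resolution limit of rating-based atrophy rates.
#'
#' @param visit_offsets Visit times in years, length >= 2, strictly
#'   increasing.
#' @param pattern `"single_step"` or `"monotone_nondecreasing_max2"`.
#' @param tol Slopes closer than this are considered equal.
#' @return Sorted numeric vector of achievable slopes (always contains 0).
#' @examples
#' enumerate_discrete_slopes(c(0, 2, 4, 6)) # 0, 0.15, 0.2
#' @export
enumerate_discrete_slopes <- function(visit_offsets,
                                      pattern = c("single_step",
                                                  "monotone_nondecreasing_max2"),
                                      tol = 1e-12) {
  pattern <- match.arg(pattern)
  off <- visit_offsets
  if (length(off) < 2L || any(diff(off) <= 0)) {
    stop("visit_offsets must be >= 2 strictly increasing times",
         call. = FALSE)
  }
  k <- length(off)
  seqs <- if (pattern == "single_step") {
    # step to 1 just before visit j (j = 2..k), or never
    c(list(rep(0, k)),
      lapply(2:k, function(j) rep(c(0, 1), c(j - 1, k - j + 1))))
  } else {
    grid <- do.call(expand.grid, rep(list(0:2), k))
    keep <- apply(grid, 1, function(s) all(diff(s) >= 0))
    lapply(which(keep), function(i) as.numeric(grid[i, ]))
  }
  xc <- off - mean(off)
  slopes <- vapply(seqs, function(y) sum(xc * y) / sum(xc^2), 0)
  slopes <- sort(slopes)
  slopes[!duplicated(round(slopes / tol))]
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of statistical comparisons, >= 1.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 66) # 0.000758 (~ 7.6e-4)
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (m < 1 || m != round(m)) stop("m must be an integer >= 1", call. = FALSE)
  alpha / m
}

# Tie-corrected Kruskal-Wallis H.
kw_stat <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  gs <- split(r, groups)
  num <- 12 / (N * (N + 1)) *
    sum(vapply(gs, function(x) length(x) * mean(x)^2, 0)) - 3 * (N + 1)
  tj <- table(values)
  denom <- 1 - sum(tj^3 - tj) / (N^3 - N)
  if (denom <= 0) return(0) # all observations tied
  max(num / denom, 0)
}

# Exact Kruskal-Wallis p by enumerating all assignments of the observed
# values to the group sizes (used for small fixtures where the chi-square
# approximation is poor).
exact_kw_p <- function(values, groups) {
  obs <- kw_stat(values, groups)
  ns <- as.integer(table(groups))
  n <- length(values)
  count <- 0L; total <- 0L
  recurse <- function(avail, sizes, assign) {
    if (length(sizes) == 1L) {
      assign[avail] <- length(ns)
      h <- kw_stat(values, assign)
      total <<- total + 1L
      if (h >= obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    g <- length(ns) - length(sizes) + 1L
    picks <- utils::combn(length(avail), sizes[1])
    for (ci in seq_len(ncol(picks))) {
      a2 <- assign
      a2[avail[picks[, ci]]] <- g
      recurse(avail[-picks[, ci]], sizes[-1], a2)
    }
  }
  recurse(seq_len(n), ns, integer(n))
  count / total
}

# Kruskal-Wallis across groups: chi-square approximation, exact by
# enumeration for total n <= 10.
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(factor(groups))
  h <- kw_stat(values, groups)
  p <- if (length(values) <= 10L) {
    exact_kw_p(values, groups)
  } else {
    stats::pchisq(h, df = nlevels(groups) - 1, lower.tail = FALSE)
  }
  list(H = h, p_value = p)
}

#' Group comparison of per-subject annual-change estimates
#'
#' Summarises per-subject slopes by A/T group — mean, SD and n, plus
#' percent-per-year summaries for volume measures (each subject's slope
#' divided by their baseline value, x100) — and tests the null hypothesis
#' of equal group medians with a tie-corrected Kruskal-Wallis H-test
#' (chi-square approximation; exact by enumeration when 10 or fewer
#' subjects enter). The Bonferroni flag compares the p-value with
#' `alpha / m`.
#'
#' @param slopes Tibble from [subject_slopes()] (one measure).
#' @param subjects Subject table carrying `subject_id`, `at_group`,
#'   `diagnosis` (e.g. `cohort$subjects`).
#' @param stratum Optional `"SCD"` or `"MCI"` to restrict to one clinical
#'   stratum; `NULL` uses the whole cohort.
#' @param alpha,m Family-wise level and number of comparisons for the
#'   Bonferroni flag. `m` is a configured input, not recomputed.
#' @param percent Also report percent-per-year summaries (for volumes).
#' @return A list of class `group_rate_summary`: `summary` tibble,
#'   `kw_h`, `p_value`, `significant_after_bonferroni`, `alpha`, `m`,
#'   `stratum`.
#' @export
group_rate_summary <- function(slopes, subjects, stratum = NULL,
                               alpha = 0.05, m = 66, percent = FALSE) {
  dat <- dplyr::inner_join(slopes, subjects, by = "subject_id")
  if (!is.null(stratum)) dat <- dplyr::filter(dat, .data$diagnosis == stratum)
  dat <- dplyr::mutate(dat, at_group = droplevels(.data$at_group))
  present <- table(dat$at_group)
  if (sum(present > 0) < 2) {
    stop("need >= 2 non-empty groups to compare", call. = FALSE)
  }
  if (any(present == 0)) {
    warning("dropping empty group(s): ",
            paste(names(present)[present == 0], collapse = ", "),
            call. = FALSE)
  }
  summ <- dat |>
    dplyr::group_by(.data$at_group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$slope),
                     sd = stats::sd(.data$slope), .groups = "drop")
  if (percent) {
    pct <- dat |>
      dplyr::mutate(pct = 100 * .data$slope / .data$baseline_value) |>
      dplyr::group_by(.data$at_group) |>
      dplyr::summarise(pct_mean = mean(.data$pct),
                       pct_sd = stats::sd(.data$pct), .groups = "drop")
    summ <- dplyr::left_join(summ, pct, by = "at_group")
  }
  kw <- kruskal_wallis(dat$slope, dat$at_group)
  structure(
    list(summary = summ, kw_h = kw$H, p_value = kw$p_value,
         significant_after_bonferroni =
           kw$p_value < bonferroni_threshold(alpha, m),
         alpha = alpha, m = m, stratum = stratum %||% "all"),
    class = "group_rate_summary"
  )
}

#' @export
print.group_rate_summary <- function(x, ...) {
  cat(sprintf("Group annual-change summary (%s): H = %.3g, p = %.3g%s\n",
              x$stratum, x$kw_h, x$p_value,
              if (x$significant_after_bonferroni) {
                sprintf(" (< %.2g after Bonferroni)", x$alpha / x$m)
              } else ""))
  print(x$summary)
  invisible(x)
}

#' Per-timepoint mean and SD of a measure by subgroup
#'
#' Means and standard deviations of a measure at each visit within each
#' A/T group x clinical stratum cell; empty cells are absent from the
#' table.
#'
#' @inheritParams subject_slopes
#' @return Tibble: `at_group`, `diagnosis`, `visit_index`, `n`, `mean`,
#'   `sd`.
#' @export
timepoint_summary <- function(cohort, measure, hemisphere = NULL) {
  measure_values(cohort, measure, hemisphere) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::inner_join(dplyr::select(cohort$subjects, "subject_id",
                                    "at_group", "diagnosis"),
                      by = "subject_id") |>
    dplyr::group_by(.data$at_group, .data$diagnosis, .data$visit_index) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
}
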