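#' Confusion matrix between two sets of ordinal ratings
#'
#' Cross-tabulates two equal-length integer rating vectors on the 0-4 MTA
#' scale. Pairs with a missing value on either side are dropped.
#'
#' @param ratings_a,ratings_b Integer vectors with values in `{0,...,4}`.
#' @return A 5x5 integer matrix; rows index rater A's score, columns rater
#'   B's.
#' @export
confusion_matrix <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating vectors must have equal length", call. = FALSE)
  }
  keep <- !is.na(ratings_a) & !is.na(ratings_b)
  a <- ratings_a[keep]; b <- ratings_b[keep]
  if (any(a != round(a) | b != round(b) | a < 0 | a > 4 | b < 0 | b > 4)) {
    stop("ratings must be integers in {0,...,4}; round and clip ",
         "continuous ratings before tabulating", call. = FALSE)
  }
  table(factor(a, levels = 0:4), factor(b, levels = 0:4)) |>
    unclass() |>
    matrix(nrow = 5, dimnames = list(a = 0:4, b = 0:4))
}

#' Cohen's weighted kappa for ordinal MTA ratings
#'
#' Chance-corrected agreement between two raters on the five-category MTA
#' scale: `kappa = 1 - sum(w * O) / sum(w * E)` where `O` is the observed
#' proportion matrix, `E` the outer product of its marginals, and `w` the
#' disagreement weights (`linear`: `|i - j| / 4`; `quadratic`:
#' `((i - j) / 4)^2`; `unweighted`: 0/1 disagreement). Pairs with either
#' rating missing are dropped and counted. Continuous automated ratings
#' must be rounded half-away-from-zero and clipped to \[0, 4\] by the
#' caller before use.
#'
#' @param ratings_a,ratings_b Integer vectors in `{0,...,4}`, equal length,
#'   at least 2 usable pairs.
#' @param weighting `"linear"` (default), `"quadratic"` or `"unweighted"`.
#' @return A list of class `kappa_result`: `kappa`, `weighting`, `n_pairs`,
#'   `n_dropped`, `confusion` (5x5 counts), and the Landis-Koch `label`.
#' @examples
#' weighted_kappa(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4))$kappa # 1
#' weighted_kappa(c(0, 1, 2, 3, 4), c(4, 3, 2, 1, 0))$kappa # -0.5
#' @export
weighted_kappa <- function(ratings_a, ratings_b,
                           weighting = c("linear", "quadratic",
                                         "unweighted")) {
  weighting <- match.arg(weighting)
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating vectors must have equal length", call. = FALSE)
  }
  keep <- !is.na(ratings_a) & !is.na(ratings_b)
  n_dropped <- sum(!keep)
  counts <- confusion_matrix(ratings_a[keep], ratings_b[keep])
  n <- sum(counts)
  if (n < 2) stop("need at least 2 usable rating pairs", call. = FALSE)

  d <- abs(outer(0:4, 0:4, `-`)) / 4
  w <- switch(weighting, linear = d, quadratic = d^2, unweighted = (d > 0) * 1)
  O <- counts / n
  E <- outer(rowSums(O), colSums(O))
  kappa <- if (sum(counts) == sum(diag(counts))) {
    1 # perfect agreement, regardless of degenerate marginals
  } else {
    1 - sum(w * O) / sum(w * E)
  }
  structure(
    list(kappa = kappa, weighting = weighting, n_pairs = n,
         n_dropped = n_dropped, confusion = counts,
         label = landis_koch_label(kappa)),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's weighted kappa (%s weights): %.3f [%s], n = %d\n",
              x$weighting, x$kappa, x$label, x$n_pairs))
  invisible(x)
}

#' Landis-Koch interpretation of a kappa value
#'
#' Bins agreement coefficients into the conventional qualitative bands:
#' below 0 poor, \[0, 0.2) slight, \[0.2, 0.4) fair, \[0.4, 0.6) moderate,
#' \[0.6, 0.8) substantial, \[0.8, 1\] almost perfect (half-open on the
#' right).
#'
#' @param kappa Numeric vector in \[-1, 1\].
#' @return Character vector of band labels.
#' @export
landis_koch_label <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < -1 | kappa > 1)) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  labs <- c("poor", "slight", "fair", "moderate", "substantial",
            "almost perfect")
  as.character(cut(kappa, c(-1.000001, 0, 0.2, 0.4, 0.6, 0.8, 1),
                   labels = labs, right = FALSE, include.lowest = TRUE))
}

#' Spearman correlation on one independent observation per subject
#'
#' Repeated scans of one subject are not independent, so cross-measure
#' correlations are computed on exactly one visit per subject: the baseline
#' visit (deterministic, default) or one visit drawn uniformly at random
#' per subject under `seed`. Ranks are averaged over ties and the two-sided
#' p-value comes from the t approximation.
#'
#' @param cohort An [mta_cohort()] (pass the QC-filtered volume view when
#'   correlating volumes).
#' @param x_measure,y_measure Measure identifiers: a rater id, `"hc_vol"`,
#'   `"ilv_vol"`, `"mmse"` or `"adas_dwr"`.
#' @param hemisphere `"left"` or `"right"`, used by per-hemisphere measures.
#' @param selection_rule `"baseline"` or `"random_per_subject"`.
#' @param seed Seed for the random selection rule.
#' @return A list of class `correlation_result`: `rho`, `n`, `p_value`,
#'   `selection_rule`.
#' @export
independent_spearman <- function(cohort, x_measure, y_measure,
                                 hemisphere = "left",
                                 selection_rule = c("baseline",
                                                    "random_per_subject"),
                                 seed = NULL) {
  selection_rule <- match.arg(selection_rule)
  xs <- measure_values(cohort, x_measure, hemisphere)
  ys <- measure_values(cohort, y_measure, hemisphere)
  joint <- dplyr::inner_join(
    dplyr::select(xs, "subject_id", "visit_index", x = "value"),
    dplyr::select(ys, "subject_id", "visit_index", y = "value"),
    by = c("subject_id", "visit_index")
  ) |>
    dplyr::filter(!is.na(.data$x), !is.na(.data$y))
  picked <- if (selection_rule == "baseline") {
    joint |> dplyr::group_by(.data$subject_id) |>
      dplyr::slice_min(.data$visit_index, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  } else {
    if (!is.null(seed)) set.seed(seed)
    joint |> dplyr::group_by(.data$subject_id) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::ungroup()
  }
  if (nrow(picked) < 3) {
    stop("need at least 3 subjects with both measures", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(picked$x, picked$y, method = "spearman", exact = FALSE)
  )
  structure(
    list(rho = unname(ct$estimate), n = nrow(picked),
         p_value = ct$p.value, selection_rule = selection_rule),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, p = %.3g, one %s visit/subject)\n",
              x$rho, x$n, x$p_value, x$selection_rule))
  invisible(x)
}

#' Pairwise agreement and correlation table for a cohort
#'
#' Computes, per hemisphere, the weighted-kappa agreement between every
#' pair of raters (continuous ratings rounded half-away-from-zero and
#' clipped first) and the one-visit-per-subject Spearman correlation of
#' each rater's ratings with hippocampal volume, ventricular volume, MMSE
#' and ADAS delayed word recall. Kappa uses all visits; correlations
#' involving volumes should be computed on the QC-passing view, which is
#' the caller's choice of `cohort`.
#'
#' @param cohort An [mta_cohort()].
#' @param weighting Kappa weighting, see [weighted_kappa()].
#' @param selection_rule,seed Passed to [independent_spearman()].
#' @return Tidy tibble: `measure`, `rater`, `hemisphere`, `metric`
#'   (`"kappa"` or `"rho"`), `value`, `n`.
#' @export
agreement_table <- function(cohort, weighting = "linear",
                            selection_rule = "baseline", seed = NULL) {
  raters <- cohort$raters
  out <- list()
  rating_of <- function(r, h) {
    v <- measure_values(cohort, r, h)
    if (raters$scale_type[raters$rater == r] == "continuous") {
      v$value <- clip(round_half_away(v$value), 0, 4)
    }
    v
  }
  for (h in c("left", "right")) {
    for (i in seq_len(nrow(raters))) {
      for (j in seq_len(nrow(raters))) {
        if (i >= j) next
        a <- rating_of(raters$rater[i], h)
        b <- rating_of(raters$rater[j], h)
        ab <- dplyr::inner_join(a, b, by = c("subject_id", "visit_index"),
                                suffix = c("_a", "_b"))
        k <- weighted_kappa(ab$value_a, ab$value_b, weighting)
        out[[length(out) + 1L]] <- tibble::tibble(
          measure = raters$rater[i], rater = raters$rater[j],
          hemisphere = h, metric = "kappa", value = k$kappa, n = k$n_pairs
        )
      }
      for (m in c("hc_vol", "ilv_vol", "mmse", "adas_dwr")) {
        cr <- independent_spearman(cohort, raters$rater[i], m, h,
                                   selection_rule, seed)
        out[[length(out) + 1L]] <- tibble::tibble(
          measure = m, rater = raters$rater[i], hemisphere = h,
          metric = "rho", value = cr$rho, n = cr$n
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
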