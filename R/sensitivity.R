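#' Baseline-to-follow-up change pairs for one rater
#'
#' Pairs every follow-up image with its subject's baseline (visit 0) scan,
#' per hemisphere: rating change `delta_mta`, volume changes in mm^3 and as
#' percent of the baseline volume, and elapsed time. Pairs missing either
#' volume (e.g. QC-failed images, when the QC-filtered view is supplied)
#' are dropped and counted in attribute `n_dropped`; subjects without a
#' baseline visit are skipped with a warning. Hemispheres contribute
#' separate pairs; pooling them downstream is the default.
#'
#' @param cohort An [mta_cohort()] (the volume view from [qc_filter()] for
#'   volume-complete pairs).
#' @param rater_id Rater whose rating change defines `delta_mta`.
#' @return Tibble of class `delta_pairs`: `subject_id`, `hemisphere`,
#'   `rater`, `visit_index`, `delta_mta`, `delta_hc`, `delta_hc_pct`,
#'   `delta_ilv`, `delta_ilv_pct`, `delta_t`.
#' @export
compute_deltas <- function(cohort, rater_id) {
  stopifnot(rater_id %in% cohort$raters$rater)
  vis <- cohort$visits |>
    dplyr::inner_join(
      dplyr::filter(cohort$ratings, .data$rater == rater_id) |>
        dplyr::select("subject_id", "visit_index", "hemisphere", "mta"),
      by = c("subject_id", "visit_index", "hemisphere")
    )
  base <- vis |>
    dplyr::filter(.data$visit_index == 0L) |>
    dplyr::select("subject_id", "hemisphere", mta0 = "mta",
                  hc0 = "hc_vol_mm3", ilv0 = "ilv_vol_mm3",
                  age0 = "age_at_scan")
  no_base <- setdiff(unique(vis$subject_id), unique(base$subject_id))
  if (length(no_base) > 0L) {
    warning(length(no_base), " subject(s) without a baseline visit skipped",
            call. = FALSE)
  }
  pairs <- vis |>
    dplyr::filter(.data$visit_index > 0L) |>
    dplyr::inner_join(base, by = c("subject_id", "hemisphere")) |>
    dplyr::transmute(
      .data$subject_id, .data$hemisphere, rater = rater_id,
      .data$visit_index,
      delta_mta = .data$mta - .data$mta0,
      delta_hc = .data$hc_vol_mm3 - .data$hc0,
      delta_hc_pct = 100 * (.data$hc_vol_mm3 - .data$hc0) / .data$hc0,
      delta_ilv = .data$ilv_vol_mm3 - .data$ilv0,
      delta_ilv_pct = 100 * (.data$ilv_vol_mm3 - .data$ilv0) / .data$ilv0,
      delta_t = .data$age_at_scan - .data$age0
    )
  complete <- !is.na(pairs$delta_hc) & !is.na(pairs$delta_ilv)
  out <- pairs[complete, ]
  attr(out, "n_dropped") <- sum(!complete)
  class(out) <- c("delta_pairs", class(out))
  out
}

# Scott's-rule bandwidth for a Gaussian kernel (sd * n^(-1/5)).
scott_bandwidth <- function(x) stats::sd(x) * length(x)^(-1 / 5)

#' Kernel densities of volume change per rating-change class
#'
#' Gaussian kernel density estimates of a volume-change variable within
#' each rating-change class (`delta_mta` of 0, +1, +2-or-more; pairs with
#' a decreased rating are excluded and counted). All classes are evaluated
#' on one shared 512-point grid spanning the pooled data plus three
#' maximal bandwidths, and each class carries its empirical prior
#' (class count / retained total). A non-zero class with fewer than
#' `min_class_size` pairs triggers pooling of all increased-rating pairs
#' into a single "1plus" class, with a warning.
#'
#' @param pairs A `delta_pairs` tibble from [compute_deltas()].
#' @param variable One of `"delta_hc"`, `"delta_hc_pct"`, `"delta_ilv"`,
#'   `"delta_ilv_pct"`.
#' @param bandwidth_rule `"scott"` (Gaussian-kernel Scott's rule,
#'   `sd * n^(-1/5)`) or a fixed numeric bandwidth.
#' @param min_class_size Minimum pairs per retained class.
#' @param grid_n Number of evaluation points.
#' @return A list of class `delta_densities`: `grid`, `dens` (named list
#'   of per-class density vectors), `priors`, `counts`, `bandwidths`,
#'   `variable`, `n_negative_excluded`.
#' @export
kde_by_delta_class <- function(pairs, variable = "delta_hc",
                               bandwidth_rule = "scott",
                               min_class_size = 5L, grid_n = 512L) {
  stopifnot(variable %in% c("delta_hc", "delta_hc_pct", "delta_ilv",
                            "delta_ilv_pct"))
  x <- pairs[[variable]]
  dm <- round(pairs$delta_mta)
  keep <- !is.na(x) & !is.na(dm)
  x <- x[keep]; dm <- dm[keep]
  n_neg <- sum(dm < 0)
  x <- x[dm >= 0]; dm <- dm[dm >= 0]
  cls <- ifelse(dm == 0, "0", ifelse(dm == 1, "1", "2"))
  counts <- table(factor(cls, levels = c("0", "1", "2")))
  if (counts[["0"]] < min_class_size) {
    stop("fewer than ", min_class_size, " unchanged-rating pairs",
         call. = FALSE)
  }
  if (any(counts[c("1", "2")] > 0 & counts[c("1", "2")] < min_class_size)) {
    warning("small rating-increase class; pooling all increased-rating ",
            "pairs into one '1plus' class", call. = FALSE)
    cls <- ifelse(dm == 0, "0", "1plus")
  }
  cls <- factor(cls)
  cls <- droplevels(cls[TRUE])
  groups <- split(x, cls)
  groups <- groups[vapply(groups, length, 0L) > 0]
  bw <- vapply(groups, function(g) {
    if (identical(bandwidth_rule, "scott")) scott_bandwidth(g)
    else as.numeric(bandwidth_rule)
  }, 0)
  if (any(!is.finite(bw) | bw <= 0)) {
    stop("degenerate bandwidth; classes need spread or a fixed bandwidth",
         call. = FALSE)
  }
  lo <- min(x) - 3 * max(bw)
  hi <- max(x) + 3 * max(bw)
  grid <- seq(lo, hi, length.out = grid_n)
  dens <- mapply(function(g, b) {
    stats::density(g, bw = b, from = lo, to = hi, n = grid_n)$y
  }, groups, bw, SIMPLIFY = FALSE)
  cnt <- vapply(groups, length, 0L)
  structure(
    list(grid = grid, dens = dens, priors = cnt / sum(cnt), counts = cnt,
         bandwidths = bw, variable = variable,
         n_negative_excluded = n_neg),
    class = "delta_densities"
  )
}

#' @export
print.delta_densities <- function(x, ...) {
  cat(sprintf("<delta_densities> %s: classes %s (n = %s), grid [%.4g, %.4g]\n",
              x$variable, paste(names(x$dens), collapse = "/"),
              paste(x$counts, collapse = "/"),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Volume-change threshold at which a higher rating becomes more likely
#'
#' Compares the prior-weighted density of unchanged-rating pairs,
#' `g0(x) = p0 f0(x)`, with that of increased-rating pairs,
#' `g+(x) = sum(pk fk(x))` over classes k >= 1, and locates the volume
#' change beyond which a follow-up image is more likely to receive a
#' higher rating than the same one. The threshold is the crossing beyond
#' which `g+` exceeds `g0` all the way to the grid edge in the stated
#' direction (toward loss, i.e. more negative, for shrinking structures;
#' toward growth for expanding ones), linearly interpolated between the
#' bracketing grid points. With `weighting = "raw"` the
#' increased-rating classes are pooled into a single density without
#' prior weighting (an unweighted curve crossing).
#'
#' @param densities A `delta_densities` object from [kde_by_delta_class()].
#' @param direction `"loss"` or `"growth"`.
#' @param weighting `"prior"` (default, a posterior-probability crossing)
#'   or `"raw"`.
#' @return A list of class `crossover_threshold`: `threshold` (`NA` if no
#'   crossing, with `crossed = FALSE`), `direction`, `weighting`,
#'   `variable`, `grid`, `g0`, `gplus`.
#' @export
crossover_threshold <- function(densities, direction = c("loss", "growth"),
                                weighting = c("prior", "raw")) {
  direction <- match.arg(direction)
  weighting <- match.arg(weighting)
  stopifnot(inherits(densities, "delta_densities"))
  cls <- names(densities$dens)
  if (!"0" %in% cls || length(cls) < 2L) {
    stop("need both an unchanged class and an increased class", call. = FALSE)
  }
  plus <- setdiff(cls, "0")
  p <- densities$priors
  if (weighting == "prior") {
    g0 <- p[["0"]] * densities$dens[["0"]]
    gplus <- Reduce(`+`, lapply(plus, function(k) p[[k]] * densities$dens[[k]]))
  } else {
    g0 <- densities$dens[["0"]]
    wplus <- p[plus] / sum(p[plus])
    gplus <- Reduce(`+`, lapply(plus, function(k) {
      wplus[[k]] * densities$dens[[k]]
    }))
  }
  grid <- densities$grid
  d <- gplus - g0

  # scan inward from the directional edge: the threshold is the inner end
  # of the maximal run of g+ > g0 anchored at that edge, so that g+ stays
  # greater from the threshold all the way to the grid edge
  ord <- if (direction == "loss") seq_along(grid) else rev(seq_along(grid))
  pos <- d[ord] > 0
  threshold <- NA_real_
  if (pos[1] && !all(pos)) {
    run_end <- which(!pos)[1] - 1L
    b <- ord[run_end]
    nxt <- ord[run_end + 1L] # first point inward where d <= 0
    # linear interpolation of the zero of d between grid[b] and grid[nxt]
    threshold <- grid[b] + (grid[nxt] - grid[b]) *
      (0 - d[b]) / (d[nxt] - d[b])
  }
  structure(
    list(threshold = threshold, crossed = !is.na(threshold),
         direction = direction, weighting = weighting,
         variable = densities$variable, grid = grid, g0 = g0,
         gplus = gplus, priors = p),
    class = "crossover_threshold"
  )
}

#' @export
print.crossover_threshold <- function(x, ...) {
  if (x$crossed) {
    cat(sprintf(
      "crossover (%s, %s-weighted) at %s = %.4g\n",
      x$direction, x$weighting, x$variable, x$threshold
    ))
  } else {
    cat(sprintf("no crossover found for %s (%s direction)\n",
                x$variable, x$direction))
  }
  invisible(x)
}
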