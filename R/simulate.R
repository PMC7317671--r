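#' Configure the synthetic longitudinal cohort generator
#'
#' Full parameterisation of the synthetic memory-clinic cohort. Defaults
#' emulate the study conditions of the motivating six-year cohort: three
#' CSF A/T groups of 54/18/21 subjects aged 60-80 at baseline, four scans
#' at 0/2/4/6 years, a continuous latent MTA trait per hemisphere evolving
#' linearly in time with group-specific baseline and rate distributions
#' (calibrated to the automated-rater summaries in [reference_rates()]),
#' hippocampal volume linear in the latent trait, inferior-lateral-ventricle
#' volume exponential in it (the volume-rating relationship is convex),
#' two biased discretising human raters plus one continuous automated
#' rater, and a per-image segmentation QC failure probability of 33/372.
#'
#' @param group_sizes Named integer vector of subjects per A/T group.
#' @param scd_frac Named numeric vector: fraction of each group carrying a
#'   subjective-cognitive-decline (vs MCI) diagnosis.
#' @param baseline_age List `mean`, `sd` (years) and truncation `range`.
#' @param visit_offsets Scan times in years from baseline, strictly
#'   increasing and starting at 0.
#' @param latent_baseline,latent_rate Per-group `c(mean, sd)` of the latent
#'   continuous MTA trait at baseline (scale units) and of its annual
#'   change (units/year).
#' @param lr_correlation Correlation of the left and right hemisphere
#'   latent baseline and rate draws (a shared subject-level component).
#' @param hc_link Hippocampal volume model: `HC = intercept - slope * m +
#'   noise`, in mm^3 (slope in mm^3 per MTA unit).
#' @param ilv_link Ventricle model: `ILV = v0 * exp(growth * m) + noise`,
#'   floored at 1 mm^3.
#' @param rater_models Per human rater: additive `bias` and `noise_sd` in
#'   latent units, applied before rounding half-away-from-zero and clipping
#'   to \[0, 4\].
#' @param auto_noise_sd Rating noise of the continuous automated rater
#'   (latent units); its output is clipped to \[0, 4\] but not rounded.
#' @param qc_fail_prob Per-image probability of segmentation QC failure.
#' @param csf Per-group `ab` and `ptau` as `c(mean, sd)`; draws are
#'   rejection-sampled to respect the group's side of `cutoffs`.
#' @param cognition Per-group `c(mean, sd)` lists for MMSE and ADAS delayed
#'   word recall baselines and annual rates.
#' @param dementia_threshold Latent MTA level (mean of hemispheres) above
#'   which the dementia-diagnosis flag is set; a simulation convenience,
#'   not a calibrated hazard model.
#' @param cutoffs CSF cut-offs, see [csf_cutoffs()].
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    group_sizes = c(AnTn = 54L, ApTn = 18L, ApTp = 21L),
    scd_frac = c(AnTn = 42 / 54, ApTn = 8 / 18, ApTp = 11 / 21),
    baseline_age = list(mean = 70.1, sd = 5.4, range = c(60, 80)),
    visit_offsets = c(0, 2, 4, 6),
    latent_baseline = list(AnTn = c(1.26, 0.57), ApTn = c(1.40, 0.68),
                           ApTp = c(1.24, 0.61)),
    latent_rate = list(AnTn = c(0.04, 0.04), ApTn = c(0.075, 0.05),
                       ApTp = c(0.12, 0.08)),
    lr_correlation = 0.8,
    hc_link = list(intercept = 4700, slope = 820, noise_sd = 150),
    ilv_link = list(v0 = 150, growth = 1.28, noise_sd = 60),
    rater_models = list(rad1 = list(bias = -0.05, noise_sd = 0.3),
                        rad2 = list(bias = -0.70, noise_sd = 0.3)),
    auto_noise_sd = 0.15,
    qc_fail_prob = 33 / 372,
    csf = list(AnTn = list(ab = c(0.15, 0.03), ptau = c(35.7, 10.9)),
               ApTn = list(ab = c(0.09, 0.02), ptau = c(47.9, 14.4)),
               ApTp = list(ab = c(0.07, 0.02), ptau = c(113.4, 27.6))),
    cognition = list(
      mmse0 = list(AnTn = c(28.57, 1.46), ApTn = c(28.06, 1.75),
                   ApTp = c(27.62, 2.06)),
      mmse_rate = list(AnTn = c(-0.15, 0.47), ApTn = c(-0.49, 0.70),
                       ApTp = c(-1.13, 1.02)),
      adas0 = list(AnTn = c(3.41, 2.39), ApTn = c(5.17, 2.41),
                   ApTp = c(5.38, 3.05)),
      adas_rate = list(AnTn = c(-0.04, 0.38), ApTn = c(0.14, 0.40),
                       ApTp = c(0.39, 0.50))
    ),
    dementia_threshold = 2.5,
    cutoffs = csf_cutoffs(),
    seed = 1L) {
  cfg <- structure(
    list(group_sizes = group_sizes, scd_frac = scd_frac,
         baseline_age = baseline_age, visit_offsets = visit_offsets,
         latent_baseline = latent_baseline, latent_rate = latent_rate,
         lr_correlation = lr_correlation, hc_link = hc_link,
         ilv_link = ilv_link, rater_models = rater_models,
         auto_noise_sd = auto_noise_sd, qc_fail_prob = qc_fail_prob,
         csf = csf, cognition = cognition,
         dementia_threshold = dementia_threshold, cutoffs = cutoffs,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  if (length(cfg$group_sizes) == 0L || any(cfg$group_sizes < 1)) {
    stop("every simulated group must have at least one subject",
         call. = FALSE)
  }
  if (!all(names(cfg$group_sizes) %in% at_group_levels())) {
    stop("group_sizes names must be A/T group labels", call. = FALSE)
  }
  off <- cfg$visit_offsets
  if (length(off) < 2L || off[1] != 0 || any(diff(off) <= 0)) {
    stop("visit_offsets must start at 0 and increase strictly",
         call. = FALSE)
  }
  sds <- c(cfg$baseline_age$sd, vapply(cfg$latent_baseline, `[`, 0, 2),
           vapply(cfg$latent_rate, `[`, 0, 2), cfg$hc_link$noise_sd,
           cfg$ilv_link$noise_sd, cfg$auto_noise_sd,
           vapply(cfg$rater_models, function(r) r$noise_sd, 0))
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (cfg$qc_fail_prob < 0 || cfg$qc_fail_prob > 1) {
    stop("qc_fail_prob must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$lr_correlation < 0 || cfg$lr_correlation > 1) {
    stop("lr_correlation must lie in [0, 1]", call. = FALSE)
  }
  cfg
}

# Correlated left/right draws: shared + hemisphere-specific components.
draw_lr <- function(n, mean, sd, rho) {
  zs <- stats::rnorm(n)
  zl <- stats::rnorm(n)
  zr <- stats::rnorm(n)
  list(left = mean + sd * (sqrt(rho) * zs + sqrt(1 - rho) * zl),
       right = mean + sd * (sqrt(rho) * zs + sqrt(1 - rho) * zr))
}

# Group-conditional CSF draw, rejection-sampled to respect the cut-offs.
draw_csf <- function(n, pars, group, cutoffs) {
  ok <- switch(group,
    AnTn = function(ab, pt) ab >= cutoffs[["ab"]] & pt <= cutoffs[["ptau"]] &
      ab > 0 & pt > 0,
    ApTn = function(ab, pt) ab < cutoffs[["ab"]] & pt <= cutoffs[["ptau"]] &
      ab > 0 & pt > 0,
    ApTp = function(ab, pt) ab < cutoffs[["ab"]] & pt > cutoffs[["ptau"]] &
      ab > 0,
    AnTp = function(ab, pt) ab >= cutoffs[["ab"]] & pt > cutoffs[["ptau"]] &
      ab > 0
  )
  ab <- stats::rnorm(n, pars$ab[1], pars$ab[2])
  pt <- stats::rnorm(n, pars$ptau[1], pars$ptau[2])
  bad <- which(!ok(ab, pt))
  while (length(bad) > 0L) {
    ab[bad] <- stats::rnorm(length(bad), pars$ab[1], pars$ab[2])
    pt[bad] <- stats::rnorm(length(bad), pars$ptau[1], pars$ptau[2])
    bad <- bad[!ok(ab[bad], pt[bad])]
  }
  list(ab = ab, ptau = pt)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a full cohort from a [simulation_config()]: per-subject latent MTA
#' baselines and annual rates (correlated across hemispheres, baselines
#' truncated to \[0, 4\]), linear latent trajectories at the visit offsets,
#' volumes through the configured hippocampal (linear) and ventricular
#' (exponential) links, discretised biased human ratings and a continuous
#' automated rating, group-consistent CSF values, per-image QC flags, and
#' linear-in-time cognition. The result passes [read_cohort()] validation
#' unchanged.
#'
#' @param config A [simulation_config()].
#' @return An [mta_cohort()].
#' @examples
#' cohort <- generate_cohort(simulation_config(
#'   group_sizes = c(AnTn = 4L, ApTn = 3L, ApTp = 3L), seed = 1
#' ))
#' cohort
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  set.seed(config$seed)
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  ids <- sprintf("S%04d", seq_len(n))
  off <- config$visit_offsets
  n_vis <- length(off)

  # deterministic SCD/MCI composition per group
  diagnosis <- character(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    n_scd <- round(length(idx) * config$scd_frac[[g]])
    diagnosis[idx] <- rep(c("SCD", "MCI"),
                          c(n_scd, length(idx) - n_scd))
  }

  age0 <- rtruncnorm(n, config$baseline_age$mean, config$baseline_age$sd,
                     config$baseline_age$range[1], config$baseline_age$range[2])

  ab <- numeric(n); ptau <- numeric(n)
  m0 <- list(left = numeric(n), right = numeric(n))
  rt <- list(left = numeric(n), right = numeric(n))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    csf <- draw_csf(length(idx), config$csf[[g]], g, config$cutoffs)
    ab[idx] <- csf$ab; ptau[idx] <- csf$ptau
    b <- draw_lr(length(idx), config$latent_baseline[[g]][1],
                 config$latent_baseline[[g]][2], config$lr_correlation)
    r <- draw_lr(length(idx), config$latent_rate[[g]][1],
                 config$latent_rate[[g]][2], config$lr_correlation)
    for (h in c("left", "right")) {
      m0[[h]][idx] <- clip(b[[h]], 0, 4)
      rt[[h]][idx] <- r[[h]]
    }
  }

  cg <- config$cognition
  g_par <- function(lst, col) vapply(groups, function(g) lst[[g]][col], 0)
  mmse0 <- stats::rnorm(n, g_par(cg$mmse0, 1), g_par(cg$mmse0, 2))
  mmse_r <- stats::rnorm(n, g_par(cg$mmse_rate, 1), g_par(cg$mmse_rate, 2))
  adas0 <- stats::rnorm(n, g_par(cg$adas0, 1), g_par(cg$adas0, 2))
  adas_r <- stats::rnorm(n, g_par(cg$adas_rate, 1), g_par(cg$adas_rate, 2))

  # long over subject x visit
  sv <- tidyr::expand_grid(i = seq_len(n), visit_index = seq_len(n_vis) - 1L)
  sv$offset <- off[sv$visit_index + 1L]
  sv$qc_pass <- stats::runif(nrow(sv)) >= config$qc_fail_prob
  sv$mmse <- as.integer(clip(round_half_away(mmse0[sv$i] +
                                               mmse_r[sv$i] * sv$offset),
                             0, 30))
  sv$adas_dwr <- pmax(adas0[sv$i] + adas_r[sv$i] * sv$offset, 0)
  m_mean <- (m0$left[sv$i] + rt$left[sv$i] * sv$offset +
               m0$right[sv$i] + rt$right[sv$i] * sv$offset) / 2
  sv$dementia_dx <- m_mean > config$dementia_threshold

  # long over subject x visit x hemisphere
  svh <- tidyr::expand_grid(sv, hemisphere = c("left", "right"))
  m <- ifelse(svh$hemisphere == "left",
              m0$left[svh$i] + rt$left[svh$i] * svh$offset,
              m0$right[svh$i] + rt$right[svh$i] * svh$offset)
  nr <- nrow(svh)
  hc <- config$hc_link$intercept - config$hc_link$slope * m +
    stats::rnorm(nr, 0, config$hc_link$noise_sd)
  ilv <- config$ilv_link$v0 * exp(config$ilv_link$growth * m) +
    stats::rnorm(nr, 0, config$ilv_link$noise_sd)
  visits <- tibble::tibble(
    subject_id = ids[svh$i],
    visit_index = svh$visit_index,
    age_at_scan = age0[svh$i] + svh$offset,
    hemisphere = svh$hemisphere,
    hc_vol_mm3 = pmax(hc, 1),
    ilv_vol_mm3 = pmax(ilv, 1),
    qc_pass = svh$qc_pass,
    mmse = svh$mmse,
    adas_dwr = svh$adas_dwr,
    dementia_dx = svh$dementia_dx
  )

  m_clipped <- clip(m, 0, 4)
  rat <- list(
    avra = clip(m_clipped + stats::rnorm(nr, 0, config$auto_noise_sd), 0, 4)
  )
  for (rn in names(config$rater_models)) {
    rm <- config$rater_models[[rn]]
    rat[[rn]] <- clip(round_half_away(m_clipped + rm$bias +
                                        stats::rnorm(nr, 0, rm$noise_sd)),
                      0, 4)
  }
  ratings <- dplyr::bind_rows(lapply(names(rat), function(rn) {
    tibble::tibble(subject_id = ids[svh$i], visit_index = svh$visit_index,
                   rater = rn, hemisphere = svh$hemisphere, mta = rat[[rn]])
  })) |>
    dplyr::arrange(.data$subject_id, .data$visit_index, .data$rater,
                   .data$hemisphere)

  subjects <- tibble::tibble(
    subject_id = ids, diagnosis = diagnosis,
    csf_ab42_40 = ab, csf_ptau = ptau,
    at_group = factor(groups, levels = at_group_levels())
  )
  raters <- tibble::tibble(
    rater = c("avra", names(config$rater_models)),
    scale_type = c("continuous", rep("discrete", length(config$rater_models)))
  )
  mta_cohort(subjects, visits, ratings, raters)
}

#' Deterministic cohort fixtures
#'
#' Small named cohorts for examples and tests: `tiny` has one subject per
#' A/T group; `paper_like` reproduces the study-scale composition (93
#' subjects, groups 54/18/21); `noise_free` uses the study-scale
#' composition with every noise source, rater bias, and QC failure switched
#' off, so ratings are exact deterministic functions of the latent trait.
#'
#' @param name One of `"tiny"`, `"paper_like"`, `"noise_free"`.
#' @return An [mta_cohort()].
#' @export
make_fixture <- function(name = c("tiny", "paper_like", "noise_free")) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = simulation_config(
      group_sizes = c(AnTn = 1L, ApTn = 1L, ApTp = 1L),
      scd_frac = c(AnTn = 1, ApTn = 0, ApTp = 1),
      seed = 101L
    ),
    paper_like = simulation_config(seed = 42L),
    noise_free = zero_noise_config(seed = 7L)
  )
  generate_cohort(cfg)
}

#' Zero-noise simulation configuration
#'
#' A [simulation_config()] with every random dispersion set to zero (latent
#' baseline/rate spread, volume and rating noise, rater bias, age spread,
#' cognition spread) and no QC failures. Useful for exactness tests: the
#' automated rating equals the latent trajectory and human ratings equal
#' its rounding.
#'
#' @param seed Seed (retained for interface symmetry; the cohort is
#'   deterministic).
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
zero_noise_config <- function(seed = 7L, ...) {
  zero_sd <- function(lst) lapply(lst, function(p) c(p[1], 0))
  base <- simulation_config()
  simulation_config(
    baseline_age = list(mean = 70.1, sd = 0, range = c(60, 80)),
    latent_baseline = zero_sd(base$latent_baseline),
    latent_rate = zero_sd(base$latent_rate),
    hc_link = list(intercept = 4700, slope = 820, noise_sd = 0),
    ilv_link = list(v0 = 150, growth = 1.28, noise_sd = 0),
    rater_models = list(rad1 = list(bias = 0, noise_sd = 0),
                        rad2 = list(bias = 0, noise_sd = 0)),
    auto_noise_sd = 0,
    qc_fail_prob = 0,
    cognition = lapply(base$cognition, zero_sd),
    seed = seed,
    ...
  )
}
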