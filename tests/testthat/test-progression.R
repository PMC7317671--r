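test_that("per-subject least-squares slopes match the closed form", {
  expect_equal(fit_subject_slope(c(70, 72, 74, 76), c(1, 1, 1, 1))$slope, 0)
  expect_equal(fit_subject_slope(c(70, 72, 74, 76), c(0, 1, 1, 1))$slope, 0.15)
  expect_equal(fit_subject_slope(c(70, 72, 74, 76), c(0, 0, 1, 1))$slope, 0.2)
  f <- fit_subject_slope(c(70, 72, NA, 76), c(3000, 2900, 2800, 2700))
  expect_equal(f$n_points, 3)
  expect_equal(f$baseline_value, 3000)
  expect_error(fit_subject_slope(70, 1), ">= 2 points")
  expect_error(fit_subject_slope(c(70, 70), c(1, 2)), "distinct ages")
})

test_that("slopes are shift-invariant in age and scale-equivariant in value", {
  set.seed(6)
  for (i in 1:5) {
    ages <- cumsum(runif(4, 0.5, 3)) + 60
    vals <- rnorm(4)
    f0 <- fit_subject_slope(ages, vals)
    f_shift <- fit_subject_slope(ages + 7, vals)
    expect_equal(f_shift$slope, f0$slope)
    expect_equal(f_shift$intercept, f0$intercept - 7 * f0$slope)
    expect_equal(fit_subject_slope(ages, 3 * vals)$slope, 3 * f0$slope)
  }
})

test_that("discrete ratings admit only a few annual-change values", {
  expect_equal(enumerate_discrete_slopes(c(0, 2, 4, 6), "single_step"),
               c(0, 0.15, 0.2))
  expect_equal(enumerate_discrete_slopes(c(0, 1), "single_step"), c(0, 1))
  # brute force over all monotone 0/1/2 sequences as the independent oracle
  off <- c(0, 2, 4, 6)
  grids <- expand.grid(rep(list(0:2), 4))
  keep <- apply(grids, 1, function(s) all(diff(s) >= 0))
  oracle <- sort(unique(round(apply(grids[keep, ], 1, function(y) {
    unname(stats::coef(stats::lm(y ~ off))[2])
  }), 10)))
  got <- enumerate_discrete_slopes(off, "monotone_nondecreasing_max2")
  expect_equal(round(got, 10), oracle)
  expect_true(all(c(0, 0.15, 0.2) %in% round(got, 10)))
})

test_that("achievable slopes are bounded and always include zero", {
  set.seed(13)
  for (i in 1:5) {
    off <- sort(c(0, cumsum(runif(3, 0.5, 3))))
    for (p in c("single_step", "monotone_nondecreasing_max2")) {
      s <- enumerate_discrete_slopes(off, p)
      expect_true(0 %in% s)
      max_step <- if (p == "single_step") 1 else 2
      expect_true(all(s >= 0 & s <= max_step / min(diff(off)) + 1e-9))
    }
  }
  expect_error(enumerate_discrete_slopes(0), ">= 2")
})

test_that("Kruskal-Wallis group comparison matches rank arithmetic", {
  subjects <- tibble::tibble(
    subject_id = sprintf("P%d", 1:9), diagnosis = "SCD",
    at_group = factor(rep(c("AnTn", "ApTn", "ApTp"), each = 3),
                      levels = at_group_levels())
  )
  slopes <- tibble::tibble(subject_id = subjects$subject_id,
                           slope = 1:9, baseline_value = 1)
  g <- group_rate_summary(slopes, subjects, m = 1)
  expect_equal(g$kw_h, 7.2) # 12/(9*10) * 3*((2-5)^2 + 0 + (8-5)^2)
  # exact enumeration p: only the 3! fully separated assignments reach H = 7.2
  expect_equal(g$p_value, 6 / (choose(9, 3) * choose(6, 3)), tolerance = 1e-12)

  # identical distributions give H = 0, p = 1
  slopes2 <- tibble::tibble(subject_id = subjects$subject_id,
                            slope = rep(c(1, 2, 3), 3), baseline_value = 1)
  g2 <- group_rate_summary(slopes2, subjects, m = 1)
  expect_equal(g2$kw_h, 0)
  expect_equal(g2$p_value, 1)
})

test_that("large-sample Kruskal-Wallis agrees with the stats implementation", {
  set.seed(77)
  subjects <- tibble::tibble(
    subject_id = sprintf("P%d", 1:60), diagnosis = "SCD",
    at_group = factor(rep(c("AnTn", "ApTn", "ApTp"), each = 20),
                      levels = at_group_levels())
  )
  slopes <- tibble::tibble(
    subject_id = subjects$subject_id,
    slope = round(rnorm(60, rep(c(0, 0.3, 0.8), each = 20)), 1), # with ties
    baseline_value = 1
  )
  g <- group_rate_summary(slopes, subjects, m = 1)
  kt <- stats::kruskal.test(slopes$slope, subjects$at_group)
  expect_equal(g$kw_h, unname(kt$statistic))
  expect_equal(g$p_value, kt$p.value)
})

test_that("group summaries stratify by clinical status and report percent", {
  nf <- make_fixture("noise_free")
  sl <- subject_slopes(nf, "avra", "left")
  g <- group_rate_summary(sl, nf$subjects)
  cfg <- simulation_config()
  expect_equal(g$summary$mean,
               unname(vapply(cfg$latent_rate, `[`, 0, 1)[
                 as.character(g$summary$at_group)]),
               tolerance = 1e-12)
  expect_equal(sum(g$summary$n), 93)
  g_scd <- group_rate_summary(sl, nf$subjects, stratum = "SCD")
  expect_lt(sum(g_scd$summary$n), 93)
  hc <- subject_slopes(nf, "hc_vol", "left")
  gp <- group_rate_summary(hc, nf$subjects, percent = TRUE)
  expect_true(all(c("pct_mean", "pct_sd") %in% names(gp$summary)))
  hc2 <- dplyr::inner_join(hc, nf$subjects, by = "subject_id")
  base_means <- tapply(hc2$baseline_value, as.character(hc2$at_group), mean)
  expect_equal(gp$summary$pct_mean,
               as.numeric(100 * gp$summary$mean /
                            base_means[as.character(gp$summary$at_group)]),
               tolerance = 1e-9)
})

test_that("Bonferroni thresholds follow alpha / m", {
  expect_equal(signif(bonferroni_threshold(0.05, 66), 3), 7.58e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(1.5, 2), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m must")
})

test_that("timepoint summaries track the configured trajectories", {
  nf <- make_fixture("noise_free")
  tp <- timepoint_summary(nf, "avra", "left")
  expect_true(all(tp$sd < 1e-12)) # zero within-cell spread without noise
  cfg <- simulation_config()
  for (g in c("AnTn", "ApTn", "ApTp")) {
    m <- tp$mean[tp$at_group == g & tp$diagnosis == "SCD"]
    expect_equal(unname(diff(m) / diff(cfg$visit_offsets)),
                 rep(cfg$latent_rate[[g]][1], 3), tolerance = 1e-12)
  }
  tiny <- make_fixture("tiny")
  tp2 <- timepoint_summary(tiny, "rad1", "left")
  expect_equal(nrow(tp2), 3 * 4) # 3 occupied group x stratum cells, 4 visits
})
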