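test_that("delta pairs difference every follow-up against baseline", {
  tr <- list(
    A = list(ages = c(70, 72, 74, 76), mta = c(1, 1, 2, 2),
             hc = c(3000, 2762, 2600, 2500), ilv = c(700, 800, 900, 1000)),
    B = list(ages = c(68, 70), mta = c(0, 1),
             hc = c(3600, 3500), ilv = c(600, 700))
  )
  p <- compute_deltas(cohort_from_traj(tr), "rad1")
  expect_equal(nrow(p), (3 + 1) * 2) # follow-ups x hemispheres
  a1 <- p[p$subject_id == "A" & p$visit_index == 1 &
            p$hemisphere == "left", ]
  expect_equal(a1$delta_mta, 0)
  expect_equal(a1$delta_hc, -238)
  expect_equal(a1$delta_hc_pct, 100 * (-238) / 3000)
  expect_equal(a1$delta_t, 2)
  a2 <- p[p$subject_id == "A" & p$visit_index == 2 &
            p$hemisphere == "left", ]
  expect_equal(a2$delta_mta, 1)
})

test_that("QC-failed pairs are dropped and missing baselines skipped", {
  tr <- list(
    A = list(ages = c(70, 72, 74, 76), mta = c(1, 1, 2, 2),
             hc = c(3000, 2762, 2600, 2500), ilv = c(700, 800, 900, 1000))
  )
  qc <- list(A = c(TRUE, FALSE, TRUE, TRUE))
  co <- cohort_from_traj(tr, qc)
  views <- qc_filter(co)
  p <- compute_deltas(views$volume, "rad1")
  expect_equal(nrow(p), 2 * 2) # visit 1 dropped in the volume view
  # baseline failing QC leaves no pairable baseline
  qc2 <- list(A = c(FALSE, TRUE, TRUE, TRUE))
  expect_warning(p2 <- compute_deltas(qc_filter(cohort_from_traj(tr, qc2))$volume,
                                      "rad1"),
                 "without a baseline")
  expect_equal(nrow(p2), 0)
})

test_that("per-class kernel densities integrate to one on the shared grid", {
  set.seed(33)
  x <- rnorm(1e4)
  pairs <- tibble::tibble(delta_mta = 0L, delta_hc = x, delta_hc_pct = x,
                          delta_ilv = x, delta_ilv_pct = x)
  pairs$delta_mta[1:5000] <- 1L # two classes drawn from the same density
  kd <- kde_by_delta_class(pairs, "delta_hc")
  dx <- diff(kd$grid[1:2])
  for (k in names(kd$dens)) {
    expect_equal(sum(kd$dens[[k]]) * dx, 1, tolerance = 0.01)
    expect_lt(abs(kd$grid[which.max(kd$dens[[k]])]), 0.1)
  }
  expect_equal(sum(kd$priors), 1)
  # identical class data give identical curves
  pairs2 <- tibble::tibble(delta_mta = rep(c(0L, 1L), each = 100),
                           delta_hc = rep(rnorm(100), 2),
                           delta_hc_pct = 0, delta_ilv = 0,
                           delta_ilv_pct = 0)
  kd2 <- kde_by_delta_class(pairs2, "delta_hc")
  expect_equal(kd2$dens[["0"]], kd2$dens[["1"]])
})

test_that("negative rating changes are excluded and small classes pooled", {
  set.seed(34)
  pairs <- tibble::tibble(
    delta_mta = c(rep(0L, 20), rep(1L, 20), rep(2L, 3), rep(-1L, 4)),
    delta_hc = rnorm(47), delta_hc_pct = 0, delta_ilv = 0, delta_ilv_pct = 0
  )
  expect_warning(kd <- kde_by_delta_class(pairs, "delta_hc"), "pooling")
  expect_equal(names(kd$dens), c("0", "1plus"))
  expect_equal(kd$n_negative_excluded, 4)
  expect_equal(unname(kd$counts), c(20L, 23L))
})

test_that("crossover recovers the analytic weighted crossing of two normals", {
  grid <- seq(-6, 4, length.out = 512)
  f0 <- dnorm(grid); f1 <- dnorm(grid, -2)
  # equal priors and variances: midpoint of the means
  eq <- crossover_threshold(
    analytic_densities(grid, list("0" = f0, "1" = f1), c("0" = .5, "1" = .5)),
    "loss"
  )
  expect_equal(eq$threshold, -1, tolerance = 1e-3)
  # 3:1 priors: solve 0.75 phi(x) = 0.25 phi(x + 2) => x = -(2 + ln 3)/2
  wt <- crossover_threshold(
    analytic_densities(grid, list("0" = f0, "1" = f1),
                       c("0" = .75, "1" = .25)),
    "loss"
  )
  expect_equal(wt$threshold, -(2 + log(3)) / 2, tolerance = 1e-3)
  # raw mode ignores the priors
  raw <- crossover_threshold(
    analytic_densities(grid, list("0" = f0, "1" = f1),
                       c("0" = .75, "1" = .25)),
    "loss", weighting = "raw"
  )
  expect_equal(raw$threshold, -1, tolerance = 1e-3)
  # dominated class: explicit no-crossover result, not an exception
  dom <- crossover_threshold(
    analytic_densities(grid, list("0" = f0, "1" = 0.5 * f0),
                       c("0" = .75, "1" = .25)),
    "loss"
  )
  expect_false(dom$crossed)
  expect_true(is.na(dom$threshold))
})

test_that("threshold sign respects the scan direction", {
  grid <- seq(-5, 5, length.out = 512)
  f0 <- dnorm(grid)
  loss <- crossover_threshold(
    analytic_densities(grid, list("0" = f0, "1" = dnorm(grid, -2)),
                       c("0" = .5, "1" = .5)), "loss"
  )
  growth <- crossover_threshold(
    analytic_densities(grid, list("0" = f0, "1" = dnorm(grid, 2)),
                       c("0" = .5, "1" = .5)), "growth"
  )
  expect_lt(loss$threshold, 0)
  expect_gt(growth$threshold, 0)
})

test_that("KDE crossover converges to the analytic crossing at large n", {
  set.seed(123)
  n <- 1e5
  cls <- runif(n) < 0.25
  x <- ifelse(cls, rnorm(n, -2, 1), rnorm(n, 0, 1))
  pairs <- tibble::tibble(delta_mta = as.integer(cls), delta_hc = x,
                          delta_hc_pct = x, delta_ilv = x, delta_ilv_pct = x)
  ct <- crossover_threshold(kde_by_delta_class(pairs, "delta_hc"), "loss")
  expect_equal(ct$threshold, -(2 + log(3)) / 2, tolerance = 0.05)
})

test_that("rater noise widens the unchanged-rating density", {
  sd0_for <- function(noise, seed) {
    cfg <- simulation_config(
      group_sizes = c(AnTn = 54L, ApTn = 18L, ApTp = 21L) * 4L,
      rater_models = list(rad1 = list(bias = -0.05, noise_sd = noise),
                          rad2 = list(bias = -0.7, noise_sd = noise)),
      seed = seed
    )
    p <- suppressWarnings(
      compute_deltas(qc_filter(generate_cohort(cfg))$volume, "rad1")
    )
    list(sd0 = sd(p$delta_hc[p$delta_mta == 0]),
         thr = crossover_threshold(
           suppressWarnings(kde_by_delta_class(p, "delta_hc")), "loss"
         )$threshold)
  }
  for (s in c(11L, 12L)) {
    lo <- sd0_for(0.15, s)
    hi <- sd0_for(0.6, s)
    expect_gt(hi$sd0, lo$sd0)
    # the crossover responds to the rating-noise level
    expect_false(isTRUE(all.equal(lo$thr, hi$thr)))
  }
})
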