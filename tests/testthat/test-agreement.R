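test_that("weighted kappa matches hand-computed 5x5 evaluations", {
  expect_equal(weighted_kappa(0:4, 0:4)$kappa, 1)
  # full reversal, linear weights: sum(wO) = 0.6, sum(wE) = 0.4
  expect_equal(weighted_kappa(0:4, 4:0, "linear")$kappa, -0.5)
  # a constant rater carries no chance-corrected information
  expect_equal(weighted_kappa(c(2, 2, 2, 2), c(0, 1, 2, 3), "linear")$kappa, 0)
})

test_that("kappa is symmetric, NA pairs are dropped, errors are raised", {
  set.seed(8)
  for (i in 1:5) {
    a <- sample(0:4, 30, replace = TRUE)
    b <- pmin(pmax(a + sample(-1:1, 30, replace = TRUE), 0), 4)
    for (w in c("linear", "quadratic", "unweighted")) {
      expect_equal(weighted_kappa(a, b, w)$kappa,
                   weighted_kappa(b, a, w)$kappa)
    }
  }
  k <- weighted_kappa(c(0, 1, NA, 3), c(0, 1, 2, 3))
  expect_equal(k$n_pairs, 3)
  expect_equal(k$n_dropped, 1)
  expect_error(weighted_kappa(0:3, 0:4), "equal length")
  expect_error(weighted_kappa(c(1, NA), c(NA, 1)), "at least 2")
  expect_error(weighted_kappa(c(0, 5), c(0, 1)), "integers in")
  expect_error(weighted_kappa(c(0, 1.5), c(0, 1)), "integers in")
})

test_that("only unweighted kappa is invariant to category permutation", {
  a <- c(0, 0, 1, 2, 3, 4, 4, 2, 1, 3)
  b <- c(0, 1, 1, 2, 4, 4, 3, 2, 0, 3)
  # swap categories 0 <-> 4 and 1 <-> 3 (distance-breaking relabel 0->4 etc.)
  relab <- function(x) c(4, 0, 2, 3, 1)[x + 1]
  expect_equal(weighted_kappa(a, b, "unweighted")$kappa,
               weighted_kappa(relab(a), relab(b), "unweighted")$kappa)
  expect_false(isTRUE(all.equal(
    weighted_kappa(a, b, "linear")$kappa,
    weighted_kappa(relab(a), relab(b), "linear")$kappa
  )))
})

test_that("quadratic weights forgive near-miss raters more than linear", {
  set.seed(15)
  lat <- rnorm(4000, 2, 1)
  a <- pmin(pmax(round(lat + rnorm(4000, 0, 0.5)), 0), 4)
  b <- pmin(pmax(round(lat + rnorm(4000, 0, 0.5)), 0), 4)
  expect_gt(weighted_kappa(a, b, "quadratic")$kappa,
            weighted_kappa(a, b, "linear")$kappa)
})

test_that("noise-free equal-bias raters agree perfectly", {
  nf <- make_fixture("noise_free")
  wide <- nf$ratings |>
    tidyr::pivot_wider(names_from = rater, values_from = mta)
  expect_equal(weighted_kappa(wide$rad1, wide$rad2)$kappa, 1)
})

test_that("agreement bands follow the conventional half-open intervals", {
  expect_equal(landis_koch_label(0.30), "fair")
  expect_equal(landis_koch_label(0.61), "substantial")
  expect_equal(landis_koch_label(0.40), "moderate") # right-open boundary
  expect_equal(landis_koch_label(c(-0.2, 0, 0.2, 0.8, 1)),
               c("poor", "slight", "fair", "almost perfect", "almost perfect"))
  expect_error(landis_koch_label(1.2), "\\[-1, 1\\]")
})

test_that("confusion matrices conserve the score histograms", {
  m <- confusion_matrix(0:4, 0:4)
  expect_equal(unname(diag(m)), rep(1L, 5))
  expect_equal(sum(m), 5)
  m2 <- confusion_matrix(c(0, 0), c(1, 2))
  expect_equal(m2["0", "1"], 1L, ignore_attr = TRUE)
  expect_equal(m2["0", "2"], 1L, ignore_attr = TRUE)
  set.seed(2)
  a <- sample(0:4, 50, TRUE); b <- sample(0:4, 50, TRUE)
  m3 <- confusion_matrix(a, b)
  expect_equal(unname(rowSums(m3)), unname(tabulate(a + 1, 5)))
  expect_equal(unname(colSums(m3)), unname(tabulate(b + 1, 5)))
})

test_that("independent correlations use one visit per subject", {
  co <- cohort_from_xy(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5))
  r <- independent_spearman(co, "mmse", "adas_dwr")
  expect_equal(r$rho, 0.8) # 1 - 6 * sum(d^2 = 4) / (5 * 24)
  expect_equal(r$n, 5)
  r_up <- independent_spearman(cohort_from_xy(1:6, (1:6)^2), "mmse", "adas_dwr")
  expect_equal(r_up$rho, 1)
  r_dn <- independent_spearman(cohort_from_xy(1:6, -(1:6)^3), "mmse", "adas_dwr")
  expect_equal(r_dn$rho, -1)
  expect_error(independent_spearman(cohort_from_xy(1:2, 2:1),
                                    "mmse", "adas_dwr"), "at least 3")
  # random selection rule is reproducible under a seed
  pl <- make_fixture("paper_like")
  s1 <- independent_spearman(pl, "avra", "hc_vol", "left",
                             "random_per_subject", seed = 5)
  s2 <- independent_spearman(pl, "avra", "hc_vol", "left",
                             "random_per_subject", seed = 5)
  expect_equal(s1$rho, s2$rho)
  expect_lt(s1$rho, 0) # ratings anticorrelate with hippocampal volume
})

test_that("the agreement table covers rater pairs and measures per hemisphere", {
  co <- generate_cohort(simulation_config(
    group_sizes = c(AnTn = 10L, ApTn = 8L, ApTp = 8L), seed = 2L
  ))
  tab <- agreement_table(co)
  expect_equal(sort(unique(tab$metric)), c("kappa", "rho"))
  # 3 rater pairs x 2 hemispheres kappas; 3 raters x 4 measures x 2 hemis rhos
  expect_equal(sum(tab$metric == "kappa"), 6)
  expect_equal(sum(tab$metric == "rho"), 24)
  expect_true(all(abs(tab$value) <= 1))
})
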