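# Shared builders for small hand-made cohorts. Generated fixtures come from
# make_fixture(); these helpers construct minimal cohorts with fully
# controlled values.

# One-visit cohort carrying arbitrary per-subject mmse / adas values, for
# correlation tests on known vectors.
cohort_from_xy <- function(x, y) {
  n <- length(x)
  ids <- sprintf("P%02d", seq_len(n))
  subjects <- tibble::tibble(
    subject_id = ids, diagnosis = "SCD",
    csf_ab42_40 = 0.15, csf_ptau = 35,
    at_group = factor("AnTn", levels = at_group_levels())
  )
  visits <- tidyr::expand_grid(subject_id = ids,
                               hemisphere = c("left", "right")) |>
    dplyr::mutate(visit_index = 0L, age_at_scan = 70,
                  hc_vol_mm3 = 3500, ilv_vol_mm3 = 800, qc_pass = TRUE,
                  mmse = as.integer(x[match(subject_id, ids)]),
                  adas_dwr = y[match(subject_id, ids)],
                  dementia_dx = FALSE)
  ratings <- visits |>
    dplyr::transmute(subject_id, visit_index, rater = "rad1", hemisphere,
                     mta = 1)
  mta_cohort(subjects, visits, ratings,
             tibble::tibble(rater = "rad1", scale_type = "discrete"))
}

# Longitudinal cohort with explicit per-visit ratings and volumes for one
# rater and one set of subjects; `traj` is a list per subject with fields
# mta (vector per visit), hc, ilv (vectors), ages.
cohort_from_traj <- function(traj, qc = NULL) {
  ids <- names(traj)
  subjects <- tibble::tibble(
    subject_id = ids, diagnosis = "SCD",
    csf_ab42_40 = 0.15, csf_ptau = 35,
    at_group = factor("AnTn", levels = at_group_levels())
  )
  rows <- lapply(ids, function(id) {
    tr <- traj[[id]]
    k <- length(tr$ages)
    tidyr::expand_grid(visit_index = seq_len(k) - 1L,
                       hemisphere = c("left", "right")) |>
      dplyr::mutate(subject_id = id,
                    age_at_scan = tr$ages[visit_index + 1L],
                    hc_vol_mm3 = tr$hc[visit_index + 1L],
                    ilv_vol_mm3 = tr$ilv[visit_index + 1L],
                    qc_pass = if (is.null(qc)) TRUE else
                      qc[[id]][visit_index + 1L],
                    mmse = 28L, adas_dwr = 4, dementia_dx = FALSE,
                    mta = tr$mta[visit_index + 1L])
  })
  long <- dplyr::bind_rows(rows)
  visits <- dplyr::select(long, -"mta")
  ratings <- dplyr::transmute(long, subject_id, visit_index, rater = "rad1",
                              hemisphere, mta)
  mta_cohort(subjects, visits, ratings,
             tibble::tibble(rater = "rad1", scale_type = "discrete"))
}

# Build a delta_densities object from analytic density curves.
analytic_densities <- function(grid, dens, priors, variable = "delta_hc") {
  structure(
    list(grid = grid, dens = dens, priors = priors,
         counts = stats::setNames(rep(10L, length(dens)), names(dens)),
         bandwidths = stats::setNames(rep(1, length(dens)), names(dens)),
         variable = variable, n_negative_excluded = 0L),
    class = "delta_densities"
  )
}
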