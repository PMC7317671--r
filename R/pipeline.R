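#' Configure a full analysis run
#'
#' Collects every tunable of the end-to-end pipeline: the input cohort
#' (a CSV path, or a [simulation_config()] to generate one), CSF cut-offs,
#' kappa weighting, the one-visit-per-subject selection rule, kernel
#' density settings, the multiple-comparison correction, and the output
#' directory. Identical configurations (including `seed`) produce
#' byte-identical numeric outputs.
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param simulation A [simulation_config()] used when `input` is `NULL`;
#'   its seed is replaced by `seed`.
#' @param cutoffs CSF cut-offs, see [csf_cutoffs()].
#' @param kappa_weighting `"linear"`, `"quadratic"` or `"unweighted"`.
#' @param selection_rule `"baseline"` or `"random_per_subject"`.
#' @param kde List: `bandwidth_rule`, `min_class_size`, `grid_n`.
#' @param alpha,m Bonferroni inputs (see [bonferroni_threshold()]).
#' @param out_dir Output directory; created if needed.
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = simulation_config(),
                            cutoffs = csf_cutoffs(),
                            kappa_weighting = "linear",
                            selection_rule = "baseline",
                            kde = list(bandwidth_rule = "scott",
                                       min_class_size = 5L, grid_n = 512L),
                            alpha = 0.05, m = 66L,
                            out_dir = tempfile("mta_run_"), seed = 1L) {
  cfg <- structure(
    list(input = input, simulation = simulation, cutoffs = cutoffs,
         kappa_weighting = kappa_weighting,
         selection_rule = selection_rule, kde = kde, alpha = alpha,
         m = as.integer(m), out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
  diag <- check_config_fields(unclass(cfg))
  if (length(diag$errors) > 0L) stop(diag$errors[1], call. = FALSE)
  cfg
}

check_config_fields <- function(x) {
  errors <- character(); warnings <- character()
  if (!is.null(x$kappa_weighting) &&
      !x$kappa_weighting %in% c("linear", "quadratic", "unweighted")) {
    errors <- c(errors, paste0("kappa_weighting: '", x$kappa_weighting,
                               "' is not one of linear/quadratic/unweighted"))
  }
  if (!is.null(x$selection_rule) &&
      !x$selection_rule %in% c("baseline", "random_per_subject")) {
    errors <- c(errors, paste0("selection_rule: '", x$selection_rule,
                               "' is not one of baseline/random_per_subject"))
  }
  if (!is.null(x$alpha) && (x$alpha <= 0 || x$alpha >= 1)) {
    errors <- c(errors, "alpha: must lie in (0, 1)")
  }
  if (!is.null(x$m) && (x$m < 1 || x$m != round(x$m))) {
    errors <- c(errors, "m: must be an integer >= 1")
  }
  if (!is.null(x$cutoffs) &&
      (!all(c("ab", "ptau") %in% names(x$cutoffs)) ||
         any(x$cutoffs[c("ab", "ptau")] <= 0))) {
    errors <- c(errors, "cutoffs: needs positive 'ab' and 'ptau'")
  }
  if (is.null(x$seed)) {
    warnings <- c(warnings,
                  "seed: absent; a random seed will be drawn and recorded")
  }
  list(errors = errors, warnings = warnings)
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML pipeline configuration and checks its fields, returning
#' pass/fail with per-field messages (e.g. an unknown kappa weighting
#' fails naming the field; a missing seed passes with a warning that one
#' will be drawn and recorded).
#'
#' @param path Path to a YAML configuration.
#' @return A list of class `config_diagnostics`: `ok`, `errors`,
#'   `warnings`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  x <- yaml::read_yaml(path)
  diag <- check_config_fields(x)
  structure(list(ok = length(diag$errors) == 0L, errors = diag$errors,
                 warnings = diag$warnings),
            class = "config_diagnostics")
}

#' @export
print.config_diagnostics <- function(x, ...) {
  cat(if (x$ok) "config OK" else "config INVALID", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Load a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [pipeline_config()]; a `simulation` mapping is passed to
#'   [simulation_config()].
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  diag <- validate_config(path)
  if (!diag$ok) stop("invalid config: ", diag$errors[1], call. = FALSE)
  x <- yaml::read_yaml(path)
  args <- list()
  for (k in c("input", "kappa_weighting", "selection_rule", "alpha", "m",
              "out_dir", "seed")) {
    if (!is.null(x[[k]])) args[[k]] <- x[[k]]
  }
  if (!is.null(x$cutoffs)) args$cutoffs <- unlist(x$cutoffs)
  if (!is.null(x$kde)) args$kde <- utils::modifyList(
    list(bandwidth_rule = "scott", min_class_size = 5L, grid_n = 512L),
    x$kde
  )
  if (!is.null(x$simulation)) {
    sim_args <- x$simulation
    if (!is.null(sim_args$group_sizes)) {
      sim_args$group_sizes <- unlist(sim_args$group_sizes)
    }
    args$simulation <- do.call(simulation_config, sim_args)
  }
  if (is.null(x$seed)) args$seed <- sample.int(1e6, 1)
  do.call(pipeline_config, args)
}

# Mask volume fields of QC-failed images so that volume-dependent stages
# of a full-cohort analysis silently drop them.
mask_failed_volumes <- function(cohort) {
  fail <- cohort$visits |>
    dplyr::group_by(.data$subject_id, .data$visit_index) |>
    dplyr::summarise(fail = any(!.data$qc_pass), .groups = "drop")
  cohort$visits <- cohort$visits |>
    dplyr::left_join(fail, by = c("subject_id", "visit_index")) |>
    dplyr::mutate(
      hc_vol_mm3 = ifelse(.data$fail, NA_real_, .data$hc_vol_mm3),
      ilv_vol_mm3 = ifelse(.data$fail, NA_real_, .data$ilv_vol_mm3)
    ) |>
    dplyr::select(-"fail")
  cohort
}

write_table <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                        \(x) signif(x, 6)))
  readr::write_csv(df, path, progress = FALSE)
  path
}

#' Run the full longitudinal MTA analysis
#'
#' Executes every stage in order — load or simulate the cohort, QC
#' filtering, inter-rater agreement and cross-measure correlation,
#' per-subject slopes and group rate comparisons, per-timepoint
#' summaries, rating-change kernel densities and crossover thresholds,
#' and progression-time estimates — writing one CSV per stage plus a JSON
#' run report and the resolved configuration into `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `run_report`: per-stage counts, the output
#'   `manifest`, package `version` and `seed`. Output files:
#'   `agreement.csv`, `slopes.csv`, `group_rates.csv`,
#'   `timepoint_summary.csv`, `densities.csv`, `thresholds.csv`,
#'   `conversion.csv`, `run_report.json`, `config_resolved.yaml`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  cohort <- if (!is.null(config$input)) {
    read_cohort(config$input, cutoffs = config$cutoffs)
  } else {
    sim <- config$simulation
    sim$seed <- config$seed
    generate_cohort(sim)
  }
  views <- qc_filter(cohort)
  masked <- mask_failed_volumes(views$rating)

  # agreement: kappas on all images, correlations on QC-passing volumes
  agr <- agreement_table(masked, weighting = config$kappa_weighting,
                         selection_rule = config$selection_rule,
                         seed = config$seed)
  write_table(agr, out("agreement.csv"))

  # per-subject slopes and group comparisons
  rater_ids <- cohort$raters$rater
  specs <- rbind(
    expand.grid(measure = c(rater_ids, "hc_vol", "ilv_vol"),
                hemisphere = c("left", "right"),
                stringsAsFactors = FALSE),
    data.frame(measure = c("mmse", "adas_dwr"), hemisphere = NA_character_)
  )
  slopes_all <- list(); rates_all <- list()
  for (i in seq_len(nrow(specs))) {
    ms <- specs$measure[i]; hm <- specs$hemisphere[i]
    src <- if (ms %in% c("hc_vol", "ilv_vol")) masked else cohort
    sl <- subject_slopes(src, ms, if (is.na(hm)) NULL else hm)
    slopes_all[[i]] <- sl
    for (stratum in list(NULL, "SCD", "MCI")) {
      gs <- tryCatch(
        group_rate_summary(sl, cohort$subjects, stratum = stratum,
                           alpha = config$alpha, m = config$m,
                           percent = ms %in% c("hc_vol", "ilv_vol")),
        error = function(e) NULL
      )
      if (is.null(gs)) next
      rates_all[[length(rates_all) + 1L]] <- gs$summary |>
        dplyr::mutate(measure = ms, hemisphere = hm, stratum = gs$stratum,
                      kw_h = gs$kw_h, p_value = gs$p_value,
                      significant_after_bonferroni =
                        gs$significant_after_bonferroni,
                      significance_threshold =
                        bonferroni_threshold(config$alpha, config$m))
    }
  }
  slopes_tbl <- dplyr::bind_rows(slopes_all)
  write_table(slopes_tbl, out("slopes.csv"))
  rates_tbl <- dplyr::bind_rows(rates_all)
  write_table(rates_tbl, out("group_rates.csv"))

  tp <- dplyr::bind_rows(lapply(rater_ids, function(r) {
    dplyr::bind_rows(lapply(c("left", "right"), function(h) {
      timepoint_summary(cohort, r, h) |>
        dplyr::mutate(measure = r, hemisphere = h)
    }))
  }))
  write_table(tp, out("timepoint_summary.csv"))

  # sensitivity: discrete raters, volume-complete pairs, hemispheres pooled
  discrete <- cohort$raters$rater[cohort$raters$scale_type == "discrete"]
  dens_rows <- list(); thr_rows <- list(); n_pairs <- 0L
  sens_spec <- data.frame(
    variable = c("delta_hc", "delta_hc_pct", "delta_ilv", "delta_ilv_pct"),
    direction = c("loss", "loss", "growth", "growth")
  )
  for (r in discrete) {
    pairs <- suppressWarnings(compute_deltas(masked, r))
    n_pairs <- n_pairs + nrow(pairs)
    for (i in seq_len(nrow(sens_spec))) {
      vr <- sens_spec$variable[i]
      kd <- tryCatch(
        suppressWarnings(kde_by_delta_class(
          pairs, vr, bandwidth_rule = config$kde$bandwidth_rule,
          min_class_size = config$kde$min_class_size,
          grid_n = config$kde$grid_n
        )),
        error = function(e) NULL
      )
      if (is.null(kd)) next
      ct <- crossover_threshold(kd, direction = sens_spec$direction[i])
      thr_rows[[length(thr_rows) + 1L]] <- tibble::tibble(
        rater = r, variable = vr, direction = ct$direction,
        threshold = ct$threshold, crossed = ct$crossed,
        n_pairs = sum(kd$counts)
      )
      for (k in names(kd$dens)) {
        dens_rows[[length(dens_rows) + 1L]] <- tibble::tibble(
          rater = r, variable = vr, class = k, prior = kd$priors[[k]],
          x = kd$grid, density = kd$dens[[k]]
        )
      }
    }
  }
  write_table(dplyr::bind_rows(thr_rows), out("thresholds.csv"))
  write_table(dplyr::bind_rows(dens_rows), out("densities.csv"))
  thr_tbl <- dplyr::bind_rows(thr_rows)

  # progression-time estimates from this run's own rates and thresholds
  auto <- cohort$raters$rater[cohort$raters$scale_type == "continuous"][1]
  own_rates <- dplyr::bind_rows(lapply(c("left", "right"), function(h) {
    dplyr::inner_join(subject_slopes(cohort, auto, h),
                      cohort$subjects, by = "subject_id") |>
      dplyr::group_by(.data$at_group) |>
      dplyr::summarise(hemisphere = h, avra_dmta_yr = mean(.data$slope),
                       .groups = "drop")
  }))
  own_hc <- dplyr::bind_rows(lapply(c("left", "right"), function(h) {
    dplyr::inner_join(subject_slopes(masked, "hc_vol", h),
                      cohort$subjects, by = "subject_id") |>
      dplyr::group_by(.data$at_group) |>
      dplyr::summarise(hemisphere = h, hc_dmm3_yr = mean(.data$slope),
                       .groups = "drop")
  }))
  own <- dplyr::inner_join(own_rates, own_hc,
                           by = c("at_group", "hemisphere"))
  hc_thr <- thr_tbl |>
    dplyr::filter(.data$variable == "delta_hc", .data$crossed)
  conv <- if (nrow(hc_thr) > 0L) {
    conversion_summary(own, stats::setNames(abs(hc_thr$threshold),
                                            hc_thr$rater))
  } else {
    conversion_summary(own, reference_thresholds())
  }
  write_table(conv, out("conversion.csv"))

  resolved <- unclass(config)
  resolved$simulation <- if (is.null(config$input)) {
    unclass(config$simulation)
  }
  yaml::write_yaml(resolved, out("config_resolved.yaml"))

  manifest <- c("agreement.csv", "slopes.csv", "group_rates.csv",
                "timepoint_summary.csv", "densities.csv", "thresholds.csv",
                "conversion.csv")
  report <- structure(
    list(
      n_subjects = nrow(cohort$subjects),
      n_images = views$n_images,
      n_qc_failed = views$n_failed,
      n_images_volume_view = views$n_kept,
      n_delta_pairs = n_pairs,
      significance_threshold = bonferroni_threshold(config$alpha, config$m),
      manifest = manifest,
      version = as.character(utils::packageVersion("mtalong")),
      seed = config$seed
    ),
    class = "run_report"
  )
  jsonlite::write_json(unclass(report), out("run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  subjects %d, images %d (%d QC-failed -> %d in volume view)\n",
              x$n_subjects, x$n_images, x$n_qc_failed,
              x$n_images_volume_view))
  cat(sprintf("  delta pairs %d; significance threshold %.3g; seed %d\n",
              x$n_delta_pairs, x$significance_threshold, x$seed))
  cat("  outputs:", paste(x$manifest, collapse = ", "), "\n")
  invisible(x)
}
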