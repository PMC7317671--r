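#' @importFrom rlang .data
NULL

#' A/T biomarker group levels
#'
#' The four CSF biomarker groups obtained by dichotomising the amyloid-beta
#' 42/40 ratio (A) and phosphorylated tau (T): `AnTn` (both normal), `ApTn`
#' (abnormal amyloid only), `ApTp` (both abnormal) and `AnTp` (abnormal tau
#' only, a combination rarely observed in memory-clinic cohorts).
#'
#' @return Character vector of the four group labels, in pathology order.
#' @export
at_group_levels <- function() c("AnTn", "ApTn", "ApTp", "AnTp")

#' Default CSF cut-offs for A/T stratification
#'
#' Amyloid positivity is defined as an A-beta 42/40 ratio strictly below
#' `ab`, tau positivity as p-tau strictly above `ptau` pg/ml. Equality maps
#' to the normal side (strict inequalities).
#'
#' @return Named numeric vector with elements `ab` and `ptau`.
#' @export
csf_cutoffs <- function() c(ab = 0.10, ptau = 72)

cohort_csv_columns <- c(
  "subject_id", "visit_index", "age_at_scan", "diagnosis",
  "csf_ab42_40", "csf_ptau", "rater", "hemisphere", "mta",
  "hc_vol_mm3", "ilv_vol_mm3", "qc_pass", "mmse", "adas_dwr", "dementia_dx"
)

#' Stratify subjects into A/T groups from CSF biomarkers
#'
#' Dichotomises the CSF amyloid-beta 42/40 ratio and phosphorylated tau
#' concentration into the four A/T biomarker groups. A subject is A-positive
#' iff `ab42_40 < cutoffs["ab"]` and T-positive iff `ptau > cutoffs["ptau"]`;
#' values equal to a cut-off therefore fall on the normal side.
#'
#' @param ab42_40 Numeric vector of CSF A-beta 42/40 ratios (positive, finite).
#' @param ptau Numeric vector of CSF p-tau concentrations in pg/ml
#'   (positive, finite).
#' @param cutoffs Named numeric vector with elements `ab` and `ptau`;
#'   defaults to [csf_cutoffs()].
#' @return Factor with levels [at_group_levels()], same length as the inputs.
#' @examples
#' stratify_csf(c(0.15, 0.09, 0.07), c(35.7, 47.9, 113.4))
#' @export
stratify_csf <- function(ab42_40, ptau, cutoffs = csf_cutoffs()) {
  stopifnot(length(ab42_40) == length(ptau))
  if (any(!is.finite(ab42_40)) || any(!is.finite(ptau)) ||
      any(ab42_40 <= 0) || any(ptau <= 0)) {
    stop("CSF values must be positive and finite", call. = FALSE)
  }
  a_pos <- ab42_40 < cutoffs[["ab"]]
  t_pos <- ptau > cutoffs[["ptau"]]
  lab <- ifelse(a_pos,
    ifelse(t_pos, "ApTp", "ApTn"),
    ifelse(t_pos, "AnTp", "AnTn")
  )
  factor(lab, levels = at_group_levels())
}

new_mta_cohort <- function(subjects, visits, ratings, raters) {
  structure(
    list(subjects = subjects, visits = visits, ratings = ratings,
         raters = raters),
    class = "mta_cohort"
  )
}

#' Construct a longitudinal MTA cohort
#'
#' Bundles the three tidy tables describing a longitudinal cohort rated on
#' the ordinal medial temporal atrophy (MTA) scale, and validates their
#' invariants (referential integrity, strictly increasing ages, rating
#' ranges per rater scale type).
#'
#' @param subjects Tibble with one row per subject: `subject_id`,
#'   `diagnosis` ("SCD" or "MCI"), `csf_ab42_40`, `csf_ptau`, `at_group`.
#' @param visits Tibble with one row per subject x visit x hemisphere:
#'   `subject_id`, `visit_index`, `age_at_scan`, `hemisphere`,
#'   `hc_vol_mm3`, `ilv_vol_mm3`, `qc_pass`, `mmse`, `adas_dwr`,
#'   `dementia_dx`.
#' @param ratings Tibble with one row per subject x visit x rater x
#'   hemisphere: `subject_id`, `visit_index`, `rater`, `hemisphere`, `mta`.
#' @param raters Tibble registering each rater: `rater`, `scale_type`
#'   ("discrete" for integer 0-4 human raters, "continuous" for automated
#'   raters producing values in \[0, 4\]).
#' @return An object of class `mta_cohort`.
#' @export
mta_cohort <- function(subjects, visits, ratings, raters) {
  x <- new_mta_cohort(
    tibble::as_tibble(subjects), tibble::as_tibble(visits),
    tibble::as_tibble(ratings), tibble::as_tibble(raters)
  )
  validate_mta_cohort(x)
}

validate_mta_cohort <- function(x) {
  s <- x$subjects; v <- x$visits; r <- x$ratings; reg <- x$raters
  if (anyDuplicated(s$subject_id)) {
    stop("duplicate subject_id in subjects table", call. = FALSE)
  }
  orphan <- setdiff(unique(c(v$subject_id, r$subject_id)), s$subject_id)
  if (length(orphan) > 0L) {
    stop("visits/ratings reference unknown subjects: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  if (!all(v$hemisphere %in% c("left", "right"))) {
    stop("hemisphere must be 'left' or 'right'", call. = FALSE)
  }
  dup_v <- duplicated(v[c("subject_id", "visit_index", "hemisphere")])
  if (any(dup_v)) {
    stop("duplicate (subject, visit, hemisphere) in visits: row ",
         which(dup_v)[1], call. = FALSE)
  }
  dup_r <- duplicated(r[c("subject_id", "visit_index", "rater", "hemisphere")])
  if (any(dup_r)) {
    stop("duplicate (subject, visit, rater, hemisphere) in ratings: row ",
         which(dup_r)[1], call. = FALSE)
  }
  # ages strictly increasing with visit_index within subject
  chk <- v |>
    dplyr::distinct(.data$subject_id, .data$visit_index, .data$age_at_scan) |>
    dplyr::arrange(.data$subject_id, .data$visit_index) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      ok = all(diff(.data$age_at_scan) > 0) &&
        !anyDuplicated(.data$visit_index),
      .groups = "drop"
    )
  if (any(!chk$ok)) {
    stop("age_at_scan must increase strictly with visit_index for subject ",
         chk$subject_id[!chk$ok][1], call. = FALSE)
  }
  if (!all(r$rater %in% reg$rater)) {
    stop("ratings reference unregistered raters", call. = FALSE)
  }
  if (!all(reg$scale_type %in% c("discrete", "continuous"))) {
    stop("rater scale_type must be 'discrete' or 'continuous'", call. = FALSE)
  }
  mta <- r$mta[!is.na(r$mta)]
  disc <- reg$rater[reg$scale_type == "discrete"]
  is_disc <- r$rater %in% disc & !is.na(r$mta)
  bad <- which(!is.na(r$mta) & (r$mta < 0 | r$mta > 4))
  if (length(bad) > 0L) {
    stop("MTA rating outside [0, 4] in ratings row ", bad[1], call. = FALSE)
  }
  bad_int <- which(is_disc & r$mta != round(r$mta))
  if (length(bad_int) > 0L) {
    stop("non-integer rating for discrete rater in ratings row ", bad_int[1],
         call. = FALSE)
  }
  for (col in c("hc_vol_mm3", "ilv_vol_mm3")) {
    vv <- v[[col]]
    if (any(!is.na(vv) & vv <= 0)) {
      stop(col, " must be positive where present", call. = FALSE)
    }
  }
  if (any(!is.na(v$mmse) & (v$mmse < 0 | v$mmse > 30))) {
    stop("mmse must lie in [0, 30]", call. = FALSE)
  }
  if (any(levels(s$at_group) != at_group_levels())) {
    stop("at_group must use at_group_levels()", call. = FALSE)
  }
  x
}

#' @export
print.mta_cohort <- function(x, ...) {
  n_img <- nrow(dplyr::distinct(x$visits, .data$subject_id, .data$visit_index))
  cat("<mta_cohort>\n")
  cat("  subjects:", nrow(x$subjects),
      sprintf("(%s)", paste(sprintf("%s=%d", levels(x$subjects$at_group),
                                    tabulate(x$subjects$at_group, 4)),
                            collapse = ", ")), "\n")
  cat("  images  :", n_img, "(subject x visit)\n")
  cat("  raters  :",
      paste(sprintf("%s[%s]", x$raters$rater,
                    substr(x$raters$scale_type, 1, 4)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a longitudinal cohort from CSV
#'
#' Reads the flat long-format cohort CSV (one row per subject x visit x
#' rater x hemisphere, UTF-8, documented header) and returns a validated
#' [mta_cohort()]. Missing numeric cells become `NA`; the A/T group is
#' derived from the CSF columns via [stratify_csf()]. Malformed headers,
#' duplicate observations, non-increasing ages, or out-of-range ratings
#' raise an error naming the offending row.
#'
#' @param path Path to the cohort CSV.
#' @param cutoffs CSF cut-offs passed to [stratify_csf()].
#' @param rater_scales Optional named character vector mapping rater id to
#'   `"discrete"` or `"continuous"`. When `NULL`, a rater whose observed
#'   ratings are all whole numbers is registered as discrete, otherwise as
#'   continuous.
#' @return An `mta_cohort`.
#' @examples
#' path <- system.file("extdata", "synthetic_cohort_tiny.csv",
#'                     package = "mtalong")
#' read_cohort(path)
#' @export
read_cohort <- function(path, cutoffs = csf_cutoffs(), rater_scales = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    visit_index = readr::col_integer(),
    age_at_scan = readr::col_double(),
    diagnosis = readr::col_character(),
    csf_ab42_40 = readr::col_double(),
    csf_ptau = readr::col_double(),
    rater = readr::col_character(),
    hemisphere = readr::col_character(),
    mta = readr::col_double(),
    hc_vol_mm3 = readr::col_double(),
    ilv_vol_mm3 = readr::col_double(),
    qc_pass = readr::col_logical(),
    mmse = readr::col_integer(),
    adas_dwr = readr::col_double(),
    dementia_dx = readr::col_logical()
  ), show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(cohort_csv_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("malformed header: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0L) {
    stop("could not parse ", path, ": row ", prob$row[1], ", ",
         prob$expected[1], call. = FALSE)
  }
  bad_mta <- which(!is.na(raw$mta) & (raw$mta < 0 | raw$mta > 4))
  if (length(bad_mta) > 0L) {
    stop("MTA rating outside [0, 4] at CSV data row ", bad_mta[1],
         call. = FALSE)
  }

  subjects <- raw |>
    dplyr::distinct(.data$subject_id, .data$diagnosis,
                    .data$csf_ab42_40, .data$csf_ptau)
  if (anyDuplicated(subjects$subject_id)) {
    stop("inconsistent subject-level fields (diagnosis/CSF) for subject ",
         subjects$subject_id[duplicated(subjects$subject_id)][1],
         call. = FALSE)
  }
  if (!all(subjects$diagnosis %in% c("SCD", "MCI"))) {
    stop("diagnosis must be 'SCD' or 'MCI'", call. = FALSE)
  }
  subjects$at_group <- stratify_csf(subjects$csf_ab42_40, subjects$csf_ptau,
                                    cutoffs)
  if (any(subjects$at_group == "AnTp")) {
    warning("cohort contains A-T+ subjects, a CSF combination rarely ",
            "observed in memory-clinic populations", call. = FALSE)
  }

  ratings <- raw |>
    dplyr::select("subject_id", "visit_index", "rater", "hemisphere", "mta")
  if (is.null(rater_scales)) {
    reg <- ratings |>
      dplyr::group_by(rater = .data$rater) |>
      dplyr::summarise(
        scale_type = ifelse(all(.data$mta[!is.na(.data$mta)] ==
                                  round(.data$mta[!is.na(.data$mta)])),
                            "discrete", "continuous"),
        .groups = "drop"
      )
  } else {
    reg <- tibble::tibble(rater = names(rater_scales),
                          scale_type = unname(rater_scales))
  }

  visits <- raw |>
    dplyr::distinct(.data$subject_id, .data$visit_index, .data$age_at_scan,
                    .data$hemisphere, .data$hc_vol_mm3, .data$ilv_vol_mm3,
                    .data$qc_pass, .data$mmse, .data$adas_dwr,
                    .data$dementia_dx)
  dup <- duplicated(visits[c("subject_id", "visit_index", "hemisphere")])
  if (any(dup)) {
    stop("inconsistent visit-level fields for subject ",
         visits$subject_id[dup][1], " visit ", visits$visit_index[dup][1],
         call. = FALSE)
  }
  mta_cohort(subjects, visits, ratings, reg)
}

#' Write a cohort to the flat CSV format
#'
#' Inverse of [read_cohort()]: emits one row per subject x visit x rater x
#' hemisphere at full numeric precision, so that reading the file back
#' reproduces the cohort field for field.
#'
#' @param cohort An `mta_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  long <- cohort$ratings |>
    dplyr::left_join(cohort$visits,
                     by = c("subject_id", "visit_index", "hemisphere")) |>
    dplyr::left_join(
      dplyr::select(cohort$subjects, "subject_id", "diagnosis",
                    "csf_ab42_40", "csf_ptau"),
      by = "subject_id"
    ) |>
    dplyr::select(dplyr::all_of(cohort_csv_columns)) |>
    dplyr::arrange(.data$subject_id, .data$visit_index, .data$rater,
                   .data$hemisphere)
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Split a cohort into QC-filtered views
#'
#' Volume-based analyses use only images that passed segmentation quality
#' control; rating-based analyses keep every image (visual ratings are not
#' discarded on segmentation failure). This returns both views with
#' provenance counts, where an "image" is one subject x visit acquisition
#' (both hemispheres share its QC flag).
#'
#' @param cohort An `mta_cohort` whose visits carry `qc_pass` flags.
#' @return A list of class `mta_cohort_views` with elements `volume` (cohort
#'   restricted to QC-passing visits; subjects with no passing visit are
#'   dropped), `rating` (the full cohort), and counts `n_images`,
#'   `n_failed`, `n_kept`.
#' @export
qc_filter <- function(cohort) {
  imgs <- dplyr::distinct(cohort$visits, .data$subject_id, .data$visit_index,
                          .data$qc_pass)
  img_fail <- imgs |> dplyr::group_by(.data$subject_id, .data$visit_index) |>
    dplyr::summarise(fail = any(!.data$qc_pass), .groups = "drop")
  n_images <- nrow(img_fail)
  n_failed <- sum(img_fail$fail)

  keep_v <- cohort$visits |>
    dplyr::semi_join(dplyr::filter(img_fail, !.data$fail),
                     by = c("subject_id", "visit_index"))
  keep_subjects <- cohort$subjects |>
    dplyr::semi_join(keep_v, by = "subject_id")
  keep_r <- cohort$ratings |>
    dplyr::semi_join(keep_v, by = c("subject_id", "visit_index"))
  volume <- new_mta_cohort(keep_subjects, keep_v, keep_r, cohort$raters)

  structure(
    list(volume = volume, rating = cohort,
         n_images = n_images, n_failed = n_failed,
         n_kept = n_images - n_failed),
    class = "mta_cohort_views"
  )
}

#' @export
print.mta_cohort_views <- function(x, ...) {
  cat("<mta_cohort_views> ", x$n_kept, "/", x$n_images,
      " images pass QC (", x$n_failed, " excluded from volume analyses)\n",
      sep = "")
  invisible(x)
}

# Extract one measure as a tidy (subject_id, visit_index, age_at_scan, value)
# table. Measures: a rater id (per-hemisphere rating), "hc_vol" / "ilv_vol"
# (per-hemisphere volume), or "mmse" / "adas_dwr" (whole-visit). Hemisphere
# is required for per-hemisphere measures and ignored otherwise.
measure_values <- function(cohort, measure, hemisphere = NULL) {
  per_visit <- cohort$visits |>
    dplyr::distinct(.data$subject_id, .data$visit_index, .data$age_at_scan)
  if (measure %in% cohort$raters$rater) {
    stopifnot(!is.null(hemisphere))
    out <- cohort$ratings |>
      dplyr::filter(.data$rater == measure, .data$hemisphere == !!hemisphere) |>
      dplyr::transmute(.data$subject_id, .data$visit_index, value = .data$mta)
  } else if (measure %in% c("hc_vol", "ilv_vol")) {
    stopifnot(!is.null(hemisphere))
    col <- paste0(sub("_vol$", "", measure), "_vol_mm3")
    out <- cohort$visits |>
      dplyr::filter(.data$hemisphere == !!hemisphere) |>
      dplyr::transmute(.data$subject_id, .data$visit_index,
                       value = .data[[col]])
  } else if (measure %in% c("mmse", "adas_dwr")) {
    out <- cohort$visits |>
      dplyr::distinct(.data$subject_id, .data$visit_index,
                      value = .data[[measure]])
  } else {
    stop("unknown measure: ", measure, call. = FALSE)
  }
  dplyr::inner_join(out, per_visit, by = c("subject_id", "visit_index"))
}
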