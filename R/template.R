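# Age/sex matching, voxel-wise mean/SD normal templates, and z-score atrophy
# maps — the normative-mapping core.

#' Select age- and sex-matched normal subjects
#'
#' Retains exactly the cohort rows with the same sex and an integer age
#' within `age_window` years of the target age, inclusive on both bounds.
#' Input order is preserved; an empty result is valid.
#'
#' @param cohort cohort metadata `data.frame` (see [read_cohort_table()]).
#' @param age target integer age in years.
#' @param sex `"female"` or `"male"` (aliases accepted).
#' @param age_window half-width of the age window in years (default 2).
#' @return the matching subset of `cohort`.
#' @export
match_subjects <- function(cohort, age, sex, age_window = 2) {
  sex <- normalize_sex(sex)
  keep <- cohort$sex == sex & abs(cohort$age - age) <= age_window
  cohort[keep, , drop = FALSE]
}

#' Build a voxel-wise mean/SD normal template
#'
#' Voxel-wise arithmetic mean and sample standard deviation (n - 1
#' denominator; see `sd_denominator`) over at least two volumes sharing one
#' grid, each subject contributing once.
#'
#' @param volumes list of [gm_volume()] on a common grid with unique
#'   subject ids.
#' @param sex,age_center,age_window matching criteria recorded with the
#'   template (metadata only).
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"` (population).
#' @return an object of class `normal_template` with fields `mean`, `sd`,
#'   `n_subjects`, `subject_ids`, `voxel_size` and the matching criteria.
#' @export
build_template <- function(volumes, sex = NA_character_, age_center = NA_integer_,
                           age_window = 2, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  n <- length(volumes)
  if (n < 2L) an_stop("at least 2 volumes are required for a template", "too_few")
  ids <- vapply(volumes, function(v) v$subject_id, character(1))
  if (anyDuplicated(ids))
    an_stop(sprintf("duplicate subject(s) in template: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "duplicate_id")
  for (v in volumes[-1]) stopifnot_same_grid(volumes[[1]], v)
  d <- dim(volumes[[1]]$values)
  M <- vapply(volumes, function(v) as.vector(v$values), numeric(prod(d)))
  mu <- rowMeans(M)
  denom <- if (sd_denominator == "n-1") n - 1 else n
  sdv <- sqrt(rowSums((M - mu)^2) / denom)
  structure(list(mean = array(mu, d), sd = array(sdv, d), n_subjects = n,
                 subject_ids = ids, sex = sex, age_center = age_center,
                 age_window = age_window,
                 voxel_size = volumes[[1]]$voxel_size),
            class = "normal_template")
}

#' Compute a z-score atrophy map
#'
#' z = (patient - template mean) / template SD at voxels where the template
#' SD exceeds `epsilon`; other voxels are marked invalid (z set to 0, never
#' infinite) and excluded from all downstream spatial statistics.
#'
#' @param patient a [gm_volume()] on the template grid.
#' @param template a [build_template()] result.
#' @param epsilon positive SD floor, a.u. (default 1e-6); suppresses
#'   division blow-ups in zero-variance background voxels.
#' @return an object of class `zmap` with fields `z` (3D array), `valid`
#'   (3D logical), `patient_id`, `template_n`.
#' @export
compute_zmap <- function(patient, template, epsilon = 1e-6) {
  stopifnot(inherits(patient, "gm_volume"), inherits(template, "normal_template"))
  if (epsilon <= 0) an_stop("epsilon must be > 0", "spec")
  stopifnot_same_grid(patient, template, "patient and template")
  valid <- template$sd > epsilon
  z <- array(0, dim(template$mean))
  z[valid] <- (patient$values[valid] - template$mean[valid]) / template$sd[valid]
  structure(list(z = z, valid = valid, patient_id = patient$subject_id,
                 template_n = template$n_subjects,
                 voxel_size = patient$voxel_size),
            class = "zmap")
}
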