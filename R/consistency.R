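# Template-subsampling consistency experiment: repeated random draws of
# age/sex-matched normal subjects, across-repeat voxel-wise SD of the
# z-score maps, and its spatial mean as a function of template size.

#' Experiment configuration
#'
#' Defaults mirror the full-scale study design: template sizes 3 to 100, 100
#' random repeats per size, an age window of +/- 2 years, and eligibility
#' requiring at least 100 matched subjects in the pool; scale `n_max`,
#' `repeats` and `min_pool` down for desk-scale runs.
#'
#' @param n_min,n_max smallest/largest template size (subjects).
#' @param repeats random template draws per size (>= 2).
#' @param age_window matching half-width, years.
#' @param min_pool matched-pool size required for a patient to be eligible;
#'   must be >= `n_max`.
#' @param epsilon template-SD validity floor, a.u.
#' @param seed base seed; each (patient, template size) pair gets an
#'   independent derived substream, so adding patients or reordering sizes
#'   does not perturb other draws.
#' @param mask_frac threshold (fraction of maximum) for the automatic brain
#'   mask derived from the matched pool's mean volume.
#' @param brain_mask optional explicit [brain_mask()] overriding the
#'   automatic one.
#' @param knee_smoothing smoothing for [find_knee()] (`NULL` = automatic).
#' @param knee_threshold minimal normalized chord distance to declare a knee.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_min = 3, n_max = 100, repeats = 100,
                              age_window = 2, min_pool = 100, epsilon = 1e-6,
                              seed = 1L, mask_frac = 0.05, brain_mask = NULL,
                              knee_smoothing = NULL, knee_threshold = 0.01) {
  if (n_min < 2 || n_min > n_max) an_stop("need 2 <= n_min <= n_max", "config")
  if (repeats < 2) an_stop("repeats must be >= 2", "config")
  if (min_pool < n_max) an_stop("min_pool must be >= n_max", "config")
  if (epsilon <= 0) an_stop("epsilon must be > 0", "config")
  structure(list(n_min = as.integer(n_min), n_max = as.integer(n_max),
                 repeats = as.integer(repeats), age_window = age_window,
                 min_pool = as.integer(min_pool), epsilon = epsilon,
                 seed = as.integer(seed), mask_frac = mask_frac,
                 brain_mask = brain_mask, knee_smoothing = knee_smoothing,
                 knee_threshold = knee_threshold),
            class = "experiment_config")
}

#' A patient case for the consistency experiment
#'
#' @param volume the patient's [gm_volume()].
#' @param age integer age in years.
#' @param sex `"female"` or `"male"`.
#' @param id identifier; defaults to the volume's subject id.
#' @return an object of class `patient_case`.
#' @export
patient_case <- function(volume, age, sex, id = volume$subject_id) {
  stopifnot(inherits(volume, "gm_volume"))
  structure(list(volume = volume, age = as.integer(age),
                 sex = normalize_sex(sex), id = as.character(id)),
            class = "patient_case")
}

# Independent substream seed per (patient, template size). Deterministic
# arithmetic hash; all intermediates stay well below 2^53 and the result
# below 2^31.
.substream_seed <- function(seed, patient_id, n) {
  h <- 0
  for (ch in utf8ToInt(as.character(patient_id))) h <- (h * 31 + ch) %% 1000003
  as.integer(((seed %% 65011) * 33029 + h * 1009 + (n %% 65011) * 2003) %% 2147483629)
}

#' Draw template subjects at random from the matched pool
#'
#' `n` distinct subjects sampled uniformly without replacement (within one
#' repeat; subjects may recur across repeats). Draws from the session RNG
#' stream.
#'
#' @param pool a cohort `data.frame` or a vector of subject ids.
#' @param n number of subjects to draw.
#' @return an object of the same kind as `pool` with `n` entries.
#' @export
draw_template_subjects <- function(pool, n) {
  size <- if (is.data.frame(pool)) nrow(pool) else length(pool)
  if (size < n)
    an_stop(sprintf("pool of %d subjects is too small to draw %d", size, n),
            "pool_too_small")
  # a template is an unordered subject set: return draws in stable pool
  # order, which also makes downstream reductions order-independent
  idx <- sort.int(sample.int(size, n))
  if (is.data.frame(pool)) pool[idx, , drop = FALSE] else pool[idx]
}

#' Voxel-wise SD of z-scores across repeats
#'
#' Sample SD (n - 1) per voxel over a stack of z-maps on one grid. Voxels are
#' retained only where every repeat's map is valid (intersection rule), so
#' the SD is never computed over a partially defined sample.
#'
#' @param zmaps list of [compute_zmap()] results (>= 2).
#' @return list with `sd` (3D array; 0 outside the combined validity) and
#'   `valid` (3D logical intersection).
#' @export
sd_across_repeats <- function(zmaps) {
  if (length(zmaps) < 2L) an_stop("need at least 2 z-maps", "too_few")
  for (z in zmaps[-1]) stopifnot_same_grid(zmaps[[1]], z, "z-maps")
  d <- dim(zmaps[[1]]$z)
  Z <- vapply(zmaps, function(z) as.vector(z$z), numeric(prod(d)))
  valid <- Reduce(`&`, lapply(zmaps, function(z) z$valid))
  mu <- rowMeans(Z)
  sdv <- sqrt(rowSums((Z - mu)^2) / (length(zmaps) - 1))
  sdv[!as.vector(valid)] <- 0
  list(sd = array(sdv, d), valid = valid)
}

#' Spatial mean of a voxel field over a mask
#'
#' @param field 3D array (e.g. the SD field from [sd_across_repeats()]).
#' @param mask [brain_mask()] or 3D logical array; must select at least one
#'   voxel.
#' @return scalar arithmetic mean.
#' @export
spatial_mean <- function(field, mask) {
  if (inherits(mask, "brain_mask")) mask <- mask$include
  if (!identical(dim(field), dim(mask)))
    an_stop("field and mask grids differ", "grid_mismatch")
  if (!any(mask)) an_stop("mask selects no voxels", "empty_mask")
  mean(field[mask])
}

# Core loop on mask-restricted vectors: patient_vec (V), pool_mat (V x P).
# Template mean/SD use the two-pass centered form so identical draws yield
# exactly zero across-repeat SD.
.consistency_core <- function(patient_vec, pool_mat, n, repeats, epsilon) {
  P <- ncol(pool_mat)
  V <- length(patient_vec)
  Z <- matrix(0, V, repeats)
  valid <- rep(TRUE, V)
  for (r in seq_len(repeats)) {
    # sorted draw: the template is a set, and a stable column order keeps
    # the floating-point reductions identical whenever the set is identical
    # (so n = pool size gives an exactly zero across-repeat SD)
    X <- pool_mat[, sort.int(sample.int(P, n)), drop = FALSE]
    mu <- rowMeans(X)
    sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
    ok <- sdv > epsilon
    zr <- numeric(V)
    zr[ok] <- (patient_vec[ok] - mu[ok]) / sdv[ok]
    Z[, r] <- zr
    valid <- valid & ok
  }
  if (!any(valid))
    an_stop("no voxel is valid in every repeat; cannot form the spatial mean",
            "empty_mask")
  Zv <- Z[valid, , drop = FALSE]
  mu <- rowMeans(Zv)
  sdv <- sqrt(rowSums((Zv - mu)^2) / (repeats - 1))
  mean(sdv)
}

.pool_to_matrix <- function(volumes) {
  d <- dim(volumes[[1]]$values)
  for (v in volumes[-1]) stopifnot_same_grid(volumes[[1]], v, "pool volumes")
  vapply(volumes, function(v) as.vector(v$values), numeric(prod(d)))
}

.resolve_mask <- function(pool_mat, d, mask, mask_frac) {
  if (is.null(mask)) {
    mn <- array(rowMeans(pool_mat), d)
    mask_from_mean(mn, frac = mask_frac)$include
  } else if (inherits(mask, "brain_mask")) mask$include else mask
}

#' Consistency statistic at one template size
#'
#' Composes draw -> template -> z-map `repeats` times, then the voxel-wise
#' across-repeat SD and its spatial mean over the brain mask. Deterministic
#' under a fixed seed. Returns exactly 0 when `n` equals the pool size
#' (every repeat draws the identical template).
#'
#' @param patient a [gm_volume()].
#' @param pool list of matched-pool [gm_volume()].
#' @param n template size; at most `length(pool)`.
#' @param repeats number of random repeats (>= 2).
#' @param epsilon template-SD validity floor.
#' @param mask optional [brain_mask()]; default derived from the pool mean.
#' @param mask_frac threshold for the automatic mask.
#' @param seed optional seed set before drawing.
#' @return scalar: the spatial mean of the across-repeat z-score SD.
#' @export
consistency_at_n <- function(patient, pool, n, repeats = 100, epsilon = 1e-6,
                             mask = NULL, mask_frac = 0.05, seed = NULL) {
  stopifnot(inherits(patient, "gm_volume"))
  if (length(pool) < n)
    an_stop(sprintf("pool of %d subjects is too small to draw %d",
                    length(pool), n), "pool_too_small")
  if (repeats < 2) an_stop("repeats must be >= 2", "config")
  stopifnot_same_grid(patient, pool[[1]], "patient and pool")
  pm <- .pool_to_matrix(pool)
  inc <- .resolve_mask(pm, dim(patient$values), mask, mask_frac)
  idx <- which(as.vector(inc))
  if (!length(idx)) an_stop("mask selects no voxels", "empty_mask")
  if (!is.null(seed)) set.seed(seed)
  .consistency_core(patient$values[idx], pm[idx, , drop = FALSE], n, repeats,
                    epsilon)
}

#' Consistency curve over template sizes
#'
#' One point per template size n in `[n_min, n_max]`: the spatial mean of the
#' across-repeat voxel-wise z-score SD at that size. Each (patient, n) pair
#' uses an independent RNG substream derived from the config seed, so curves
#' are reproducible and order-independent.
#'
#' @param patient a [patient_case()].
#' @param cohort list with `table` (metadata) and `volumes` (named list of
#'   [gm_volume()]), e.g. from [generate_cohort()].
#' @param config an [experiment_config()].
#' @return an object of class `consistency_curve` with fields `patient_id`,
#'   `n`, `value`, `repeats`.
#' @export
consistency_curve <- function(patient, cohort, config = experiment_config()) {
  stopifnot(inherits(patient, "patient_case"), inherits(config, "experiment_config"))
  matched <- match_subjects(cohort$table, patient$age, patient$sex,
                            config$age_window)
  if (nrow(matched) < config$min_pool)
    an_stop(sprintf(
      "patient %s ineligible: %d matched subjects (sex %s, age %d +/- %s) < required %d (shortfall %d)",
      patient$id, nrow(matched), patient$sex, patient$age, config$age_window,
      config$min_pool, config$min_pool - nrow(matched)), "ineligible")
  pool <- cohort$volumes[matched$subject_id]
  stopifnot_same_grid(patient$volume, pool[[1]], "patient and pool")
  pm <- .pool_to_matrix(pool)
  inc <- .resolve_mask(pm, dim(patient$volume$values), config$brain_mask,
                       config$mask_frac)
  idx <- which(as.vector(inc))
  pv <- patient$volume$values[idx]
  pmm <- pm[idx, , drop = FALSE]
  ns <- seq(config$n_min, config$n_max)
  vals <- vapply(ns, function(n) {
    set.seed(.substream_seed(config$seed, patient$id, n))
    .consistency_core(pv, pmm, n, config$repeats, config$epsilon)
  }, numeric(1))
  structure(list(patient_id = patient$id, n = as.integer(ns), value = vals,
                 repeats = config$repeats),
            class = "consistency_curve")
}

#' Run the full cohort-size experiment
#'
#' Checks every patient's eligibility (matched pool >= `min_pool`), computes
#' each consistency curve and its knee point, and summarizes the knees: the
#' maximum (the minimum number of template subjects required for consistent
#' atrophy estimation), mean, SD, median and interquartile range.
#'
#' @param patients list of [patient_case()].
#' @param cohort cohort list (`table` + `volumes`).
#' @param config an [experiment_config()].
#' @return list with `curves`, `knees` (a `data.frame` with per-patient knee
#'   size, distance and found flag) and `summary` (list with `max_knee`,
#'   `mean`, `sd`, `median`, `iqr`).
#' @export
run_experiment <- function(patients, cohort, config = experiment_config()) {
  shortfall <- character(0)
  for (p in patients) {
    m <- match_subjects(cohort$table, p$age, p$sex, config$age_window)
    if (nrow(m) < config$min_pool) shortfall <- c(shortfall, p$id)
  }
  if (length(shortfall))
    an_stop(sprintf("ineligible patient(s), matched pool < %d: %s",
                    config$min_pool, paste(shortfall, collapse = ", ")),
            "ineligible")
  curves <- lapply(patients, consistency_curve, cohort = cohort, config = config)
  knees <- lapply(curves, find_knee, smoothing = config$knee_smoothing,
                  threshold = config$knee_threshold)
  ktab <- data.frame(
    patient_id = vapply(curves, function(cv) cv$patient_id, character(1)),
    n_at_knee = vapply(knees, function(k) if (k$found) k$n_at_knee else NA_integer_,
                       integer(1)),
    distance = vapply(knees, function(k) k$distance, numeric(1)),
    found = vapply(knees, function(k) k$found, logical(1)),
    stringsAsFactors = FALSE)
  kk <- ktab$n_at_knee[ktab$found]
  summary <- if (length(kk)) {
    list(max_knee = max(kk), mean = mean(kk), sd = stats::sd(kk),
         median = stats::median(kk),
         iqr = as.numeric(stats::quantile(kk, c(0.25, 0.75))))
  } else list(max_knee = NA, mean = NA, sd = NA, median = NA, iqr = c(NA, NA))
  list(curves = curves, knees = ktab, summary = summary)
}

#' Write a consistency curve to CSV
#'
#' Columns `n_subjects, sd_spatial_mean, patient_id, repeats`; values keep
#' full double precision (>= 10 significant digits) so curves round-trip
#' exactly via [read_curve()].
#'
#' @param curve a [consistency_curve()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "consistency_curve"))
  if (!length(curve$n)) an_stop("curve is empty", "empty_curve")
  df <- data.frame(n_subjects = curve$n,
                   sd_spatial_mean = sprintf("%.17g", curve$value),
                   patient_id = curve$patient_id, repeats = curve$repeats,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a consistency curve from CSV
#'
#' @param path CSV written by [write_curve()].
#' @return a `consistency_curve` object.
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("n_subjects", "sd_spatial_mean", "patient_id", "repeats")
  missing <- setdiff(need, names(df))
  if (length(missing))
    an_stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
            "missing_column")
  structure(list(patient_id = df$patient_id[1],
                 n = as.integer(df$n_subjects),
                 value = as.numeric(df$sd_spatial_mean),
                 repeats = df$repeats[1]),
            class = "consistency_curve")
}
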