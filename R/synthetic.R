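# Synthetic cohort generator.
#
# Emulates CAT12-style preprocessed (spatially normalized, modulated,
# smoothed) gray-matter maps: a uniform gray-matter level inside an
# ellipsoidal brain, declining linearly with age, offset by sex, plus a
# spatially smooth zero-mean Gaussian random field per subject. Background
# outside the brain ellipsoid is exactly zero (zero-variance background, as
# in real template-space maps). Focal atrophy is injected multiplicatively
# inside mesiotemporal-like ellipsoidal masks.

#' Specification of a synthetic normal cohort
#'
#' Defaults describe a healthy adult pool: modulated GM level 0.6 a.u. at the
#' mid-cohort age, declining 0.003 a.u./year, males 0.02 a.u. below females,
#' between-subject SD 0.06 a.u. with 8 mm FWHM spatial smoothness, ages
#' uniform over 20-90 years, 57.9% female.
#'
#' @param shape integer length-3, voxels per axis.
#' @param voxel_size voxel edge lengths in mm (default 2 mm isotropic).
#' @param n_subjects number of subjects to generate.
#' @param age_range integer `c(min, max)` in years; ages drawn uniformly.
#' @param sex_ratio fraction female in `[0, 1]`.
#' @param baseline_mean GM level at the mid-cohort age, a.u. (> 0).
#' @param age_slope change in GM per year of age, a.u./yr (typically <= 0).
#' @param sex_offset additive shift applied to males, a.u.
#' @param between_subject_sd marginal SD of the smooth subject-specific
#'   random field, a.u. (>= 0).
#' @param noise_fwhm full width at half maximum of the field's spatial
#'   smoothness, mm.
#' @param seed RNG seed for [generate_cohort()].
#' @return an object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(shape = c(24, 24, 24), voxel_size = c(2, 2, 2),
                                  n_subjects = 100, age_range = c(20, 90),
                                  sex_ratio = 0.579, baseline_mean = 0.6,
                                  age_slope = -0.003, sex_offset = -0.02,
                                  between_subject_sd = 0.06, noise_fwhm = 8,
                                  seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) an_stop("shape must be 3 ints >= 1", "dim")
  if (n_subjects < 1L) an_stop("n_subjects must be >= 1", "spec")
  if (baseline_mean <= 0) an_stop("baseline_mean must be > 0", "spec")
  if (between_subject_sd < 0) an_stop("between_subject_sd must be >= 0", "spec")
  age_range <- as.integer(age_range)
  if (length(age_range) != 2L || age_range[1] > age_range[2])
    an_stop("age_range must be c(min, max) with min <= max", "spec")
  if (sex_ratio < 0 || sex_ratio > 1) an_stop("sex_ratio must be in [0, 1]", "spec")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 n_subjects = as.integer(n_subjects), age_range = age_range,
                 sex_ratio = sex_ratio, baseline_mean = baseline_mean,
                 age_slope = age_slope, sex_offset = sex_offset,
                 between_subject_sd = between_subject_sd,
                 noise_fwhm = noise_fwhm, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# Gaussian smoothing matrix for one axis: S[i, j] = w(|i - j|), rows
# normalized to sum 1; truncated (non-circular) at the grid edges.
.smoothing_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  S <- exp(-d^2 / (2 * sigma_vox^2))
  S / rowSums(S)
}

.apply_axis <- function(arr, S, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  dp <- d[perm]
  m <- S %*% matrix(a, dp[1], dp[2] * dp[3])
  a <- array(m, dp)
  aperm(a, order(perm))
}

#' Smooth zero-mean Gaussian random field with exact marginal SD
#'
#' White Gaussian noise is convolved with a separable Gaussian kernel of the
#' requested FWHM, then rescaled voxel-wise by the exact per-voxel standard
#' deviation of the smoothed field so that the marginal SD equals `sd`
#' everywhere (including at grid edges, where truncated kernels would
#' otherwise deflate the variance). Without this renormalization the
#' field's SD would depend on the kernel width.
#'
#' @param shape integer length-3 grid shape.
#' @param voxel_size voxel edge lengths, mm.
#' @param fwhm smoothness, mm (0 = white noise).
#' @param sd target marginal SD.
#' @return 3D array; draws from the R session RNG stream.
#' @export
smooth_gaussian_field <- function(shape, voxel_size = c(1, 1, 1), fwhm = 0, sd = 1) {
  shape <- as.integer(shape)
  w <- array(stats::rnorm(prod(shape)), shape)
  if (sd == 0) return(array(0, shape))
  if (fwhm <= 0) return(w * sd)
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  Ss <- lapply(seq_len(3), function(a) .smoothing_matrix(shape[a], sigma_vox[a]))
  sm <- .apply_axis(.apply_axis(.apply_axis(w, Ss[[1]], 1), Ss[[2]], 2), Ss[[3]], 3)
  # marginal SD of the separably smoothed white field factorizes over axes
  rn <- lapply(Ss, function(S) sqrt(rowSums(S^2)))
  denom <- outer(outer(rn[[1]], rn[[2]]), rn[[3]])
  sm / denom * sd
}

# Ellipsoid membership on a voxel grid; center and semiaxes in voxel units.
.ellipsoid <- function(shape, center, semiaxes) {
  ix <- seq_len(shape[1]); iy <- seq_len(shape[2]); iz <- seq_len(shape[3])
  dx2 <- ((ix - center[1]) / semiaxes[1])^2
  dy2 <- ((iy - center[2]) / semiaxes[2])^2
  dz2 <- ((iz - center[3]) / semiaxes[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Default ellipsoidal brain support for a grid
#'
#' Centered ellipsoid with semiaxes 0.45 of the grid shape; synthetic
#' subjects have zero gray matter outside it.
#'
#' @param shape integer length-3 grid shape.
#' @param voxel_size voxel size for the mask.
#' @return a [brain_mask()].
#' @export
default_brain_ellipsoid <- function(shape, voxel_size = c(1, 1, 1)) {
  shape <- as.integer(shape)
  ctr <- (shape + 1) / 2
  brain_mask(.ellipsoid(shape, ctr, 0.45 * shape), voxel_size = voxel_size)
}

#' Mirror-symmetric mesiotemporal-like region masks
#'
#' Two disjoint ellipsoids, one per hemisphere, mirror-symmetric about the
#' mid-sagittal plane (first axis), placed infero-medially within the default
#' brain ellipsoid — a stand-in for the medial temporal volume-loss pattern
#' typical of Alzheimer's disease.
#'
#' @param shape integer length-3 grid shape; every axis must be >= 8.
#' @param voxel_size voxel size for the masks.
#' @return list with elements `left` and `right`, each a [brain_mask()].
#' @export
default_mesiotemporal_masks <- function(shape, voxel_size = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (any(shape < 8L)) an_stop("grid too small: every axis must be >= 8 voxels", "dim")
  ctr <- (shape + 1) / 2
  off <- c(0.20, -0.10, -0.15) * shape
  semi <- pmax(0.09 * shape, 1)
  left <- .ellipsoid(shape, ctr + c(-off[1], off[2], off[3]), semi)
  right <- .ellipsoid(shape, ctr + off, semi)
  list(left = brain_mask(left, voxel_size), right = brain_mask(right, voxel_size))
}

#' Generate one synthetic subject
#'
#' Voxel value = baseline + age_slope * (age - age_ref) + sex_offset * 1(male)
#' + smooth random field, clipped at 0, inside the brain ellipsoid; 0
#' outside. The age reference is the midpoint of the spec's age range, so
#' `baseline_mean` is the mid-cohort mean. Draws from the current RNG state;
#' seed externally (or via [generate_cohort()]) for reproducibility.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param age integer age in years, within `spec$age_range`.
#' @param sex `"female"` or `"male"`.
#' @param subject_id identifier for the volume.
#' @return a [gm_volume()].
#' @export
generate_subject <- function(spec, age, sex, subject_id = NA_character_) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (age < spec$age_range[1] || age > spec$age_range[2])
    an_stop(sprintf("age %s outside spec age_range [%d, %d]", age,
                    spec$age_range[1], spec$age_range[2]), "age_range")
  sex <- normalize_sex(sex)
  age_ref <- mean(spec$age_range)
  level <- spec$baseline_mean + spec$age_slope * (age - age_ref) +
    spec$sex_offset * (sex == "male")
  noise <- smooth_gaussian_field(spec$shape, spec$voxel_size, spec$noise_fwhm,
                                 spec$between_subject_sd)
  vals <- pmax(level + noise, 0)
  support <- default_brain_ellipsoid(spec$shape, spec$voxel_size)$include
  vals[!support] <- 0
  gm_volume(array(vals, spec$shape), voxel_size = spec$voxel_size,
            subject_id = subject_id)
}

#' Generate a synthetic normal cohort
#'
#' Ages are drawn uniformly over the spec's integer age range and sex
#' Bernoulli(sex_ratio); the whole cohort is reproducible under the spec's
#' seed. Metadata rows and volumes are aligned by subject id.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param id_prefix prefix for generated subject ids.
#' @return list with `table` (cohort metadata `data.frame`) and `volumes`
#'   (named list of [gm_volume()]).
#' @export
generate_cohort <- function(spec, id_prefix = "SYN") {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  ages <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
  sexes <- ifelse(stats::runif(n) < spec$sex_ratio, "female", "male")
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  volumes <- vector("list", n)
  for (i in seq_len(n))
    volumes[[i]] <- generate_subject(spec, ages[i], sexes[i], subject_id = ids[i])
  names(volumes) <- ids
  table <- data.frame(subject_id = ids, age = as.integer(ages), sex = sexes,
                      cohort = "synthetic", scanner = "synthetic",
                      volume_ref = NA_character_, stringsAsFactors = FALSE)
  list(table = table, volumes = volumes)
}

#' Focal atrophy specification
#'
#' @param region_mask a [brain_mask()] delimiting the atrophic region.
#' @param severity fractional gray-matter reduction in `[0, 1]`.
#' @return an object of class `atrophy_spec`.
#' @export
atrophy_spec <- function(region_mask, severity) {
  stopifnot(inherits(region_mask, "brain_mask"))
  if (severity < 0 || severity > 1) an_stop("severity must be in [0, 1]", "spec")
  structure(list(region_mask = region_mask, severity = severity),
            class = "atrophy_spec")
}

#' Inject focal atrophy into a volume
#'
#' Values inside the region mask are multiplied by `1 - severity`; values
#' outside are unchanged.
#'
#' @param volume a [gm_volume()].
#' @param atrophy an [atrophy_spec()] (or a [brain_mask()] together with
#'   `severity`).
#' @param severity used when `atrophy` is a bare mask.
#' @return a new [gm_volume()].
#' @export
inject_atrophy <- function(volume, atrophy, severity = NULL) {
  stopifnot(inherits(volume, "gm_volume"))
  if (inherits(atrophy, "brain_mask")) atrophy <- atrophy_spec(atrophy, severity)
  stopifnot(inherits(atrophy, "atrophy_spec"))
  stopifnot_same_grid(volume, atrophy$region_mask, "volume and atrophy mask")
  vals <- volume$values
  m <- atrophy$region_mask$include
  vals[m] <- vals[m] * (1 - atrophy$severity)
  gm_volume(vals, voxel_size = volume$voxel_size,
            subject_id = volume$subject_id, header = volume$header)
}
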