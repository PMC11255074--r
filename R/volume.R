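# Gray-matter volume container and NIfTI-1 round-trip I/O.
#
# A gm_volume is a 3D scalar field of modulated gray-matter volume (arbitrary
# units, >= 0) on a fixed voxel grid. The NIfTI header/affine is carried
# opaquely for round-tripping; it is never used for resampling — every stage
# requires all inputs to share one grid.

#' Construct a gray-matter volume
#'
#' @param values 3D numeric array; finite, non-negative modulated GM values.
#' @param voxel_size numeric length-3, voxel edge lengths in mm (> 0).
#' @param subject_id identifier carried through the pipeline.
#' @param header optional opaque NIfTI header template (kept for round-trips).
#' @return an object of class `gm_volume`.
#' @export
gm_volume <- function(values, voxel_size = c(1, 1, 1), subject_id = NA_character_,
                      header = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    an_stop("values must be a 3D array", "dim")
  if (any(dim(values) < 1L)) an_stop("all grid dimensions must be >= 1", "dim")
  if (!all(is.finite(values))) an_stop("volume contains NaN/Inf voxels", "nonfinite")
  if (any(values < 0)) an_stop("gray-matter values must be >= 0", "negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    an_stop("voxel_size must be 3 positive numbers (mm)", "voxel_size")
  structure(list(values = values, voxel_size = voxel_size,
                 subject_id = as.character(subject_id), header = header),
            class = "gm_volume")
}

#' Construct a brain mask
#'
#' @param include 3D logical array; at least one voxel must be included.
#' @param voxel_size voxel edge lengths in mm.
#' @return an object of class `brain_mask`.
#' @export
brain_mask <- function(include, voxel_size = c(1, 1, 1)) {
  if (!is.array(include) || length(dim(include)) != 3L)
    an_stop("include must be a 3D array", "dim")
  include <- array(as.logical(include), dim(include))
  if (any(is.na(include))) an_stop("mask contains NA entries", "nonfinite")
  if (!any(include)) an_stop("mask must include at least one voxel", "empty_mask")
  structure(list(include = include, voxel_size = as.numeric(voxel_size)),
            class = "brain_mask")
}

#' Read a 3D gray-matter volume from a NIfTI-1 file
#'
#' Fails distinctly on unreadable files, non-3D images, and NaN/Inf voxel
#' content. The data array round-trips bit-identically through
#' [write_volume()].
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param subject_id identifier to attach; defaults to the file stem.
#' @return a [gm_volume()].
#' @export
read_volume <- function(path, subject_id = NULL) {
  if (!file.exists(path)) an_stop(sprintf("no such file: %s", path), "unreadable")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) an_stop(
                    sprintf("failed to read NIfTI file %s: %s", path,
                            conditionMessage(e)), "unreadable"))
  d <- dim(img)
  if (length(d) != 3L)
    an_stop(sprintf("expected a 3D image, got %dD (%s)", length(d),
                    paste(d, collapse = "x")), "dim")
  vals <- array(as.numeric(img), d)
  if (!all(is.finite(vals)))
    an_stop(sprintf("volume %s contains NaN/Inf voxels", path), "nonfinite")
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  vs <- RNifti::pixdim(img)[seq_len(3)]
  gm_volume(vals, voxel_size = vs, subject_id = subject_id, header = img)
}

#' Write a gray-matter volume to a NIfTI-1 file
#'
#' Data are written as float64 so that the array read back by [read_volume()]
#' equals the input exactly.
#'
#' @param volume a [gm_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "gm_volume"))
  img <- if (is.null(volume$header)) RNifti::asNifti(volume$values)
         else RNifti::asNifti(volume$values, reference = volume$header)
  RNifti::pixdim(img) <- volume$voxel_size
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Derive a brain mask from a mean volume
#'
#' Voxels whose mean gray-matter value exceeds a fraction of the global
#' maximum are retained. This defines the spatial support over which the
#' consistency statistic is averaged when no explicit mask is supplied.
#'
#' @param mean_volume 3D array or [gm_volume()] of voxel-wise means.
#' @param frac threshold as a fraction of the maximum (default 0.05).
#' @param voxel_size voxel size for the resulting mask.
#' @return a [brain_mask()].
#' @export
mask_from_mean <- function(mean_volume, frac = 0.05, voxel_size = NULL) {
  if (inherits(mean_volume, "gm_volume")) {
    if (is.null(voxel_size)) voxel_size <- mean_volume$voxel_size
    mean_volume <- mean_volume$values
  }
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  mx <- max(mean_volume)
  if (mx <= 0) an_stop("mean volume is identically zero; no brain support", "empty_mask")
  brain_mask(mean_volume > frac * mx, voxel_size = voxel_size)
}
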