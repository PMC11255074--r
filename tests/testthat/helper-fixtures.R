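# Shared fixtures and independent oracles used across test files.

# A uniform gm_volume on a small grid.
const_volume <- function(value, shape = c(4, 4, 4), id = "v",
                         voxel_size = c(1, 1, 1)) {
  gm_volume(array(value, shape), voxel_size = voxel_size, subject_id = id)
}

# Random non-negative volumes on one grid.
random_volumes <- function(n, shape = c(4, 4, 4), seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    gm_volume(array(stats::runif(prod(shape), 0.1, 1), shape),
              subject_id = sprintf("R%03d", i))
  })
}

# Brute-force Kneedle oracle: normalize the raw samples, vertical distance to
# the chord between the normalized endpoints, argmax over samples (first on
# ties). Independent of the spline path (use with smoothing = 0 data).
oracle_knee <- function(x, y) {
  xn <- (x - min(x)) / (max(x) - min(x))
  yn <- (y - min(y)) / (max(y) - min(y))
  chord <- yn[1] + (yn[length(yn)] - yn[1]) * (xn - xn[1]) / (xn[length(xn)] - xn[1])
  d <- chord - yn
  list(n = x[which(d == max(d))[1]], distance = max(d))
}

# A small cohort table for matching tests.
toy_cohort_table <- function(ages, sexes, ids = NULL) {
  n <- length(ages)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  data.frame(subject_id = ids, age = as.integer(ages), sex = sexes,
             cohort = "toy", scanner = "sim", volume_ref = NA_character_,
             stringsAsFactors = FALSE)
}
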