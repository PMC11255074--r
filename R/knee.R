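# Kneedle-style knee-point detection: smoothing-spline fit, min-max
# normalization to the unit square, and the largest distance between the
# curve and the chord joining its endpoints.

#' Fit a cubic smoothing spline and evaluate at the input abscissae
#'
#' `smoothing = 0` is the interpolation limit (fitted values equal the data
#' at the knots); `smoothing = NULL` selects the penalty automatically by
#' generalized cross-validation via [stats::smooth.spline()]; a positive
#' number is passed through as the spline's lambda penalty.
#'
#' @param x strictly increasing numeric vector (>= 4 points).
#' @param y response values.
#' @param smoothing `NULL`, 0, or a positive penalty.
#' @return fitted y values at `x`.
#' @export
fit_smoothing_spline <- function(x, y, smoothing = NULL) {
  if (length(x) < 4L) an_stop("need at least 4 points", "too_few")
  if (length(y) != length(x)) an_stop("x and y lengths differ", "length")
  if (any(diff(x) <= 0)) an_stop("x must be strictly increasing", "nonmonotone_x")
  if (max(y) == min(y)) return(rep(y[1], length(y)))
  if (!is.null(smoothing) && smoothing == 0) {
    # interpolating cubic spline evaluated at its own knots returns y
    return(stats::spline(x, y, xout = x)$y)
  }
  fit <- if (is.null(smoothing)) {
    stats::smooth.spline(x, y, cv = FALSE)
  } else {
    stats::smooth.spline(x, y, lambda = smoothing)
  }
  stats::predict(fit, x)$y
}

#' Min-max normalize a curve to the unit square
#'
#' @param x,y numeric vectors; each must have a positive range (a flat curve
#'   cannot be normalized and yields no knee downstream).
#' @return list with normalized `x` and `y` in `[0, 1]`. Invariant under
#'   affine rescaling of either input axis.
#' @export
normalize_curve <- function(x, y) {
  if (max(x) == min(x)) an_stop("x has zero range", "flat")
  if (max(y) == min(y)) an_stop("y has zero range; curve is flat", "flat")
  list(x = (x - min(x)) / (max(x) - min(x)),
       y = (y - min(y)) / (max(y) - min(y)))
}

#' Locate the knee of a decreasing consistency curve
#'
#' Kneedle construction: fit a smoothing spline, min-max normalize to the
#' unit square, and find the observed sample maximizing the distance between
#' the normalized curve and the chord joining its first and last points. For
#' a convex decreasing curve the curve lies below the chord, so the signed
#' vertical distance (chord minus curve) is positive at the knee; no axis
#' flip is applied. Ties break toward the smaller sample size. The knee is
#' declared not found when the maximal distance does not exceed `threshold`
#' (e.g. a straight line) or when the curve is flat.
#'
#' @param curve a `consistency_curve`, a list/data.frame with `n` (or
#'   `n_subjects`/`x`) and `value` (or `sd_spatial_mean`/`y`) components.
#' @param smoothing passed to [fit_smoothing_spline()]; `NULL` = automatic.
#' @param threshold minimal normalized distance to declare a knee (default
#'   0.01).
#' @param distance `"vertical"` (chord minus curve at equal x; the Kneedle
#'   difference curve) or `"perpendicular"` (point-to-chord distance, same
#'   sign convention).
#' @return an object of class `knee_point`: `n_at_knee` (an observed sample,
#'   never interpolated), `distance`, `smoothed_curve`, `found`.
#' @export
find_knee <- function(curve, smoothing = NULL, threshold = 0.01,
                      distance = c("vertical", "perpendicular")) {
  distance <- match.arg(distance)
  xy <- .curve_xy(curve)
  x <- xy$x; y <- xy$y
  if (length(x) < 4L) an_stop("need at least 4 points", "too_few")
  if (max(y) == min(y)) {
    return(structure(list(n_at_knee = NA_integer_, distance = 0,
                          smoothed_curve = y, found = FALSE),
                     class = "knee_point"))
  }
  fitted <- fit_smoothing_spline(x, y, smoothing)
  if (max(fitted) == min(fitted)) {
    return(structure(list(n_at_knee = NA_integer_, distance = 0,
                          smoothed_curve = fitted, found = FALSE),
                     class = "knee_point"))
  }
  norm <- normalize_curve(x, fitted)
  n1 <- length(norm$x)
  chord <- norm$y[1] + (norm$y[n1] - norm$y[1]) *
    (norm$x - norm$x[1]) / (norm$x[n1] - norm$x[1])
  d <- chord - norm$y
  if (distance == "perpendicular") {
    slope <- (norm$y[n1] - norm$y[1]) / (norm$x[n1] - norm$x[1])
    d <- d / sqrt(1 + slope^2)
  }
  i <- which(d == max(d))[1]  # first index = smallest sample size on ties
  found <- max(d) > threshold
  structure(list(n_at_knee = if (found) as.integer(x[i]) else NA_integer_,
                 distance = max(d), smoothed_curve = fitted, found = found),
            class = "knee_point")
}

.curve_xy <- function(curve) {
  if (inherits(curve, "consistency_curve")) return(list(x = curve$n, y = curve$value))
  nm <- names(curve)
  x <- if ("n" %in% nm) curve$n else if ("n_subjects" %in% nm) curve$n_subjects
       else curve$x
  y <- if ("value" %in% nm) curve$value else if ("sd_spatial_mean" %in% nm)
       curve$sd_spatial_mean else curve$y
  if (is.null(x) || is.null(y)) an_stop("cannot extract x/y from curve", "curve")
  list(x = as.numeric(x), y = as.numeric(y))
}

#' Write a knee point as JSON
#'
#' Fields `n_at_knee`, `distance`, `found`; numbers are written at full
#' precision so identical runs produce byte-identical files.
#'
#' @param knee a [find_knee()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_knee_json <- function(knee, path) {
  stopifnot(inherits(knee, "knee_point"))
  jsonlite::write_json(list(n_at_knee = knee$n_at_knee,
                            distance = knee$distance, found = knee$found),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
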