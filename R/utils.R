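# Shared helpers: classed error conditions and grid bookkeeping.

an_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("atrophynorm_error_", class), "atrophynorm_error",
              "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' Half-up rounding
#'
#' Rounds halves away from zero toward the next integer (0.5 -> 1), unlike
#' [round()] which rounds halves to even. Diagnostic percentages are reported
#' with this convention.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Do two volumes live on the same voxel grid?
#'
#' Grid identity means identical array dimensions and voxel sizes. All
#' pipeline stages require exact grid agreement; nothing is resampled or
#' broadcast.
#'
#' @param a,b objects carrying `values`/`include` arrays and `voxel_size`.
#' @return logical scalar.
#' @export
same_grid <- function(a, b) {
  da <- grid_shape(a); db <- grid_shape(b)
  identical(da, db) && isTRUE(all(abs(voxel_size_of(a) - voxel_size_of(b)) < 1e-9))
}

grid_shape <- function(x) {
  if (inherits(x, "gm_volume")) return(dim(x$values))
  if (inherits(x, "brain_mask")) return(dim(x$include))
  if (inherits(x, "normal_template")) return(dim(x$mean))
  if (inherits(x, "zmap")) return(dim(x$z))
  if (is.array(x)) return(dim(x))
  an_stop("object has no voxel grid", "grid")
}

voxel_size_of <- function(x) {
  vs <- x$voxel_size
  if (is.null(vs)) vs <- c(1, 1, 1)
  vs
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    an_stop(sprintf("grid mismatch between %s: %s vs %s", what,
                    paste(grid_shape(a), collapse = "x"),
                    paste(grid_shape(b), collapse = "x")),
            "grid_mismatch")
  }
  invisible(TRUE)
}
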