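#' Euclidean deviation of the instrument tip from the target
#'
#' Straight-line distance (mm) between the stereotactic target and the
#' participant-generated tip position:
#' `d = sqrt((xt-xs)^2 + (yt-ys)^2 + (zt-zs)^2)`.
#'
#' Both arguments may be single points (length-3 numeric vectors or
#' 1-row data frames with columns `x`, `y`, `z`) or n-row data
#' frames/matrices, in which case distances are computed row-wise.
#'
#' @param target,tip Target and tip coordinates in mm.
#' @return Non-negative deviation(s) in mm.
#' @examples
#' target_deviation(c(0, 0, 0), c(1, 2, 2))  # 3
#' @export
target_deviation <- function(target, tip) {
  target <- as_coord_matrix(target, "target")
  tip <- as_coord_matrix(tip, "tip")
  if (ncol(target) != ncol(tip)) {
    abort("`target` and `tip` must have the same number of coordinates.")
  }
  if (nrow(target) != nrow(tip)) {
    if (nrow(target) == 1L) target <- target[rep(1L, nrow(tip)), , drop = FALSE]
    else if (nrow(tip) == 1L) tip <- tip[rep(1L, nrow(target)), , drop = FALSE]
    else abort("`target` and `tip` must have matching rows (or one row).")
  }
  sqrt(rowSums((target - tip)^2))
}

as_coord_matrix <- function(x, arg) {
  if (is.data.frame(x)) {
    cols <- intersect(c("x", "y", "z"), names(x))
    if (length(cols) < 2L) {
      abort(sprintf("`%s` data frame needs columns x, y[, z].", arg))
    }
    x <- as.matrix(x[cols])
  } else if (is.numeric(x) && is.null(dim(x))) {
    x <- matrix(x, nrow = 1L)
  } else if (is.matrix(x)) {
    storage.mode(x) <- "double"
  } else {
    abort(sprintf("`%s` must be a numeric vector, matrix or data frame.", arg))
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` coordinates must all be finite.", arg))
  }
  if (ncol(x) < 2L || ncol(x) > 3L) {
    abort(sprintf("`%s` must have 2 or 3 coordinates per point.", arg))
  }
  x
}

#' Motor instability of a tip trajectory
#'
#' Scalar dispersion of the tracked instrument-tip position over a
#' window: the total variance of the positions, i.e. the sum of
#' per-axis variances about the trajectory mean (the trace of the
#' positional covariance matrix). It is zero for a perfectly steady
#' trajectory and grows with the spatial spread of micromovements; being
#' a covariance trace it is invariant to translation and rotation of the
#' coordinate frame.
#'
#' @param traj Trajectory samples: an n-by-2 (or n-by-3) matrix or a
#'   data frame with columns `x`, `y`\[, `z`\]; one row per time sample,
#'   n >= 2.
#' @param normalization `"population"` (default; divisor n) or
#'   `"sample"` (divisor n - 1).
#' @return A single non-negative instability value (squared length
#'   units of the input).
#' @details Windowing is the caller's responsibility: the variance is
#'   taken over exactly the samples supplied. No filtering, detrending
#'   or resampling is applied.
#' @examples
#' trajectory_instability(cbind(c(0, 2), c(0, 0)))  # 1
#' @export
trajectory_instability <- function(traj,
                                   normalization = c("population", "sample")) {
  normalization <- match.arg(normalization)
  traj <- as_coord_matrix(traj, "traj")
  n <- nrow(traj)
  if (n < 2L) abort("`traj` needs at least 2 samples.")
  centred <- sweep(traj, 2L, colMeans(traj))
  divisor <- if (normalization == "population") n else n - 1L
  sum(centred^2) / divisor
}
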