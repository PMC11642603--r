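#' Resample a trajectory to a fixed number of points with cubic splines
#'
#' Fits the x and y coordinates separately as cubic splines of the sample
#' index (the routine's default endpoint handling) and evaluates both at `n`
#' equally spaced index values spanning the full range, making trajectories
#' of different durations comparable point-by-point.
#'
#' @param traj A trajectory: either a list with a `samples` matrix
#'   (columns x, y, ...) or a 2+ column matrix of (x, y) samples.
#' @param n Number of output points.
#' @return A list of class `resampled_trajectory` with elements `points`
#'   (`n` x 2 matrix) and `trial_id` (if present on the input).
#' @examples
#' semi <- ideal_shape("circle", n = 30)
#' r <- resample_trajectory(semi)
#' nrow(r$points)
#' @export
resample_trajectory <- function(traj, n = 100) {
  xy <- if (is.list(traj) && !is.null(traj$samples)) traj$samples else traj
  xy <- as.matrix(xy)
  keep <- !duplicated(xy[, 1:2, drop = FALSE])
  xy <- xy[keep, , drop = FALSE]
  if (nrow(xy) < 4)
    stop("degenerate trajectory: need at least 4 distinct samples")
  idx <- seq_len(nrow(xy))
  at <- seq(1, nrow(xy), length.out = n)
  fx <- splinefun(idx, xy[, 1], method = "fmm")
  fy <- splinefun(idx, xy[, 2], method = "fmm")
  out <- list(points = cbind(x = fx(at), y = fy(at)),
              trial_id = if (is.list(traj)) traj$trial_id else NULL)
  class(out) <- "resampled_trajectory"
  out
}

resampled_points <- function(x) {
  if (inherits(x, "resampled_trajectory")) x$points else as.matrix(x)
}
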