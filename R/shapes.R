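#' Ideal half-circle and half-diamond trajectories
#'
#' Returns `n` points, uniformly spaced in arc length, along the ideal shape
#' running from the start point at the top to the end point at the bottom of
#' the drawing corridor.  The half circle is the semicircle whose diameter is
#' the start-end segment, bulging rightward; the half diamond is the two line
#' segments through the apex at half height, offset rightward by half the
#' start-end distance.
#'
#' @param shape `"circle"` or `"diamond"`.
#' @param n Number of points to return.
#' @param start,end Numeric length-2 start and end points in pixels.
#'   Defaults place the start at (0, 400) and the end at the origin, i.e. a
#'   400 px vertical corridor drawn top to bottom.
#' @return An `n` x 2 matrix of (x, y) coordinates.
#' @examples
#' head(ideal_shape("circle", n = 5))
#' @export
ideal_shape <- function(shape = c("circle", "diamond"), n = 100,
                        start = c(0, 400), end = c(0, 0)) {
  shape <- match.arg(shape)
  stopifnot(n >= 2, length(start) == 2, length(end) == 2)
  d <- sqrt(sum((end - start)^2))
  if (d <= 0) stop("start and end point must differ")
  mid <- (start + end) / 2
  along <- (end - start) / d           # unit vector start -> end
  perp <- c(-along[2], along[1])       # rightward when drawing downward
  r <- d / 2
  if (shape == "circle") {
    phi <- seq(0, pi, length.out = n)
    pts <- cbind(mid[1] + r * (sin(phi) * perp[1] - cos(phi) * along[1]),
                 mid[2] + r * (sin(phi) * perp[2] - cos(phi) * along[2]))
  } else {
    apex <- mid + r * perp
    s <- seq(0, 1, length.out = n)
    pts <- matrix(NA_real_, n, 2)
    first <- s <= 0.5
    pts[first, ] <- cbind(start[1] + 2 * s[first] * (apex[1] - start[1]),
                          start[2] + 2 * s[first] * (apex[2] - start[2]))
    pts[!first, ] <- cbind(apex[1] + (2 * s[!first] - 1) * (end[1] - apex[1]),
                           apex[2] + (2 * s[!first] - 1) * (end[2] - apex[2]))
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Arc length of an ideal shape
#'
#' @param shape `"circle"` or `"diamond"`.
#' @param d Start-end distance in pixels.
#' @return Path length in pixels.
#' @keywords internal
ideal_shape_length <- function(shape, d = 400) {
  r <- d / 2
  if (shape == "circle") pi * r else 2 * sqrt(r^2 + (d / 2)^2)
}

other_shape <- function(shape) ifelse(shape == "circle", "diamond", "circle")

#' Distance from points to a polyline sampled densely from an ideal shape
#'
#' @param pts m x 2 matrix of query points.
#' @param curve k x 2 matrix of curve points (dense sampling).
#' @return Numeric vector of length m: distance from each point to the
#'   nearest curve sample.
#' @keywords internal
dist_to_curve <- function(pts, curve) {
  # nearest dense-sample distance; curve sampling is much finer than any
  # tolerance this is used with
  d2 <- outer(pts[, 1], curve[, 1], "-")^2 + outer(pts[, 2], curve[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}
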