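#' Participant-specific shape templates
#'
#' Averages all retained resampled trajectories of each shape, pooling all
#' experimental conditions, into a pointwise mean template per shape.
#'
#' @param resampled List of `resampled_trajectory` objects (all the same
#'   length).
#' @param labels Character vector of shape labels, one per trajectory.
#' @return Named list of `shape_template` objects (`points`, `shape`,
#'   `n_contributing`), one per shape present.
#' @examples
#' trs <- replicate(5, resample_trajectory(ideal_shape("circle", 40)),
#'                  simplify = FALSE)
#' tpl <- compute_templates(trs, rep("circle", 5))
#' tpl$circle$n_contributing
#' @export
compute_templates <- function(resampled, labels) {
  stopifnot(length(resampled) == length(labels))
  shapes <- unique(labels[!is.na(labels)])
  if (length(shapes) == 0) stop("no labelled trajectories to average")
  out <- list()
  for (sh in shapes) {
    idx <- which(labels == sh)
    if (length(idx) == 0) stop("empty shape class: ", sh)
    pts <- Reduce(`+`, lapply(resampled[idx], resampled_points)) /
      length(idx)
    out[[sh]] <- structure(list(shape = sh, points = pts,
                                n_contributing = length(idx)),
                           class = "shape_template")
  }
  out
}

#' Area enclosed between a trajectory and its template
#'
#' The distortion score: the unsigned area between two matched-length curves.
#' The closed polygon formed by the trajectory followed by the reversed
#' template is split at every crossing point of the two curves, and the
#' absolute (shoelace) areas of the resulting sub-loops are summed, so that
#' lobes on opposite sides never cancel.  The score is nonnegative, zero iff
#' the curves coincide, symmetric in its two arguments and invariant under a
#' common rigid translation.
#'
#' Curves are assumed to traverse the corridor in the same overall direction
#' (both run start to end), so crossings occur in the same order along both.
#'
#' @param traj A `resampled_trajectory` or n x 2 matrix.
#' @param template A `shape_template` or n x 2 matrix with the same number
#'   of points.
#' @return Area in squared pixels.
#' @examples
#' a <- ideal_shape("circle", 100)
#' area_to_template(a, a)                        # 0
#' b <- a; b[, 1] <- b[, 1] + 2                  # 2 px lateral shift
#' round(area_to_template(a, b))                 # ~ 2 * path height
#' @export
area_to_template <- function(traj, template) {
  A <- resampled_points(traj)
  B <- template_points(template)
  if (nrow(A) != nrow(B))
    stop("trajectory and template must have the same number of points")
  if (isTRUE(all.equal(A, B, tolerance = 0, check.attributes = FALSE)) ||
      max(abs(A - B)) == 0) return(0)
  cuts <- curve_crossings(A, B)
  # cut positions: global params along A and B in [0, 1], plus the points
  tA <- c(0, cuts$tA, 1)
  tB <- c(0, cuts$tB, 1)
  px <- c(A[1, 1], cuts$x, NA)
  py <- c(A[1, 2], cuts$y, NA)
  n <- nrow(A)
  total <- 0
  for (k in seq_len(length(tA) - 1)) {
    a_lo <- tA[k] * (n - 1) + 1
    a_hi <- tA[k + 1] * (n - 1) + 1
    b_lo <- tB[k] * (n - 1) + 1
    b_hi <- tB[k + 1] * (n - 1) + 1
    ia <- which(seq_len(n) > a_lo + 1e-9 & seq_len(n) < a_hi - 1e-9)
    ib <- which(seq_len(n) > b_lo + 1e-9 & seq_len(n) < b_hi - 1e-9)
    # loop: cut point -> A arc -> next cut (or ends) -> B arc reversed
    sx <- c(if (k == 1) A[1, 1] else px[k], A[ia, 1],
            if (k == length(tA) - 1) A[n, 1] else px[k + 1],
            if (k == length(tA) - 1) B[n, 1] else NULL,
            rev(B[ib, 1]),
            if (k == 1) B[1, 1] else NULL)
    sy <- c(if (k == 1) A[1, 2] else py[k], A[ia, 2],
            if (k == length(tA) - 1) A[n, 2] else py[k + 1],
            if (k == length(tA) - 1) B[n, 2] else NULL,
            rev(B[ib, 2]),
            if (k == 1) B[1, 2] else NULL)
    total <- total + abs(shoelace(sx, sy))
  }
  total
}

# all crossings between two polylines, ordered along the first
curve_crossings <- function(A, B, tol = 1e-12) {
  n <- nrow(A)
  p1x <- A[-n, 1]; p1y <- A[-n, 2]
  rx <- diff(A[, 1]); ry <- diff(A[, 2])
  q1x <- B[-n, 1]; q1y <- B[-n, 2]
  qx <- diff(B[, 1]); qy <- diff(B[, 2])
  g <- expand.grid(i = seq_len(n - 1), j = seq_len(n - 1))
  Rx <- rx[g$i]; Ry <- ry[g$i]; Qx <- qx[g$j]; Qy <- qy[g$j]
  dX <- q1x[g$j] - p1x[g$i]; dY <- q1y[g$j] - p1y[g$i]
  den <- Rx * Qy - Ry * Qx
  ok <- abs(den) > tol
  t <- ifelse(ok, (dX * Qy - dY * Qx) / den, NA_real_)
  s <- ifelse(ok, (dX * Ry - dY * Rx) / den, NA_real_)
  hit <- ok & t >= 0 & t < 1 & s >= 0 & s < 1
  if (!any(hit))
    return(list(tA = numeric(0), tB = numeric(0),
                x = numeric(0), y = numeric(0)))
  gi <- g$i[hit]; gj <- g$j[hit]; t <- t[hit]; s <- s[hit]
  tA <- (gi - 1 + t) / (n - 1)
  tB <- (gj - 1 + s) / (n - 1)
  x <- p1x[gi] + t * rx[gi]
  y <- p1y[gi] + t * ry[gi]
  o <- order(tA)
  tA <- tA[o]; tB <- tB[o]; x <- x[o]; y <- y[o]
  # drop near-duplicate cuts (shared vertices, grazing contacts) and any
  # cut not advancing along both curves
  keep <- c(TRUE, diff(tA) > 1e-9)
  keep <- keep & tA > 1e-9 & tA < 1 - 1e-9 & tB > 1e-9 & tB < 1 - 1e-9
  keep[keep][c(FALSE, diff(tB[keep]) <= 0)] <- FALSE
  list(tA = tA[keep], tB = tB[keep], x = x[keep], y = y[keep])
}

shoelace <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

#' Fraction of trajectory points inside the drawing corridor
#'
#' @param traj A `resampled_trajectory` or n x 2 matrix.
#' @param shape `"circle"`, `"diamond"`, or an m x 2 matrix of ideal curve
#'   points.
#' @param band Corridor half-width in pixels.
#' @param start,end Anchor points used when `shape` is a name.
#' @return Fraction in [0, 1] of points within `band` of the ideal curve.
#' @export
corridor_accuracy <- function(traj, shape, band = 100,
                              start = c(0, 400), end = c(0, 0)) {
  pts <- resampled_points(traj)
  curve <- if (is.character(shape))
    ideal_shape(shape, 2000, start, end) else as.matrix(shape)
  mean(dist_to_curve(pts, curve) <= band)
}
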