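#' Classify a resampled trajectory as circle or diamond
#'
#' Implements the swap-error spline classifier.  The trajectory's rightmost
#' point (first occurrence along the path) is used as the single interior
#' knot of two least-squares univariate splines fitted to the horizontal
#' coordinate as a function of the (monotone) vertical progression: one of
#' degree 1 (two straight lines hinged at the knot, the half-diamond model)
#' and one of degree 2 (a C1 quadratic spline, the half-circle model).  The
#' label is the shape whose model has the lower residual sum of squares; a
#' corner cannot be reproduced by the C1 quadratic spline, so an exact
#' half diamond yields a zero linear residual, while smooth arcs favour the
#' quadratic fit.
#'
#' Vertical progression that is not strictly monotone after resampling
#' (pen noise produces small local reversals) is made strictly monotone by
#' clamping reversals to the running maximum and breaking ties with an
#' infinitesimal index-proportional ramp; trajectories whose reversal mass
#' exceeds 80% of the vertical extent (random scribbles, not function-like
#' in y), whose vertical extent collapses, or
#' whose rightmost point falls at the path's first or last point, are
#' flagged unclassifiable.
#'
#' @param traj A `resampled_trajectory` or an n x 2 point matrix.
#' @return A list with `label` (`"circle"`, `"diamond"`, or `NA` if
#'   unclassifiable), `residual_linear`, `residual_quadratic`, and
#'   `unclassifiable` flag.
#' @examples
#' classify_shape(ideal_shape("diamond", 100))$label
#' classify_shape(ideal_shape("circle", 100))$label
#' @export
classify_shape <- function(traj) {
  pts <- resampled_points(traj)
  n <- nrow(pts)
  x <- pts[, 1]
  u <- -(pts[, 2] - pts[1, 2])          # progression from the start downward
  rng <- max(u) - min(u)
  if (rng <= 0)
    return(list(label = NA_character_, residual_linear = NA_real_,
                residual_quadratic = NA_real_, unclassifiable = TRUE))
  # enforce a strictly monotone abscissa: clamp local reversals (pen noise)
  # to the running maximum, then break ties with an infinitesimal ramp;
  # paths whose reversal mass is a substantial fraction of the vertical
  # extent are not function-like in y and cannot be fitted
  reversal <- sum(pmax(-diff(u), 0))
  if (reversal > 0.8 * rng)
    return(list(label = NA_character_, residual_linear = NA_real_,
                residual_quadratic = NA_real_, unclassifiable = TRUE))
  if (any(diff(u) <= 0))
    u <- cummax(u) + (rng * 1e-9) * (seq_len(n) - 1)
  m <- which.max(x)[1]                  # ties: first occurrence on the path
  if (m == 1 || m == n)
    return(list(label = NA_character_, residual_linear = NA_real_,
                residual_quadratic = NA_real_, unclassifiable = TRUE))
  knot <- u[m]
  rss <- function(deg) {
    kn <- c(rep(u[1], deg + 1), knot, rep(u[n], deg + 1))
    B <- splines::splineDesign(kn, u, ord = deg + 1)
    fit <- lm.fit(B, x)
    sum(fit$residuals^2)
  }
  r1 <- rss(1)
  r2 <- rss(2)
  if (isTRUE(all.equal(r1, r2, tolerance = 1e-12)) || r1 == r2) {
    warning("linear and quadratic spline residuals tie; labelling circle")
    label <- "circle"
  } else label <- if (r1 < r2) "diamond" else "circle"
  list(label = label, residual_linear = r1, residual_quadratic = r2,
       unclassifiable = FALSE)
}

#' Flag swap errors against the cued shape
#'
#' A swap error is a trial in which the spline classifier's label differs
#' from the shape the participant was cued to draw.
#'
#' @param resampled List of `resampled_trajectory` objects.
#' @param cued Character vector of cued shapes, one per trajectory.
#' @return Logical vector (`NA` where the trajectory was unclassifiable).
#' @export
detect_swap_errors <- function(resampled, cued) {
  stopifnot(length(resampled) == length(cued))
  vapply(seq_along(resampled), function(i) {
    cl <- classify_shape(resampled[[i]])
    if (cl$unclassifiable) NA else cl$label != cued[i]
  }, logical(1))
}

#' Screen trajectories for gross errors
#'
#' Automated stand-in for a visual inspection step: a trajectory is flagged
#' when its path length exceeds `k` times the ideal length of its shape, or
#' when its maximum pointwise distance from *both* shape templates exceeds
#' `dist_ceiling` (it resembles neither shape).
#'
#' @param resampled List of `resampled_trajectory` objects.
#' @param templates Named list with `circle` and `diamond` templates
#'   ([compute_templates()] output or ideal shapes as n x 2 matrices).
#' @param k Path-length ratio threshold.
#' @param dist_ceiling Distance ceiling in pixels.
#' @param start,end Anchor points (used for the ideal lengths).
#' @return Logical vector of flags.
#' @export
screen_gross_errors <- function(resampled, templates = NULL, k = 2.0,
                                dist_ceiling = 300,
                                start = c(0, 400), end = c(0, 0)) {
  d <- sqrt(sum((end - start)^2))
  if (is.null(templates))
    templates <- list(circle = ideal_shape("circle", 100, start, end),
                      diamond = ideal_shape("diamond", 100, start, end))
  tc <- template_points(templates$circle)
  td <- template_points(templates$diamond)
  vapply(resampled, function(r) {
    pts <- resampled_points(r)
    plen <- sum(sqrt(rowSums(diff(pts)^2)))
    ratio_bad <- plen > k * min(ideal_shape_length("circle", d),
                                ideal_shape_length("diamond", d))
    dc <- max(sqrt(rowSums((pts - tc)^2)))
    dd <- max(sqrt(rowSums((pts - td)^2)))
    ratio_bad || min(dc, dd) > dist_ceiling
  }, logical(1))
}

template_points <- function(tpl) {
  if (is.list(tpl) && !is.null(tpl$points)) tpl$points else as.matrix(tpl)
}
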