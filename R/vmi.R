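#' Score trajectories of one participant for visuomotor interference
#'
#' Runs the full trajectory pipeline for one participant: resample every
#' trajectory to 100 points, drop catch trials, screen gross errors, flag and
#' drop swap errors, build participant-specific circle and diamond templates
#' from the retained trials, and measure each trial's distortion as the area
#' between its trajectory and the template of its cued shape.
#'
#' @param trajectories List of trajectories from [generate_trajectories()]
#'   (or read from file), parallel to `design` rows by `trial_id`.
#' @param design Trial table from [generate_design()].
#' @param k,dist_ceiling Gross-error screening thresholds, see
#'   [screen_gross_errors()].
#' @param start,end Anchor points.
#' @return A list with `records` (a `data.frame` of `DistortionRecord`s:
#'   `trial_id`, `context`, `combination`, `congruency`, `drawing_time`,
#'   `area`), `templates`, and the screening flags `gross`, `swap` over
#'   the non-catch trials.
#' @export
score_trajectories <- function(trajectories, design, k = 2.0,
                               dist_ceiling = 300,
                               start = c(0, 400), end = c(0, 0)) {
  ids <- vapply(trajectories, function(t) t$trial_id, numeric(1))
  design <- design[match(ids, design$trial_id), ]
  keep0 <- !design$is_catch
  trajectories <- trajectories[keep0]
  design <- design[keep0, , drop = FALSE]
  res <- lapply(trajectories, resample_trajectory)
  gross <- screen_gross_errors(res, k = k, dist_ceiling = dist_ceiling,
                               start = start, end = end)
  swap <- detect_swap_errors(res, design$own_shape)
  swap[is.na(swap)] <- TRUE            # unclassifiable: treat as removable
  retained <- !gross & !swap
  if (!any(retained)) stop("no trajectories retained after screening")
  tpl <- compute_templates(res[retained], design$own_shape[retained])
  for (sh in c("circle", "diamond"))
    if (is.null(tpl[[sh]])) stop("no retained trajectories for shape ", sh)
  rec <- design[retained, c("trial_id", "context", "combination",
                            "congruency")]
  rec$drawing_time <- design$drawing_duration[retained]
  rec$area <- vapply(which(retained), function(i)
    area_to_template(res[[i]], tpl[[design$own_shape[i]]]), numeric(1))
  rownames(rec) <- NULL
  list(records = rec, templates = tpl, gross = gross, swap = swap)
}

#' Box-Cox transform the pooled distortion scores
#'
#' Adds an `area_boxcox` column to a pooled (multi-participant) distortion
#' table, using a single maximum-likelihood exponent for the whole
#' distribution.
#'
#' @param records Distortion `data.frame` with an `area` column.
#' @return The table with `area_boxcox` added, with the fitted `lambda`,
#'   `skewness` and `kurtosis` of the transformed values as attributes.
#' @export
transform_distortions <- function(records) {
  b <- boxcox_mle(records$area[records$area > 0])
  out <- records[records$area > 0, , drop = FALSE]
  out$area_boxcox <- b$transformed
  attr(out, "lambda") <- b$lambda
  attr(out, "skewness") <- b$skewness
  attr(out, "kurtosis") <- b$kurtosis
  out
}
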