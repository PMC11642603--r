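#' Trajectory generator effect parameters
#'
#' Controls the behavioural structure of simulated pen trajectories.
#' `vmi_shift` is the maximum lateral pull (pixels) toward the partner's
#' shape on incongruent trials, one value per social context; on congruent
#' trials the pull field is identically zero because the two ideal shapes
#' coincide.  Defaults plant a larger interference effect in the Parallel
#' context, the configuration the distortion analyses are designed to
#' detect.
#'
#' @param base_noise_sd SD (pixels) of the Gaussian jitter added to each
#'   sample; tapered to zero at the start and end points so trajectories
#'   always connect the two anchors.
#' @param vmi_shift Named numeric `c(joint = , parallel = )`: maximum
#'   deflection (pixels) toward the partner's shape on incongruent trials.
#' @param swap_rate Probability of drawing the shape opposite to the cue.
#' @param gross_error_rate Probability of producing a meaningless scribble.
#' @param sample_rate Pen sampling rate in Hz.
#' @param seed Integer seed.
#' @return A list of class `trajectory_effects`.
#' @export
trajectory_effects <- function(base_noise_sd = 5,
                               vmi_shift = c(joint = 3, parallel = 10),
                               swap_rate = 0.01,
                               gross_error_rate = 0.01,
                               sample_rate = 30,
                               seed = 1L) {
  stopifnot(base_noise_sd >= 0, all(vmi_shift >= 0),
            swap_rate >= 0, swap_rate <= 1,
            gross_error_rate >= 0, gross_error_rate <= 1, sample_rate > 0)
  structure(list(base_noise_sd = base_noise_sd, vmi_shift = vmi_shift,
                 swap_rate = swap_rate, gross_error_rate = gross_error_rate,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "trajectory_effects")
}

#' Simulate pen trajectories for a trial design
#'
#' For every trial, realises a noisy half circle or half diamond running from
#' the start point to the end point, sampled at the pen rate for the trial's
#' drawing duration.  On incongruent trials an additive deflection field --
#' proportional to the pointwise difference between the partner's and the
#' participant's ideal shapes, scaled so its maximum equals the context's
#' `vmi_shift` -- pulls the trajectory toward the partner's shape.  With
#' probability `swap_rate` the opposite shape is realised; with probability
#' `gross_error_rate` the trajectory is replaced by a random scribble.
#'
#' @param design Trial table from [generate_design()].
#' @param effects A [trajectory_effects()] object.
#' @param start,end Anchor points in pixels.
#' @return A list of trajectories, each a list with elements `trial_id`,
#'   `samples` (matrix with columns x, y, t), `drawn_shape`, `is_swap`,
#'   `is_gross` (generator ground truth, not visible to the analysis).
#' @examples
#' d <- generate_design(design_params(n_blocks_per_context = 1,
#'                                    trials_per_block = 4,
#'                                    catch_per_block = 0))
#' tr <- generate_trajectories(d, trajectory_effects(seed = 2))
#' nrow(tr[[1]]$samples)
#' @export
generate_trajectories <- function(design, effects = trajectory_effects(),
                                  start = c(0, 400), end = c(0, 0)) {
  stopifnot(all(c("own_shape", "partner_cued_shape", "context",
                  "drawing_duration", "start_time") %in% names(design)))
  set.seed(derive_seed(effects$seed, 202))
  d <- sqrt(sum((end - start)^2))
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    tr <- design[i, ]
    n <- max(4L, round(tr$drawing_duration * effects$sample_rate) + 1L)
    tvec <- tr$start_time + (seq_len(n) - 1) / effects$sample_rate
    is_swap <- runif(1) < effects$swap_rate
    drawn <- if (is_swap) other_shape(tr$own_shape) else tr$own_shape
    is_gross <- runif(1) < effects$gross_error_rate
    if (is_gross) {
      # meaningless scribble: random walk between the anchors
      xy <- cbind(cumsum(rnorm(n, 0, 60)), cumsum(rnorm(n, 0, 60)))
      xy <- sweep(xy, 2, xy[1, ]) + rep(start, each = n)
      xy[n, ] <- end
    } else {
      base <- ideal_shape(drawn, n, start, end)
      shift <- effects$vmi_shift[[tr$context]]
      # deflection toward the partner's cued shape, zero when congruent
      if (shift > 0 && tr$partner_cued_shape != drawn) {
        diff <- ideal_shape(tr$partner_cued_shape, n, start, end) - base
        mx <- max(sqrt(rowSums(diff^2)))
        if (mx > 0) base <- base + diff * (shift / mx)
      }
      taper <- sin(pi * seq(0, 1, length.out = n))
      xy <- base + cbind(rnorm(n, 0, effects$base_noise_sd) * taper,
                         rnorm(n, 0, effects$base_noise_sd) * taper)
    }
    out[[i]] <- list(trial_id = tr$trial_id,
                     samples = cbind(x = xy[, 1], y = xy[, 2], t = tvec),
                     drawn_shape = drawn, is_swap = is_swap,
                     is_gross = is_gross)
  }
  out
}
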