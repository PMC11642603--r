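#' EEG generator parameters
#'
#' @param n_channels Number of channels (64 uses the bundled montage).
#' @param sfreq Sampling rate in Hz.
#' @param epoch_length Epoch length in seconds (epochs start at the cue).
#' @param condition_patterns Named list mapping `"context:combination"` to a
#'   channels x time mean pattern matrix, e.g. from
#'   [condition_patterns_preset()].
#' @param noise_sd SD of the additive Gaussian noise per channel and sample.
#' @param spatial_corr Mixing weight in [0, 1) of a channel-shared noise
#'   component (0 = independent channels).
#' @param seed Integer seed.
#' @return A list of class `eeg_gen_params`.
#' @export
eeg_gen_params <- function(n_channels = 64, sfreq = 128, epoch_length = 2.0,
                           condition_patterns = NULL, noise_sd = 1,
                           spatial_corr = 0.2, seed = 1L) {
  stopifnot(noise_sd > 0, spatial_corr >= 0, spatial_corr < 1)
  structure(list(n_channels = as.integer(n_channels), sfreq = sfreq,
                 epoch_length = epoch_length,
                 condition_patterns = condition_patterns,
                 noise_sd = noise_sd, spatial_corr = spatial_corr,
                 seed = as.integer(seed)),
            class = "eeg_gen_params")
}

#' Condition-mean pattern presets
#'
#' Builds the map from experimental condition to mean spatiotemporal
#' pattern.  Patterns are piecewise constant over `n_bins` equal temporal
#' segments (so their structure is at the temporal scale the decoding
#' pipeline analyses) and are linear combinations of two fixed random
#' direction matrices: an "own movement" direction `o` and a "partner
#' movement" direction `q`, each with unit Frobenius norm.
#'
#' * `"integrated"`: in the Parallel context the pattern is
#'   `(s/2) amp o + (p/2) amp q` (s, p = +1 for circle, -1 for diamond of
#'   the participant and partner), so every contrast is decodable; in the
#'   Joint context own and partner shares are fused into the common
#'   direction `o` with equal weights, so the two incongruent combinations
#'   share one pattern exactly while the congruent separation matches the
#'   Parallel context's.
#' * `"independent"`: both contexts use the Parallel structure.
#' * `"null"`: all conditions share the zero pattern.
#'
#' @param preset Preset name.
#' @param n_channels,sfreq,epoch_length Geometry of the patterns.
#' @param amp Pattern amplitude (Frobenius norm of each agent's full-swing
#'   separation), in noise-SD units.
#' @param n_bins Number of temporal segments.
#' @param seed Seed for the random directions.
#' @param contexts,combinations Condition grid.
#' @return Named list of channels x time matrices, names
#'   `"context:combination"`.
#' @export
condition_patterns_preset <- function(preset = c("integrated", "independent",
                                                 "null"),
                                      n_channels = 64, sfreq = 128,
                                      epoch_length = 2.0, amp = 0.35,
                                      n_bins = 10, seed = 1L,
                                      contexts = c("joint", "parallel"),
                                      combinations = c("CC", "DD", "CD",
                                                       "DC")) {
  preset <- match.arg(preset)
  n_time <- round(sfreq * epoch_length)
  set.seed(derive_seed(seed, 303))
  unit_dir <- function() {
    m <- matrix(rnorm(n_channels * n_bins), n_channels, n_bins)
    m <- m / sqrt(sum(m^2))
    # expand segments to the sample grid
    seg <- pmin(floor(seq(0, n_bins - 1e-9, length.out = n_time)) + 1,
                n_bins)
    m[, seg, drop = FALSE]
  }
  o <- unit_dir()
  q <- unit_dir()
  sgn <- function(ch) ifelse(ch == "C", 1, -1)
  out <- list()
  for (ctx in contexts) for (comb in combinations) {
    s <- sgn(substr(comb, 1, 1))
    p <- sgn(substr(comb, 2, 2))
    pat <- if (preset == "null") {
      matrix(0, n_channels, n_time)
    } else if (preset == "independent" || ctx == "parallel") {
      (s / 2) * amp * o + (p / 2) * amp * q
    } else {
      # integrated joint: both shares carried by the common direction o,
      # scaled so the congruent separation matches the parallel context
      a_j <- amp * sqrt(2) / 2
      ((s + p) / 2) * a_j * o
    }
    out[[paste(ctx, comb, sep = ":")]] <- pat
  }
  attr(out, "preset") <- preset
  attr(out, "amp") <- amp
  out
}

#' Scale a pattern map by a common factor
#'
#' Used to give simulated subjects heterogeneous signal amplitudes.
#'
#' @param patterns Named pattern list.
#' @param f Scalar factor.
#' @return Scaled pattern list (attributes preserved).
#' @export
scale_patterns <- function(patterns, f) {
  out <- lapply(patterns, function(m) m * f)
  attributes(out) <- attributes(patterns)
  out
}

#' Generate epoched EEG for a trial design
#'
#' Every epoch is its condition's mean pattern plus spatially correlated
#' Gaussian noise: `noise = sqrt(1 - rho) z_ct + sqrt(rho) z_t` with `z_ct`
#' independent over channels and `z_t` shared across channels.  Channel
#' names and flattened 2-D positions come from the bundled 64-channel
#' montage when `n_channels` is 64, otherwise from a generated ring layout.
#'
#' @param design Trial table from [generate_design()].
#' @param params An [eeg_gen_params()] with non-null `condition_patterns`.
#' @return An [epoch_set()].
#' @export
generate_epochs <- function(design, params) {
  stopifnot(inherits(params, "eeg_gen_params"))
  pats <- params$condition_patterns
  if (is.null(pats)) stop("condition_patterns must be provided")
  n_time <- round(params$sfreq * params$epoch_length)
  conds <- unique(paste(design$context, design$combination, sep = ":"))
  miss <- setdiff(conds, names(pats))
  if (length(miss))
    stop("no condition pattern for: ", paste(miss, collapse = ", "))
  for (cn in conds)
    if (!all(dim(pats[[cn]]) == c(params$n_channels, n_time)))
      stop("pattern ", cn, " has wrong dimensions")
  set.seed(derive_seed(params$seed, 404))
  n <- nrow(design)
  nch <- params$n_channels
  rho <- params$spatial_corr
  dat <- array(NA_real_, c(n, nch, n_time))
  for (i in seq_len(n)) {
    z <- matrix(rnorm(nch * n_time), nch, n_time)
    if (rho > 0) {
      shared <- matrix(rnorm(n_time), 1, n_time)
      z <- sqrt(1 - rho) * z + sqrt(rho) * shared[rep(1, nch), ]
    }
    dat[i, , ] <- pats[[paste(design$context[i], design$combination[i],
                              sep = ":")]] + params$noise_sd * z
  }
  mont <- default_montage(nch)
  epoch_set(dat, params$sfreq, design, channel_names = mont$channel,
            channel_pos = as.matrix(mont[, c("x", "y")]))
}

#' Bundled or generated sensor montage
#'
#' For 64 channels, loads the packaged synthetic 64-sensor flattened layout
#' (concentric rings with deterministic angular offsets, labelled E01-E64;
#' an idealised stand-in for a standard 64-electrode arrangement).  For
#' other channel counts, generates a comparable ring layout.
#'
#' @param n_channels Number of channels.
#' @return `data.frame` with columns `channel`, `x`, `y`.
#' @export
default_montage <- function(n_channels = 64) {
  if (n_channels == 64) {
    f <- system.file("extdata", "montage64_synthetic.csv",
                     package = "dyadicdraw")
    return(read.csv(f, stringsAsFactors = FALSE))
  }
  # generated ring layout for reduced-channel simulations
  n_rings <- max(1, ceiling(n_channels / 12))
  left <- n_channels - 1
  per_ring <- rep(floor(left / n_rings), n_rings)
  if (left %% n_rings) per_ring[seq_len(left %% n_rings)] <-
      per_ring[seq_len(left %% n_rings)] + 1
  x <- 0; y <- 0
  for (r in seq_len(n_rings)) {
    nr <- per_ring[r]
    if (nr == 0) next
    ang <- (r * pi / exp(1)) + 2 * pi * (seq_len(nr) - 1) / nr
    rad <- (r / n_rings) * (1 + 0.013 * sin(7 * ang + r))
    x <- c(x, rad * sin(ang)); y <- c(y, rad * cos(ang))
  }
  data.frame(channel = sprintf("E%02d", seq_len(n_channels)),
             x = x[seq_len(n_channels)], y = y[seq_len(n_channels)])
}
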