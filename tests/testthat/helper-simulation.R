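# shared builders for small simulated datasets

# minimal trial table accepted by generate_trajectories
fake_design <- function(n, own = "circle", partner = own, context = "parallel",
                        duration = 2) {
  data.frame(trial_id = seq_len(n), context = context,
             combination = paste0(toupper(substr(own, 1, 1)),
                                  toupper(substr(partner, 1, 1))),
             own_shape = own, partner_shape = partner,
             partner_cued_shape = partner, cue_pair = 1L, is_catch = FALSE,
             congruency = ifelse(own == partner, "congruent", "incongruent"),
             start_time = 0.3, partner_start = 0.3, partner_duration = 2,
             drawing_duration = duration, delta_time = 0,
             catch_response = FALSE, stringsAsFactors = FALSE)
}

# a small epoch set with one context and enough trials per cue-pair cell
small_epochs <- function(preset = "integrated", n_channels = 16, sfreq = 32,
                         trials_per_block = 48, n_blocks = 2,
                         contexts = "parallel", amp = 0.35, noise_sd = 1,
                         seed = 1) {
  dp <- design_params(n_blocks_per_context = n_blocks,
                      trials_per_block = trials_per_block,
                      catch_per_block = 0, contexts = contexts,
                      seed = derive_seed(seed, 11))
  d <- generate_design(dp)
  pats <- condition_patterns_preset(preset, n_channels = n_channels,
                                    sfreq = sfreq, amp = amp,
                                    seed = derive_seed(seed, 12),
                                    contexts = unique(d$context))
  ep <- eeg_gen_params(n_channels = n_channels, sfreq = sfreq,
                       condition_patterns = pats, noise_sd = noise_sd,
                       seed = derive_seed(seed, 13))
  generate_epochs(d, ep)
}

# shape sampled with iid coordinate noise
noisy_shape <- function(shape, sd = 3, n = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ideal_shape(shape, n) + matrix(rnorm(2 * n, 0, sd), n, 2)
}

# smooth random pair of curves, both strictly monotone in y
resampled_pair <- function() {
  y <- seq(400, 0, length.out = 100)
  wob <- function() {
    k <- rnorm(3, 0, 30)
    k[1] * sin(y / 400 * pi) + k[2] * sin(y / 400 * 2 * pi) +
      k[3] * cos(y / 400 * 3 * pi)
  }
  list(A = cbind(x = wob(), y = y), B = cbind(x = wob(), y = y))
}
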