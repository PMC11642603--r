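#' Configuration for a full simulated study
#'
#' Collects every knob of the end-to-end pipeline.  Defaults mirror the
#' standard session (6 blocks of 48 trials with 8 catch trials per block
#' and context, 10 supertrials of 4 averaged trials, 10 bins over the 0-2 s
#' delay window, 5 folds, 100 permutations) with an integrated-preset EEG
#' generator; `n_subjects`, `n_perm` and the EEG geometry can be scaled
#' down for quick runs.
#'
#' @param n_subjects Number of simulated participants.
#' @param design A [design_params()] object (per-subject seeds are derived
#'   from `master_seed`).
#' @param effects A [trajectory_effects()] object.
#' @param eeg_preset Pattern preset name, see [condition_patterns_preset()].
#' @param amp Pattern amplitude in noise-SD units.
#' @param subject_amp_sdlog SD (log scale) of the per-subject lognormal
#'   signal-amplitude multiplier (mean 1); 0 disables heterogeneity.
#' @param n_channels,sfreq,epoch_length EEG geometry.
#' @param noise_sd,spatial_corr Noise model, see [eeg_gen_params()].
#' @param contrasts Character vector of contrasts to decode.
#' @param n_super,n_avg,n_bins,window,k_folds,n_perm Decoding parameters.
#' @param run_decoding,run_trajectories,run_spatial Stage switches.
#' @param spatial_contrasts Contrasts for channelwise decoding (can be a
#'   subset; channelwise decoding is by far the most expensive stage).
#' @param cluster_n_perm Permutations for the cluster test.
#' @param alpha Significance level used in the report summary.
#' @param master_seed Master seed; every stage derives child seeds from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_subjects = 36,
                         design = design_params(),
                         effects = trajectory_effects(),
                         eeg_preset = "integrated",
                         amp = 0.35,
                         subject_amp_sdlog = 0.6,
                         n_channels = 64, sfreq = 128, epoch_length = 2.0,
                         noise_sd = 1, spatial_corr = 0.2,
                         contrasts = c("incongruent_combo",
                                       "congruent_combo", "own_movement",
                                       "partner_movement"),
                         n_super = 10, n_avg = 4, n_bins = 10,
                         window = c(0, 2), k_folds = 5, n_perm = 100,
                         run_decoding = TRUE, run_trajectories = TRUE,
                         run_spatial = FALSE,
                         spatial_contrasts = "congruent_combo",
                         cluster_n_perm = 1000,
                         alpha = 0.05,
                         master_seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  cfg
}

#' Run a complete simulated study
#'
#' Simulates every participant (design, trajectories, epoched EEG), runs
#' the trajectory-distortion pipeline and its group statistics, the four
#' decoding contrasts in both contexts with empirical and label-shuffled
#' null accuracies, the group-level decoding tests, and (optionally)
#' channelwise decoding with cluster-based inference.  Returns a report
#' bundle; identical `master_seed`s give identical reports.
#'
#' @param config A [study_config()].
#' @param out Optional directory; if given, the report is written as
#'   `report.json` plus CSV tables.
#' @param verbose Print per-stage progress.
#' @return A list with `behavior`, `vmi`, `decoding`, `spatial` (or NULL),
#'   `config_digest` and `seeds`.
#' @export
run_study <- function(config = study_config(), out = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  pats0 <- condition_patterns_preset(config$eeg_preset,
                                     n_channels = config$n_channels,
                                     sfreq = config$sfreq,
                                     epoch_length = config$epoch_length,
                                     amp = config$amp,
                                     n_bins = config$n_bins,
                                     seed = config$master_seed)
  all_rec <- list()
  all_counts <- list()
  behav <- list()
  dec_rows <- list()
  acc_maps <- list()
  for (s in seq_len(config$n_subjects)) {
    say("subject %d / %d", s, config$n_subjects)
    dp <- config$design
    dp$seed <- derive_seed(config$master_seed, s, 1)
    design <- generate_design(dp)
    behav[[s]] <- data.frame(
      subject = s,
      catch_acc_joint = mean(design$catch_response[design$is_catch &
                                                     design$context ==
                                                     "joint"]),
      catch_acc_parallel = mean(design$catch_response[design$is_catch &
                                                        design$context ==
                                                        "parallel"]),
      delta_joint = mean(design$delta_time[design$context == "joint" &
                                             !design$is_catch]),
      duration_parallel = mean(design$drawing_duration[design$context ==
                                                         "parallel" &
                                                         !design$is_catch]))
    if (config$run_trajectories) {
      ef <- config$effects
      ef$seed <- derive_seed(config$master_seed, s, 2)
      trs <- generate_trajectories(design, ef)
      sc <- score_trajectories(trs, design)
      rec <- sc$records
      rec$subject <- s
      all_rec[[s]] <- rec
      dropped <- design[!design$is_catch, ][sc$gross | sc$swap, ]
      cnt <- expand.grid(context = unique(design$context),
                         congruency = c("congruent", "incongruent"),
                         stringsAsFactors = FALSE)
      cnt$count <- mapply(function(ctx, cg)
        sum(dropped$context == ctx & dropped$congruency == cg),
        cnt$context, cnt$congruency)
      cnt$subject <- s
      all_counts[[s]] <- cnt
    }
    if (config$run_decoding) {
      amp_f <- if (config$subject_amp_sdlog > 0) {
        set.seed(derive_seed(config$master_seed, s, 3))
        exp(rnorm(1, -config$subject_amp_sdlog^2 / 2,
                  config$subject_amp_sdlog))
      } else 1
      ep <- eeg_gen_params(n_channels = config$n_channels,
                           sfreq = config$sfreq,
                           epoch_length = config$epoch_length,
                           condition_patterns = scale_patterns(pats0, amp_f),
                           noise_sd = config$noise_sd,
                           spatial_corr = config$spatial_corr,
                           seed = derive_seed(config$master_seed, s, 4))
      epochs <- generate_epochs(design, ep)
      ci <- 0
      for (cname in config$contrasts) for (ctx in c("joint", "parallel")) {
        ci <- ci + 1
        cs <- contrast_spec(cname, ctx)
        emp <- run_contrast(epochs, cs, n_super = config$n_super,
                            n_avg = config$n_avg, window = config$window,
                            n_bins = config$n_bins,
                            k_folds = config$k_folds,
                            n_perm = config$n_perm,
                            seed = derive_seed(config$master_seed, s, 5, ci))
        nul <- run_null(epochs, cs, n_super = config$n_super,
                        n_avg = config$n_avg, window = config$window,
                        n_bins = config$n_bins, k_folds = config$k_folds,
                        n_perm = config$n_perm,
                        seed = derive_seed(config$master_seed, s, 6, ci))
        dec_rows[[length(dec_rows) + 1]] <- data.frame(
          subject = s, contrast = cname, context = ctx,
          empirical = emp$empirical_acc, null = nul$null_acc)
        if (config$run_spatial && cname %in% config$spatial_contrasts) {
          cm <- channelwise_decode(epochs, cs, n_super = config$n_super,
                                   n_avg = config$n_avg,
                                   window = config$window,
                                   n_bins = config$n_bins,
                                   k_folds = config$k_folds,
                                   n_perm = max(1, config$n_perm %/% 5),
                                   seed = derive_seed(config$master_seed,
                                                      s, 7, ci))
          key <- paste(cname, ctx, sep = ":")
          acc_maps[[key]] <- rbind(acc_maps[[key]], cm$acc)
        }
      }
    }
  }
  behav <- do.call(rbind, behav)
  report <- list(seeds = list(master_seed = config$master_seed),
                 config_digest = config_digest(config))
  report$behavior <- list(
    catch_wilcoxon = if (nrow(behav) >= 5)
      wilcoxon_signed_rank(behav$catch_acc_joint, behav$catch_acc_parallel),
    delta_t = one_sample_t(behav$delta_joint, 0),
    parallel_duration_t = one_sample_t(behav$duration_parallel, 2),
    table = behav)
  if (config$run_trajectories) {
    rec <- transform_distortions(do.call(rbind, all_rec))
    lmm <- fit_vmi_lmm(rec)
    ce <- congruency_effect(rec)
    glm_counts <- fit_count_glm(do.call(rbind, all_counts))
    report$vmi <- list(lambda = attr(rec, "lambda"),
                       skewness = attr(rec, "skewness"),
                       kurtosis = attr(rec, "kurtosis"),
                       lmm = lmm$coefficients, lmm_converged = lmm$converged,
                       congruency_test = ce$test,
                       congruency_effects = ce$effects,
                       discarded_glm = glm_counts$coefficients)
  }
  if (config$run_decoding) {
    dec <- do.call(rbind, dec_rows)
    report$decoding <- c(group_decoding_tests(dec), list(table = dec))
  }
  if (config$run_spatial && length(acc_maps)) {
    adj <- build_adjacency(default_montage(config$n_channels)[, c("x", "y")])
    report$spatial <- lapply(acc_maps, function(m)
      cluster_permutation_test(m, 0.5, adj$adjacency,
                               n_perm = config$cluster_n_perm,
                               seed = derive_seed(config$master_seed, 8)))
  }
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_report_json(strip_tables(report), file.path(out, "report.json"))
    if (config$run_decoding)
      write.csv(report$decoding$table,
                file.path(out, "decoding_accuracies.csv"),
                row.names = FALSE)
    if (config$run_trajectories)
      write.csv(report$vmi$congruency_effects,
                file.path(out, "congruency_effects.csv"), row.names = FALSE)
  }
  report
}

config_digest <- function(config) {
  flat <- unlist(config[!vapply(config, is.function, logical(1))])
  sum(utf8ToInt(paste(names(flat), flat, collapse = "|", sep = "="))) %%
    1000000007
}

strip_tables <- function(x) {
  if (is.list(x)) {
    x$table <- NULL
    lapply(x, strip_tables)
  } else x
}
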