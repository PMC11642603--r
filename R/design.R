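#' Parameters of the dyadic drawing task design
#'
#' Bundles every constant that defines the trial structure of one simulated
#' session.  Defaults reproduce the standard session: 6 blocks of 48 trials
#' per social context, 8 catch trials per block, four shape combinations
#' (CC, DD, CD, DC; first letter the participant's shape, second the
#' partner's), two cue pairs, partner movement durations drawn uniformly from
#' 1.8-2.2 s in the Joint context and 1.6-2.4 s in the Parallel context, a
#' partner start time jittered +/-100 ms around the participant's average
#' start, a maximum allowed start time of 800 ms and a 200 ms synchronisation
#' criterion.
#'
#' @param n_blocks_per_context Blocks per social context.
#' @param trials_per_block Trials per block (must be divisible by the number
#'   of combinations; the per-cell non-catch and catch counts must also be
#'   integral for the design to be balanced).
#' @param catch_per_block Catch trials per block (partner draws the non-cued
#'   shape).
#' @param contexts Character vector of social contexts.
#' @param combinations Character vector of shape combinations.
#' @param partner_duration_joint,partner_duration_parallel Length-2 numeric:
#'   bounds of the uniform partner movement duration (seconds) per context.
#' @param partner_start_jitter Half-width (seconds) of the uniform jitter of
#'   the partner's start time around the participant's mean start time.
#' @param max_start_time Maximum allowed participant start time (seconds).
#' @param delta_criterion Joint-context synchronisation criterion (seconds).
#' @param start_time_mean,start_time_sd Mean and SD of the participant's
#'   start time (seconds); draws are truncated at `max_start_time`.
#' @param delta_mean,delta_sd Mean and between-subject SD of the
#'   participant's average Joint-context delta time (own end minus partner
#'   end, seconds); the subject-level offset is drawn once per session.
#' @param delta_trial_sd Trial-to-trial SD of the delta time around the
#'   subject's offset.
#' @param parallel_duration_mean,parallel_duration_sd Mean and
#'   between-subject SD of the participant's average drawing duration
#'   (seconds) in the Parallel context.
#' @param duration_trial_sd Trial-to-trial SD of the Parallel drawing
#'   duration around the subject's mean.
#' @param catch_detect_prob Named numeric, mean probability of correctly
#'   flagging a catch trial in each context.
#' @param catch_detect_sd Between-subject SD of the catch-detection
#'   probability (subject-level draws are clamped to [0.5, 0.999]).
#' @param false_alarm_prob Probability of wrongly flagging a regular trial.
#' @param seed Integer seed.
#' @return A list of class `design_params`.
#' @seealso [generate_design()]
#' @examples
#' p <- design_params(seed = 1)
#' p$trials_per_block
#' @export
design_params <- function(n_blocks_per_context = 6,
                          trials_per_block = 48,
                          catch_per_block = 8,
                          contexts = c("joint", "parallel"),
                          combinations = c("CC", "DD", "CD", "DC"),
                          partner_duration_joint = c(1.8, 2.2),
                          partner_duration_parallel = c(1.6, 2.4),
                          partner_start_jitter = 0.100,
                          max_start_time = 0.800,
                          delta_criterion = 0.200,
                          start_time_mean = 0.350,
                          start_time_sd = 0.080,
                          delta_mean = 0.01,
                          delta_sd = 0.051,
                          delta_trial_sd = 0.05,
                          parallel_duration_mean = 1.93,
                          parallel_duration_sd = 0.15,
                          duration_trial_sd = 0.1,
                          catch_detect_prob = c(joint = 0.94, parallel = 0.92),
                          catch_detect_sd = 0.04,
                          false_alarm_prob = 0.01,
                          seed = 1L) {
  p <- list(n_blocks_per_context = as.integer(n_blocks_per_context),
            trials_per_block = as.integer(trials_per_block),
            catch_per_block = as.integer(catch_per_block),
            contexts = contexts, combinations = combinations,
            cue_pairs = 1:2,
            partner_duration_joint = partner_duration_joint,
            partner_duration_parallel = partner_duration_parallel,
            partner_start_jitter = partner_start_jitter,
            max_start_time = max_start_time,
            delta_criterion = delta_criterion,
            start_time_mean = start_time_mean,
            start_time_sd = start_time_sd,
            delta_mean = delta_mean, delta_sd = delta_sd,
            delta_trial_sd = delta_trial_sd,
            parallel_duration_mean = parallel_duration_mean,
            duration_trial_sd = duration_trial_sd,
            catch_detect_sd = catch_detect_sd,
            parallel_duration_sd = parallel_duration_sd,
            catch_detect_prob = catch_detect_prob,
            false_alarm_prob = false_alarm_prob,
            seed = as.integer(seed))
  validate_design_params(p)
  class(p) <- "design_params"
  p
}

validate_design_params <- function(p) {
  nc <- length(p$combinations)
  if (p$trials_per_block %% nc != 0)
    stop("trials_per_block must be divisible by the number of combinations")
  if (p$catch_per_block >= p$trials_per_block)
    stop("catch_per_block must be smaller than trials_per_block")
  ncatch_ctx <- p$n_blocks_per_context * p$catch_per_block
  if (ncatch_ctx %% nc != 0)
    stop("catch trials per context not divisible across combinations: ",
         "infeasible balance")
  noncatch_cell <- p$n_blocks_per_context * p$trials_per_block / nc -
    ncatch_ctx / nc
  if (noncatch_cell <= 0 || noncatch_cell %% 1 != 0)
    stop("non-catch trials per cell not a positive integer: ",
         "infeasible balance")
  for (iv in list(p$partner_duration_joint, p$partner_duration_parallel)) {
    if (length(iv) != 2 || any(iv <= 0) || iv[1] >= iv[2])
      stop("duration intervals must be positive with low < high")
  }
  invisible(p)
}

#' Generate a balanced trial design
#'
#' Builds the full trial table of one simulated session.  Within every
#' context, combination cells are balanced exactly: each context x
#' combination cell receives the same number of non-catch and the same number
#' of catch trials, and cue pairs are balanced within each cell (cue pairs
#' alternate across blocks, so each cell sees each cue pair in half of the
#' blocks).  Catch trials are trials in which the partner actually draws the
#' shape opposite to the partner's cue.  Timing fields (start time, partner
#' duration/start, drawing duration, delta time) and catch responses are
#' drawn from the distributions in `params`.
#'
#' @param params A [design_params()] object.
#' @return A `data.frame` with one row per trial and columns `trial_id`,
#'   `context`, `block`, `combination`, `own_shape`, `partner_shape`
#'   (the shape the partner actually draws), `cue_pair`, `is_catch`,
#'   `congruency`, `start_time`, `partner_start`, `partner_duration`,
#'   `drawing_duration`, `delta_time`, `catch_response`.
#' @examples
#' d <- generate_design(design_params(seed = 7))
#' nrow(d)                       # 576 trials
#' table(d$context, d$combination)
#' @export
generate_design <- function(params = design_params()) {
  validate_design_params(params)
  p <- params
  set.seed(derive_seed(p$seed, 101))
  # subject-level traits: the printed SDs describe between-subject spread
  # of per-participant means, so one offset is drawn per session
  subj_delta <- rnorm(1, p$delta_mean, p$delta_sd)
  subj_par_dur <- rnorm(1, p$parallel_duration_mean, p$parallel_duration_sd)
  subj_detect <- setNames(
    pmin(pmax(rnorm(length(p$contexts), p$catch_detect_prob[p$contexts],
                    p$catch_detect_sd), 0.5), 0.999), p$contexts)
  nc <- length(p$combinations)
  per_block_comb <- p$trials_per_block / nc
  catch_per_comb_block <- p$catch_per_block / nc   # may be fractional; balance
  rows <- list()
  tid <- 0L
  for (ctx in p$contexts) {
    # distribute catch trials over blocks x combinations so that each
    # combination gets the same total catch count within the context
    catch_total_comb <- p$n_blocks_per_context * p$catch_per_block / nc
    catch_alloc <- matrix(0L, p$n_blocks_per_context, nc)
    # round-robin fill: block-by-block assign catch slots cycling combinations
    comb_cycle <- rep(seq_len(nc), length.out = p$n_blocks_per_context *
                        p$catch_per_block)
    k <- 1
    for (b in seq_len(p$n_blocks_per_context)) {
      for (j in seq_len(p$catch_per_block)) {
        catch_alloc[b, comb_cycle[k]] <- catch_alloc[b, comb_cycle[k]] + 1L
        k <- k + 1
      }
    }
    stopifnot(all(colSums(catch_alloc) == catch_total_comb))
    mean_start <- p$start_time_mean
    for (b in seq_len(p$n_blocks_per_context)) {
      cue <- ifelse(b %% 2 == 1, 1L, 2L)
      block_rows <- list()
      for (ci in seq_len(nc)) {
        comb <- p$combinations[ci]
        n_catch_here <- catch_alloc[b, ci]
        n_tr <- per_block_comb
        is_catch <- c(rep(TRUE, n_catch_here), rep(FALSE, n_tr - n_catch_here))
        for (i in seq_len(n_tr)) {
          tid <- tid + 1L
          own <- ifelse(substr(comb, 1, 1) == "C", "circle", "diamond")
          partner_cued <- ifelse(substr(comb, 2, 2) == "C", "circle",
                                 "diamond")
          partner_drawn <- if (is_catch[i]) other_shape(partner_cued) else
            partner_cued
          st <- min(abs(rnorm(1, p$start_time_mean, p$start_time_sd)),
                    p$max_start_time - 1e-3)
          pd <- if (ctx == "joint")
            runif(1, p$partner_duration_joint[1], p$partner_duration_joint[2])
          else
            runif(1, p$partner_duration_parallel[1],
                  p$partner_duration_parallel[2])
          ps <- runif(1, mean_start - p$partner_start_jitter,
                      mean_start + p$partner_start_jitter)
          if (ctx == "joint") {
            delta <- rnorm(1, subj_delta, p$delta_trial_sd)
            dur <- max(0.8, ps + pd + delta - st)
          } else {
            dur <- max(0.8, rnorm(1, subj_par_dur, p$duration_trial_sd))
            delta <- (st + dur) - (ps + pd)
          }
          resp <- if (is_catch[i])
            rbinom(1, 1, subj_detect[[ctx]]) == 1
          else rbinom(1, 1, p$false_alarm_prob) == 1
          block_rows[[length(block_rows) + 1]] <- data.frame(
            trial_id = tid, context = ctx, block = b, combination = comb,
            own_shape = own, partner_shape = partner_drawn,
            partner_cued_shape = partner_cued,
            cue_pair = cue, is_catch = is_catch[i],
            congruency = ifelse(comb %in% c("CC", "DD"), "congruent",
                                "incongruent"),
            start_time = st, partner_start = ps, partner_duration = pd,
            drawing_duration = dur, delta_time = delta,
            catch_response = resp, stringsAsFactors = FALSE)
        }
      }
      block_df <- do.call(rbind, block_rows)
      # shuffle presentation order within the block
      block_df <- block_df[sample.int(nrow(block_df)), ]
      rows[[length(rows) + 1]] <- block_df
      mean_start <- mean(block_df$start_time)   # adaptive partner start
    }
  }
  out <- do.call(rbind, rows)
  out$trial_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Trials usable for EEG decoding
#'
#' Regular trials that were not falsely flagged as catch trials, plus catch
#' trials that were correctly detected: only these carry an accurate
#' representation of the partner's cued shape through the delay period.
#'
#' @param design A design `data.frame` from [generate_design()].
#' @return Logical vector over rows of `design`.
#' @export
usable_trials <- function(design) {
  ifelse(design$is_catch, design$catch_response, !design$catch_response)
}
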