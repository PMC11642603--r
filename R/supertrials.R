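#' Epoched EEG container
#'
#' Validating constructor for the epochs container used by all decoding
#' functions.
#'
#' @param data Numeric array, trials x channels x time.
#' @param sfreq Sampling rate in Hz.
#' @param labels `data.frame` of per-trial condition labels (one row per
#'   trial; must contain `context`, `combination`, `cue_pair`, `is_catch`,
#'   `catch_response`).
#' @param channel_names Character vector, one name per channel.
#' @param channel_pos Channels x 2 matrix of flattened sensor positions.
#' @param tmin Time (seconds, relative to cue onset) of the first sample.
#' @return A list of class `epoch_set` with a `times` vector.
#' @export
epoch_set <- function(data, sfreq, labels, channel_names = NULL,
                      channel_pos = NULL, tmin = 0) {
  stopifnot(length(dim(data)) == 3)
  if (nrow(labels) != dim(data)[1])
    stop("trial count (", dim(data)[1], ") does not match label rows (",
         nrow(labels), ")")
  need <- c("context", "combination", "cue_pair", "is_catch",
            "catch_response")
  miss <- setdiff(need, names(labels))
  if (length(miss)) stop("labels missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(channel_names))
    channel_names <- sprintf("E%02d", seq_len(dim(data)[2]))
  if (length(channel_names) != dim(data)[2])
    stop("channel_names length does not match channel dimension")
  structure(list(data = data, sfreq = sfreq,
                 times = tmin + (seq_len(dim(data)[3]) - 1) / sfreq,
                 labels = labels, channel_names = channel_names,
                 channel_pos = channel_pos),
            class = "epoch_set")
}

#' Specification of a two-class decoding contrast
#'
#' The four contrasts: `incongruent_combo` (CD vs DC) and `congruent_combo`
#' (CC vs DD) discriminate whole movement combinations with pure supertrials
#' (all averaged trials from one condition, balanced over cue pairs);
#' `own_movement` (CC+CD vs DC+DD) and `partner_movement` (CC+DC vs CD+DD)
#' discriminate one agent's shape with mixed supertrials (one trial from
#' each condition x cue-pair cell of the class).
#'
#' @param name One of `"incongruent_combo"`, `"congruent_combo"`,
#'   `"own_movement"`, `"partner_movement"`.
#' @param context Social context the contrast is evaluated in.
#' @return A list of class `contrast_spec`: `name`, `context`, `classes`
#'   (named list of combination sets), `recipe` (`"pure"` or `"mixed"`).
#' @export
contrast_spec <- function(name = c("incongruent_combo", "congruent_combo",
                                   "own_movement", "partner_movement"),
                          context = c("joint", "parallel")) {
  name <- match.arg(name)
  context <- match.arg(context)
  classes <- switch(name,
    incongruent_combo = list(CD = "CD", DC = "DC"),
    congruent_combo = list(CC = "CC", DD = "DD"),
    own_movement = list(circle = c("CC", "CD"), diamond = c("DC", "DD")),
    partner_movement = list(circle = c("CC", "DC"), diamond = c("CD", "DD")))
  structure(list(name = name, context = context, classes = classes,
                 recipe = if (name %in% c("own_movement",
                                          "partner_movement"))
                   "mixed" else "pure"),
            class = "contrast_spec")
}

# sample the member trials of every supertrial for one permutation;
# consumes the current RNG stream; returns list(class=, members=) entries
sample_supertrial_members <- function(labels, contrast, n_super = 10,
                                      n_avg = 4) {
  cue_levels <- sort(unique(labels$cue_pair))
  if (length(cue_levels) != 2)
    stop("supertrial construction needs exactly two cue pairs")
  out <- list()
  for (cl in names(contrast$classes)) {
    conds <- contrast$classes[[cl]]
    cells <- expand.grid(combination = conds, cue_pair = cue_levels,
                         stringsAsFactors = FALSE)
    if (contrast$recipe == "pure") {
      need_per_cell <- n_super * n_avg / 2
      if (n_avg %% 2 != 0)
        stop("pure-condition supertrials need an even n_avg")
    } else {
      if (n_avg != nrow(cells))
        stop("mixed supertrials average one trial per condition x cue-pair ",
             "cell; n_avg must equal ", nrow(cells))
      need_per_cell <- n_super
    }
    draws <- list()
    for (ci in seq_len(nrow(cells))) {
      idx <- which(labels$context == contrast$context &
                     labels$combination == cells$combination[ci] &
                     labels$cue_pair == cells$cue_pair[ci])
      if (length(idx) < need_per_cell)
        stop("insufficient trials in cell ", contrast$context, ":",
             cells$combination[ci], ":cue", cells$cue_pair[ci], " (have ",
             length(idx), ", need ", need_per_cell, ")")
      draws[[ci]] <- sample(idx, need_per_cell)   # without replacement
    }
    for (s in seq_len(n_super)) {
      members <- if (contrast$recipe == "pure") {
        per_cue <- n_avg / 2
        unlist(lapply(draws, function(d)
          d[((s - 1) * per_cue + 1):(s * per_cue)]))
      } else {
        vapply(draws, function(d) d[s], numeric(1))
      }
      out[[length(out) + 1]] <- list(class = cl, members = members)
    }
  }
  out
}

#' Build supertrials by averaging randomly sampled trials
#'
#' Averages sets of `n_avg` same-class trials into higher signal-to-noise
#' "supertrials", balanced over cue pairs: pure-condition contrasts average
#' `n_avg` trials of one condition, half from each cue pair; mixed contrasts
#' average one trial from each condition x cue-pair cell of the class.
#' Sampling is without replacement within one call.
#'
#' @param epochs An [epoch_set()].
#' @param contrast A [contrast_spec()].
#' @param n_super Supertrials per class.
#' @param n_avg Trials averaged into each supertrial.
#' @param seed Optional seed for the draw.
#' @return List of supertrials: `data` (channels x time), `class_label`,
#'   `members` (trial indices).
#' @export
make_supertrials <- function(epochs, contrast, n_super = 10, n_avg = 4,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sel <- sample_supertrial_members(epochs$labels, contrast, n_super, n_avg)
  lapply(sel, function(s) {
    sl <- epochs$data[s$members, , , drop = FALSE]
    list(data = apply(sl, c(2, 3), mean), class_label = s$class,
         members = s$members)
  })
}

#' Remove each channel's temporal mean from a supertrial
#'
#' @param supertrial A supertrial from [make_supertrials()] or a channels x
#'   time matrix.
#' @return Same structure with every channel's temporal mean equal to zero.
#' @export
demean_supertrial <- function(supertrial) {
  if (is.list(supertrial)) {
    supertrial$data <- supertrial$data - rowMeans(supertrial$data)
    supertrial
  } else {
    supertrial - rowMeans(supertrial)
  }
}

#' Average a channels x time matrix into temporal bins
#'
#' Splits the analysis window into `n_bins` half-open intervals
#' `[k w, (k+1) w)` on the time axis and averages, per channel, the samples
#' whose timestamps fall inside each interval (bins therefore contain 25 or
#' 26 samples at 128 Hz with 200 ms bins).  Features are returned
#' channel-major: all bins of channel 1, then channel 2, and so on.
#'
#' @param supertrial A supertrial (list) or channels x time matrix.
#' @param times Sample times in seconds (taken from the supertrial's source
#'   [epoch_set()]).
#' @param window Length-2 analysis window in seconds.
#' @param n_bins Number of bins.
#' @return Numeric feature vector of length `channels * n_bins`.
#' @export
bin_features <- function(supertrial, times, window = c(0, 2), n_bins = 10) {
  dat <- if (is.list(supertrial)) supertrial$data else supertrial
  W <- bin_weights(times, window, n_bins)
  as.vector(t(dat %*% W))
}

# column-stochastic matrix mapping time samples to bin means
bin_weights <- function(times, window = c(0, 2), n_bins = 10) {
  dt <- times[2] - times[1]
  if (window[1] < times[1] - 1e-9 ||
      window[2] > times[length(times)] + dt + 1e-9)
    stop("analysis window [", window[1], ", ", window[2],
         ") outside the epoch's time span")
  width <- (window[2] - window[1]) / n_bins
  bin <- floor((times - window[1]) / width + 1e-9) + 1
  bin[times < window[1] - 1e-9 | bin > n_bins] <- NA
  W <- matrix(0, length(times), n_bins)
  for (b in seq_len(n_bins)) {
    inb <- which(bin == b)
    if (length(inb) == 0) stop("empty time bin ", b)
    W[inb, b] <- 1 / length(inb)
  }
  W
}
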