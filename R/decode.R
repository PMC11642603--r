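#' Stratified k-fold cross-validated decoding accuracy
#'
#' Splits the samples into `k` stratified folds (equal class composition in
#' every fold), trains the shrinkage LDA on the remaining folds, and returns
#' the accuracy averaged over the `k` test folds.  With the default pool of
#' 10 + 10 supertrials this yields training sets of 16 and test sets of 4.
#'
#' @param X Feature matrix (samples x features).
#' @param y Class labels (two classes of equal size divisible by `k`).
#' @param k Number of folds.
#' @return Mean accuracy over folds.
#' @export
crossval_decode <- function(X, y, k = 5) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("need exactly two classes")
  fold <- stratified_folds(y, k)
  accs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- fit_lda(X[tr, , drop = FALSE], y[tr])
    mean(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(accs)
}

# random stratified fold assignment; every fold receives the same number of
# samples from every class
stratified_folds <- function(y, k) {
  counts <- table(y)
  if (length(unique(counts)) != 1 || any(counts %% k != 0))
    stop("class sizes must be equal and divisible by k for stratified folds")
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# precompute, per usable trial, the binned feature matrix and the per-channel
# temporal means over the analysis epoch; averaging these over supertrial
# members and subtracting the replicated channel means is algebraically
# identical to average -> demean -> bin on the raw data
precompute_trial_features <- function(epochs, window = c(0, 2),
                                      n_bins = 10) {
  n <- dim(epochs$data)[1]
  nch <- dim(epochs$data)[2]
  W <- bin_weights(epochs$times, window, n_bins)
  # collapse (trial, channel) onto rows: element (i, c, t) sits at row
  # i + (c - 1) n, so one matrix product bins every trial at once
  A <- matrix(epochs$data, n * nch, dim(epochs$data)[3])
  BF <- A %*% W
  Mflat <- rowMeans(A)
  F <- matrix(NA_real_, n, nch * n_bins)
  for (ch in seq_len(nch))
    F[, ((ch - 1) * n_bins + 1):(ch * n_bins)] <-
      BF[((ch - 1) * n + 1):(ch * n), , drop = FALSE]
  list(F = F, M = matrix(Mflat, n, nch), n_bins = n_bins)
}

supertrial_features <- function(pre, members_list) {
  n_bins <- pre$n_bins
  t(vapply(members_list, function(m) {
    f <- colMeans(pre$F[m, , drop = FALSE])
    ch_mean <- colMeans(pre$M[m, , drop = FALSE])
    f - rep(ch_mean, each = n_bins)
  }, numeric(ncol(pre$F))))
}

#' Run the empirical decoding pipeline for one contrast
#'
#' Repeats the whole classification pipeline `n_perm` times -- fresh
#' supertrial sampling, per-channel demeaning, temporal binning, stratified
#' k-fold shrinkage-LDA classification -- and averages the resulting
#' accuracies.  Only usable trials enter (regular trials without a false
#' alarm, catch trials correctly detected).  Fully reproducible given
#' `seed`: permutation `i` uses the child seed `derive_seed(seed, i)`.
#'
#' @param epochs An [epoch_set()].
#' @param contrast A [contrast_spec()].
#' @param n_super,n_avg Supertrial recipe, see [make_supertrials()].
#' @param window,n_bins Temporal binning, see [bin_features()].
#' @param k_folds Cross-validation folds.
#' @param n_perm Number of pipeline repetitions.
#' @param seed Integer seed.
#' @return A `decoding_result` list: `empirical_acc` (mean over
#'   permutations), `per_perm_acc`, `contrast`, `n_perm`, `seed`.
#' @export
run_contrast <- function(epochs, contrast, n_super = 10, n_avg = 4,
                         window = c(0, 2), n_bins = 10, k_folds = 5,
                         n_perm = 100, seed = 1L) {
  run_decoding(epochs, contrast, n_super, n_avg, window, n_bins, k_folds,
               n_perm, seed, null = FALSE)
}

#' Run the label-shuffled null pipeline for one contrast
#'
#' Identical to [run_contrast()] except that in every permutation the class
#' labels of the supertrials are reassigned at random with preserved 50/50
#' balance, destroying the class information while keeping every other
#' property of the pipeline; the average over permutations estimates the
#' subject's empirical chance level.
#'
#' @inheritParams run_contrast
#' @return A `decoding_result` list with `null_acc` instead of
#'   `empirical_acc`.
#' @export
run_null <- function(epochs, contrast, n_super = 10, n_avg = 4,
                     window = c(0, 2), n_bins = 10, k_folds = 5,
                     n_perm = 100, seed = 1L) {
  run_decoding(epochs, contrast, n_super, n_avg, window, n_bins, k_folds,
               n_perm, seed, null = TRUE)
}

run_decoding <- function(epochs, contrast, n_super, n_avg, window, n_bins,
                         k_folds, n_perm, seed, null) {
  keep <- usable_trials(epochs$labels)
  pre_all <- precompute_trial_features(epochs, window, n_bins)
  pre <- list(F = pre_all$F[keep, , drop = FALSE],
              M = pre_all$M[keep, , drop = FALSE], n_bins = n_bins)
  sub <- list(labels = epochs$labels[keep, , drop = FALSE])
  accs <- vapply(seq_len(n_perm), function(i) {
    set.seed(derive_seed(seed, i))
    sel <- sample_supertrial_members(sub$labels, contrast, n_super, n_avg)
    X <- supertrial_features(pre, lapply(sel, `[[`, "members"))
    y <- vapply(sel, `[[`, character(1), "class")
    if (null) y <- sample(y)            # balanced relabelling
    crossval_decode(X, y, k_folds)
  }, numeric(1))
  res <- list(contrast = contrast$name, context = contrast$context,
              n_perm = n_perm, seed = seed, per_perm_acc = accs)
  if (null) res$null_acc <- mean(accs) else res$empirical_acc <- mean(accs)
  class(res) <- "decoding_result"
  res
}

#' Group-level inference on decoding accuracies
#'
#' For every contrast x context, tests whether the per-subject empirical
#' accuracies exceed their label-shuffled null accuracies with a one-tailed
#' paired t-test; for every contrast, compares the empirical accuracies
#' between the two contexts with a two-tailed paired t-test.  Cohen's d and
#' the default JZS Bayes factor accompany each test.
#'
#' @param results `data.frame` with columns `subject`, `contrast`,
#'   `context`, `empirical`, `null`.
#' @return A list with `vs_null` and `context_diff` data.frames of test
#'   results.
#' @export
group_decoding_tests <- function(results) {
  need <- c("subject", "contrast", "context", "empirical", "null")
  stopifnot(all(need %in% names(results)))
  vs_null <- do.call(rbind, lapply(
    split(results, list(results$contrast, results$context), drop = TRUE),
    function(d) {
      if (nrow(d) < 2) stop("need at least two subjects per cell")
      tt <- one_sample_t(d$empirical - d$null, 0, alternative = "greater")
      data.frame(contrast = d$contrast[1], context = d$context[1],
                 mean_empirical = mean(d$empirical),
                 mean_null = mean(d$null), t = tt$statistic, df = tt$df,
                 p = tt$p, d = tt$effect_size, bf10 = tt$bf10)
    }))
  context_diff <- do.call(rbind, lapply(
    split(results, results$contrast), function(d) {
      w <- merge(d[d$context == "joint", c("subject", "empirical")],
                 d[d$context == "parallel", c("subject", "empirical")],
                 by = "subject", suffixes = c("_joint", "_parallel"))
      if (nrow(w) < 2) return(NULL)
      tt <- one_sample_t(w$empirical_joint - w$empirical_parallel, 0)
      data.frame(contrast = d$contrast[1],
                 mean_joint = mean(w$empirical_joint),
                 mean_parallel = mean(w$empirical_parallel),
                 t = tt$statistic, df = tt$df, p = tt$p,
                 d = tt$effect_size, bf10 = tt$bf10)
    }))
  rownames(vs_null) <- rownames(context_diff) <- NULL
  list(vs_null = vs_null, context_diff = context_diff)
}
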