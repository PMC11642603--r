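#' Channelwise decoding accuracies
#'
#' Repeats the decoding pipeline with the feature vector of each channel
#' restricted to that channel's own binned time course (`n_bins` features),
#' yielding one accuracy per channel.  Supertrial sampling and fold
#' assignment are shared across channels within each permutation, exactly as
#' when the channels jointly feed one classifier.
#'
#' @inheritParams run_contrast
#' @return A `channel_accuracy_map` list: `acc` (named per-channel vector),
#'   `contrast`, `context`, `n_perm`, `seed`.
#' @export
channelwise_decode <- function(epochs, contrast, n_super = 10, n_avg = 4,
                               window = c(0, 2), n_bins = 10, k_folds = 5,
                               n_perm = 100, seed = 1L) {
  keep <- usable_trials(epochs$labels)
  pre_all <- precompute_trial_features(epochs, window, n_bins)
  pre <- list(F = pre_all$F[keep, , drop = FALSE],
              M = pre_all$M[keep, , drop = FALSE], n_bins = n_bins)
  sub <- list(labels = epochs$labels[keep, , drop = FALSE])
  nch <- dim(epochs$data)[2]
  acc <- matrix(NA_real_, n_perm, nch)
  for (i in seq_len(n_perm)) {
    set.seed(derive_seed(seed, i))
    sel <- sample_supertrial_members(sub$labels, contrast, n_super, n_avg)
    X <- supertrial_features(pre, lapply(sel, `[[`, "members"))
    y <- vapply(sel, `[[`, character(1), "class")
    fold_seed <- derive_seed(seed, i, 7)
    for (ch in seq_len(nch)) {
      cols <- ((ch - 1) * n_bins + 1):(ch * n_bins)
      set.seed(fold_seed)               # identical folds for every channel
      acc[i, ch] <- crossval_decode(X[, cols, drop = FALSE], y, k_folds)
    }
  }
  structure(list(acc = setNames(colMeans(acc), epochs$channel_names),
                 contrast = contrast$name, context = contrast$context,
                 n_perm = n_perm, seed = seed),
            class = "channel_accuracy_map")
}

#' Sensor adjacency from Delaunay triangulation
#'
#' Builds the undirected neighbour graph whose edges are the Delaunay
#' triangulation edges of the flattened 2-D sensor positions.
#'
#' @param pos Channels x 2 matrix (or data.frame with x, y columns) of
#'   positions.
#' @return A list with `adjacency` (symmetric logical matrix) and `edges`
#'   (two-column index matrix).
#' @export
build_adjacency <- function(pos) {
  pos <- as.matrix(pos[, tail(seq_len(ncol(pos)), 2), drop = FALSE])
  storage.mode(pos) <- "double"
  n <- nrow(pos)
  if (n < 3) stop("need at least 3 sensor positions")
  if (anyDuplicated(round(pos, 9)))
    stop("duplicate sensor positions")
  if (qr(cbind(1, pos))$rank < 3)
    stop("collinear sensor positions: triangulation is degenerate")
  tri <- deldir::deldir(pos[, 1], pos[, 2], suppressMsge = TRUE)
  edges <- as.matrix(tri$delsgs[, c("ind1", "ind2")])
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj[edges[, 2:1]] <- TRUE
  list(adjacency = adj, edges = edges)
}

# connected components of a channel subset under an adjacency matrix
channel_clusters <- function(members, adjacency) {
  clusters <- list()
  left <- members
  while (length(left)) {
    comp <- left[1]
    frontier <- comp
    left <- left[-1]
    while (length(frontier)) {
      nb <- which(apply(adjacency[frontier, , drop = FALSE], 2, any))
      new <- intersect(nb, left)
      comp <- c(comp, new)
      left <- setdiff(left, new)
      frontier <- new
    }
    clusters[[length(clusters) + 1]] <- sort(comp)
  }
  clusters
}

#' Cluster-based permutation test on channelwise accuracies
#'
#' Tests where decoding exceeds chance while controlling the family-wise
#' error over channels: per-channel one-sample t statistics against
#' `chance`, thresholded at the two-sided-equivalent t for `threshold_p`
#' applied one-sided (only above-chance channels can form clusters), are
#' grouped into connected clusters under the sensor adjacency; each
#' cluster's statistic is its summed t.  The null distribution of the
#' maximum cluster statistic is built by randomly sign-flipping each
#' subject's accuracy deviations from chance, and each observed cluster's
#' p-value is the fraction of permutations whose maximum cluster statistic
#' is at least as large.
#'
#' @param acc Subjects x channels accuracy matrix (or list of
#'   `channel_accuracy_map`s).
#' @param chance Chance accuracy level.
#' @param adjacency Adjacency matrix from [build_adjacency()].
#' @param threshold_p Cluster-forming p threshold.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Integer seed.
#' @return A `cluster_result` list: `clusters` (list of channel index
#'   vectors), `cluster_stat`, `p`, `t` (per-channel t), `n_perm`.  An
#'   empty cluster list is a valid outcome, not an error.
#' @export
cluster_permutation_test <- function(acc, chance = 0.5, adjacency,
                                     threshold_p = 0.05, n_perm = 1000,
                                     seed = 1L) {
  if (is.list(acc) && !is.matrix(acc))
    acc <- do.call(rbind, lapply(acc, `[[`, "acc"))
  acc <- as.matrix(acc)
  n_sub <- nrow(acc)
  if (n_sub < 2) stop("need at least two subjects")
  stopifnot(ncol(acc) == nrow(adjacency))
  dev <- acc - chance
  t_thresh <- qt(1 - threshold_p / 2, n_sub - 1)
  chan_t <- function(d) {
    m <- colMeans(d)
    v <- (colSums(d^2) - n_sub * m^2) / (n_sub - 1)
    m / sqrt(pmax(v, .Machine$double.eps) / n_sub)
  }
  max_cluster_stat <- function(tv) {
    supra <- which(tv > t_thresh)
    if (!length(supra)) return(0)
    max(vapply(channel_clusters(supra, adjacency),
               function(cl) sum(tv[cl]), numeric(1)))
  }
  t_obs <- chan_t(dev)
  supra <- which(t_obs > t_thresh)
  clusters <- if (length(supra)) channel_clusters(supra, adjacency) else
    list()
  stat <- vapply(clusters, function(cl) sum(t_obs[cl]), numeric(1))
  set.seed(derive_seed(seed, 505))
  null_max <- vapply(seq_len(n_perm), function(i) {
    flips <- sample(c(-1, 1), n_sub, replace = TRUE)
    max_cluster_stat(chan_t(dev * flips))
  }, numeric(1))
  p <- vapply(stat, function(s) mean(null_max >= s), numeric(1))
  structure(list(clusters = clusters, cluster_stat = stat, p = p,
                 t = t_obs, t_threshold = t_thresh, n_perm = n_perm,
                 null_max = null_max),
            class = "cluster_result")
}
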