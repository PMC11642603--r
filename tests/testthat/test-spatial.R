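test_that("Delaunay adjacency handles canonical small cases", {
  tri <- build_adjacency(cbind(c(0, 1, 0.5), c(0, 0, 1)))
  expect_equal(nrow(tri$edges), 3)
  sq <- build_adjacency(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(nrow(sq$edges), 5)        # 4 sides + 1 diagonal
  expect_error(build_adjacency(cbind(0:3, 0:3)), "collinear")
  expect_error(build_adjacency(cbind(c(0, 0, 1), c(0, 0, 1))), "duplicate")
  expect_error(build_adjacency(cbind(0, 1)), "at least 3")
})

test_that("the bundled montage yields a connected graph with >= 2
           neighbours everywhere", {
  adj <- build_adjacency(default_montage(64)[, c("x", "y")])$adjacency
  expect_true(isSymmetric(adj))
  expect_true(all(rowSums(adj) >= 2))
  comp <- dyadicdraw:::channel_clusters(1:64, adj)
  expect_length(comp, 1)                 # one connected component
})

test_that("channelwise decoding localises a planted single-channel signal", {
  dp <- design_params(n_blocks_per_context = 2, trials_per_block = 48,
                      catch_per_block = 0, contexts = "parallel", seed = 41)
  d <- generate_design(dp)
  nch <- 8; sfreq <- 32; n_time <- 64
  pats <- list()
  for (comb in c("CC", "DD", "CD", "DC")) {
    m <- matrix(0, nch, n_time)
    # channel 3 only; zero temporal mean so demeaning keeps the signal
    m[3, ] <- ifelse(substr(comb, 1, 1) == "C", 1.2, -1.2) *
      rep(c(1, -1), each = n_time / 2)
    pats[[paste("parallel", comb, sep = ":")]] <- m
  }
  ep <- eeg_gen_params(n_channels = nch, sfreq = sfreq,
                       condition_patterns = pats, seed = 42)
  e <- generate_epochs(d, ep)
  cm <- channelwise_decode(e, contrast_spec("congruent_combo", "parallel"),
                           n_super = 5, n_perm = 10, seed = 43)
  expect_gt(cm$acc[3], 0.8)
  expect_lt(max(cm$acc[-3]), cm$acc[3])
  expect_lt(abs(mean(cm$acc[-3]) - 0.5), 0.08)
  cm2 <- channelwise_decode(e, contrast_spec("congruent_combo", "parallel"),
                            n_super = 5, n_perm = 10, seed = 43)
  expect_identical(cm$acc, cm2$acc)      # seed determinism
})

test_that("flat accuracy maps produce no clusters", {
  adj <- build_adjacency(default_montage(64)[, c("x", "y")])$adjacency
  acc <- matrix(0.5, 10, 64)
  acc <- acc + matrix(rep(rnorm(10, 0, 1e-6), 64), 10, 64)  # no channel signal
  r <- cluster_permutation_test(acc, 0.5, adj, n_perm = 100, seed = 1)
  expect_length(r$clusters, 0)
  expect_s3_class(r, "cluster_result")
})

test_that("a planted connected patch is recovered significantly", {
  adj <- build_adjacency(default_montage(64)[, c("x", "y")])$adjacency
  patch <- c(1)
  while (length(patch) < 6)
    patch <- unique(c(patch,
                      which(apply(adj[patch, , drop = FALSE], 2, any))))
  patch <- patch[1:6]
  set.seed(52)
  acc <- matrix(rnorm(20 * 64, 0.5, 0.05), 20, 64)
  acc[, patch] <- acc[, patch] + 0.15
  r <- cluster_permutation_test(acc, 0.5, adj, n_perm = 1000, seed = 53)
  expect_gt(length(r$clusters), 0)
  best <- which.max(r$cluster_stat)
  expect_lt(r$p[best], 0.05)
  expect_gte(length(intersect(r$clusters[[best]], patch)), 5)
  # every reported cluster is connected under the adjacency graph
  for (cl in r$clusters) {
    if (length(cl) == 1) next
    sub <- adj[cl, cl, drop = FALSE]
    expect_length(dyadicdraw:::channel_clusters(seq_along(cl),
                                                sub), 1)
  }
})

test_that("sign-flip null matches the observed statistic under no signal", {
  adj <- build_adjacency(default_montage(64)[, c("x", "y")])$adjacency
  set.seed(61)
  obs <- replicate(60, {
    acc <- matrix(rnorm(12 * 64, 0.5, 0.05), 12, 64)
    r <- cluster_permutation_test(acc, 0.5, adj, n_perm = 150,
                                  seed = sample.int(1e6, 1))
    c(max(c(r$cluster_stat, 0)), sample(r$null_max, 1))
  })
  ks <- suppressWarnings(ks.test(obs[1, ], obs[2, ]))
  expect_gt(ks$p.value, 0.01)
})
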