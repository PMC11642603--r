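test_that("the fast feature path equals average -> demean -> bin exactly", {
  e <- small_epochs(trials_per_block = 48, n_blocks = 2, seed = 21)
  cs <- contrast_spec("incongruent_combo", "parallel")
  seed <- derive_seed(99, 1)
  st <- make_supertrials(e, cs, n_super = 5, n_avg = 4, seed = seed)
  slow <- t(vapply(st, function(s)
    bin_features(demean_supertrial(s), e$times, c(0, 2), 10),
    numeric(dim(e$data)[2] * 10)))
  pre <- dyadicdraw:::precompute_trial_features(e, c(0, 2), 10)
  fast <- dyadicdraw:::supertrial_features(pre,
                                           lapply(st, `[[`, "members"))
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("noiseless separable patterns decode perfectly", {
  e <- small_epochs(preset = "integrated", amp = 5, noise_sd = 1e-6,
                    trials_per_block = 48, n_blocks = 2, seed = 22)
  r <- run_contrast(e, contrast_spec("congruent_combo", "parallel"),
                    n_super = 5, n_perm = 3, seed = 1)
  expect_equal(r$empirical_acc, 1)
})

test_that("identical condition patterns decode at chance", {
  # average several simulated subjects: single-subject chance levels
  # fluctuate with the trial sample, the group mean must not
  accs <- vapply(1:8, function(s) {
    e <- small_epochs(preset = "null", trials_per_block = 48, n_blocks = 2,
                      seed = 22 + s)
    run_contrast(e, contrast_spec("congruent_combo", "parallel"),
                 n_super = 5, n_perm = 20, seed = s)$empirical_acc
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("label-shuffled nulls stay at chance even with strong signal", {
  e <- small_epochs(preset = "integrated", amp = 5, trials_per_block = 48,
                    n_blocks = 2, seed = 24)
  accs <- vapply(1:4, function(s) {
    run_null(e, contrast_spec("congruent_combo", "parallel"),
             n_super = 5, n_perm = 20, seed = s)$null_acc
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("decoding runs are bit-identical under one seed", {
  e <- small_epochs(trials_per_block = 48, n_blocks = 2, seed = 25)
  cs <- contrast_spec("own_movement", "parallel")
  r1 <- run_contrast(e, cs, n_super = 5, n_perm = 5, seed = 11)
  r2 <- run_contrast(e, cs, n_super = 5, n_perm = 5, seed = 11)
  expect_identical(r1$per_perm_acc, r2$per_perm_acc)
  n1 <- run_null(e, cs, n_super = 5, n_perm = 5, seed = 11)
  n2 <- run_null(e, cs, n_super = 5, n_perm = 5, seed = 11)
  expect_identical(n1$per_perm_acc, n2$per_perm_acc)
})

test_that("higher noise never helps decoding on a 3-point grid", {
  accs <- vapply(c(0.5, 2, 8), function(ns) {
    mean(vapply(1:4, function(s) {
      e <- small_epochs(preset = "integrated", amp = 0.6, noise_sd = ns,
                        trials_per_block = 48, n_blocks = 2,
                        seed = 30 + s)
      run_contrast(e, contrast_spec("congruent_combo", "parallel"),
                   n_super = 5, n_perm = 10,
                   seed = derive_seed(31, s))$empirical_acc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) <= 0.02))   # monotone up to simulation jitter
  expect_gt(accs[1], accs[3])
})

test_that("group tests behave at both extremes", {
  res <- data.frame(subject = rep(1:12, 2),
                    contrast = "congruent_combo",
                    context = rep(c("joint", "parallel"), each = 12),
                    empirical = 0.55, null = 0.55)
  expect_error(group_decoding_tests(res), "variance")
  set.seed(5)
  res$empirical <- res$null + 0.1 + rnorm(24, 0, 0.01)
  g <- group_decoding_tests(res)
  expect_true(all(g$vs_null$p < 0.001))
  expect_gt(g$context_diff$p, 0.05)      # same effect in both contexts
  res0 <- res
  res0$empirical <- res0$null + rnorm(24, 0, 0.01)
  g0 <- group_decoding_tests(res0)
  expect_true(all(g0$vs_null$p > 0.001))
})
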