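test_that("supertrial pools have the documented composition", {
  e <- small_epochs(trials_per_block = 96, n_blocks = 2, seed = 2)
  cs <- contrast_spec("congruent_combo", "parallel")
  st <- make_supertrials(e, cs, n_super = 10, n_avg = 4, seed = 7)
  expect_length(st, 20)
  expect_equal(table(vapply(st, `[[`, character(1), "class_label")),
               table(rep(c("CC", "DD"), each = 10)), ignore_attr = TRUE)
  for (s in st) {
    expect_length(s$members, 4)
    cue <- e$labels$cue_pair[s$members]
    expect_equal(as.integer(sort(table(cue))), c(2L, 2L))  # 2 per cue pair
    expect_length(unique(e$labels$combination[s$members]), 1)
  }
  # without replacement within one draw
  all_members <- unlist(lapply(st, `[[`, "members"))
  expect_false(any(duplicated(all_members)))
})

test_that("mixed supertrials take one trial per condition x cue-pair cell", {
  e <- small_epochs(trials_per_block = 96, n_blocks = 2, seed = 3)
  cs <- contrast_spec("own_movement", "parallel")
  st <- make_supertrials(e, cs, n_super = 10, n_avg = 4, seed = 8)
  expect_length(st, 20)
  for (s in st) {
    cells <- paste(e$labels$combination[s$members],
                   e$labels$cue_pair[s$members])
    expect_length(unique(cells), 4)
  }
})

test_that("insufficient cells raise an error naming the cell", {
  e <- small_epochs(trials_per_block = 8, n_blocks = 2, seed = 4)
  cs <- contrast_spec("incongruent_combo", "parallel")
  expect_error(make_supertrials(e, cs, n_super = 10, n_avg = 4, seed = 1),
               "insufficient trials in cell parallel:CD")
})

test_that("averaging constants yields the constant", {
  e <- small_epochs(trials_per_block = 96, n_blocks = 2, seed = 5)
  e$data[] <- 3.5
  st <- make_supertrials(e, contrast_spec("congruent_combo", "parallel"),
                         seed = 2)
  expect_true(all(abs(st[[1]]$data - 3.5) < 1e-12))
})

test_that("demeaning zeroes every channel's temporal mean", {
  set.seed(6)
  m <- matrix(rnorm(40), 4, 10)
  dm <- demean_supertrial(m)
  expect_true(all(abs(rowMeans(dm)) < 1e-10))
  expect_true(all(abs(demean_supertrial(matrix(2, 3, 5))) < 1e-12))
  ramp <- matrix(0:9, 2, 10, byrow = TRUE)
  expect_equal(rowMeans(demean_supertrial(ramp)), c(0, 0))
  expect_equal(demean_supertrial(ramp)[1, ], 0:9 - 4.5)
})

test_that("binning yields channels x bins features with correct values", {
  sfreq <- 128
  times <- (0:255) / sfreq
  dat <- matrix(rnorm(64 * 256), 64, 256)
  f <- bin_features(dat, times, c(0, 2), 10)
  expect_length(f, 640)
  expect_equal(f, oracle_bin(dat, times, c(0, 2), 10), tolerance = 1e-12)
  # constant input maps to constant features
  expect_true(all(abs(bin_features(matrix(2, 4, 256), times) - 2) < 1e-12))
  # channel-major layout: first 10 features belong to channel 1
  d2 <- matrix(0, 2, 256); d2[1, ] <- 1
  f2 <- bin_features(d2, times)
  expect_equal(f2, c(rep(1, 10), rep(0, 10)))
  # bins are time-defined half-open intervals holding 25 or 26 samples
  W <- dyadicdraw:::bin_weights(times, c(0, 2), 10)
  expect_equal(sort(unique(colSums(W > 0))), c(25, 26))
  expect_error(bin_features(dat, times, c(0, 3), 10), "outside")
})

test_that("linear ramps bin to the ramp at each bin's sample centroid", {
  sfreq <- 128
  times <- (0:255) / sfreq
  ramp <- matrix(times * 5 + 1, 1, 256)
  f <- bin_features(ramp, times, c(0, 2), 10)
  W <- dyadicdraw:::bin_weights(times, c(0, 2), 10)
  centroids <- as.vector(times %*% W)
  expect_equal(f, centroids * 5 + 1, tolerance = 1e-12)
})
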