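test_that("an exact half diamond with the apex on the grid fits the linear
           spline perfectly", {
  pts <- ideal_shape("diamond", 99)        # odd count puts the apex on-grid
  cl <- classify_shape(pts)
  expect_equal(cl$residual_linear, 0, tolerance = 1e-12)
  expect_gt(cl$residual_quadratic, 1)
  expect_equal(cl$label, "diamond")
})

test_that("an exact half circle is labelled circle with the quadratic fit
           winning", {
  cl <- classify_shape(ideal_shape("circle", 100))
  expect_lt(cl$residual_quadratic, cl$residual_linear)
  expect_equal(cl$label, "circle")
})

test_that("noisy shapes are classified correctly in at least 95% of cases", {
  set.seed(42)
  lab_d <- vapply(1:250, function(i)
    classify_shape(noisy_shape("diamond", 3))$label, character(1))
  lab_c <- vapply(1:250, function(i)
    classify_shape(noisy_shape("circle", 3))$label, character(1))
  expect_gte(mean(lab_d == "diamond"), 0.95)
  expect_gte(mean(lab_c == "circle"), 0.95)
})

test_that("classification agrees with the normal-equation oracle", {
  set.seed(7)
  agree <- vapply(1:300, function(i) {
    sh <- sample(c("circle", "diamond"), 1)
    pts <- noisy_shape(sh, runif(1, 0.5, 6))
    classify_shape(pts)$label == oracle_classify(pts)
  }, logical(1))
  expect_true(all(agree))
})

test_that("degenerate paths are flagged unclassifiable", {
  flat <- cbind(x = seq(0, 100, length.out = 50), y = rep(5, 50))
  expect_true(classify_shape(flat)$unclassifiable)
  set.seed(1)
  scribble <- cbind(x = cumsum(rnorm(100, 0, 40)),
                    y = cumsum(rnorm(100, 0, 40)))
  # heavy vertical reversals: not a function of the vertical coordinate
  expect_true(classify_shape(scribble)$unclassifiable)
})

test_that("swap flags compare the classified label to the cue", {
  circ <- resample_trajectory(ideal_shape("circle", 30))
  diam <- resample_trajectory(ideal_shape("diamond", 31))
  expect_equal(detect_swap_errors(list(circ, diam), c("circle", "circle")),
               c(FALSE, TRUE))
  expect_equal(detect_swap_errors(list(circ, diam), c("diamond", "diamond")),
               c(TRUE, FALSE))
})

test_that("swap flagging recovers a planted swap rate", {
  d <- fake_design(400, own = "circle")
  ef <- trajectory_effects(base_noise_sd = 1,
                           vmi_shift = c(joint = 0, parallel = 0),
                           swap_rate = 0.1, gross_error_rate = 0, seed = 31)
  trs <- generate_trajectories(d, ef)
  flags <- detect_swap_errors(lapply(trs, resample_trajectory),
                              rep("circle", 400))
  # binomial 95% interval around 0.1 at n = 400
  expect_gt(mean(flags), 0.1 - 1.96 * sqrt(0.09 / 400))
  expect_lt(mean(flags), 0.1 + 1.96 * sqrt(0.09 / 400))
})
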