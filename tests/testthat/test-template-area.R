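test_that("templates are pointwise means with the symmetry this implies", {
  base <- ideal_shape("circle", 100)
  up <- base; up[, 1] <- up[, 1] + 5
  dn <- base; dn[, 1] <- dn[, 1] - 5
  tpl <- compute_templates(list(up, dn), c("circle", "circle"))
  expect_equal(tpl$circle$points, base, ignore_attr = TRUE)
  expect_equal(tpl$circle$n_contributing, 2)
  single <- compute_templates(list(up), "circle")
  expect_equal(single$circle$points, up, ignore_attr = TRUE)
  expect_error(compute_templates(list(), character(0)), "no labelled")
})

test_that("averaging many noisy shapes converges to the ideal template", {
  set.seed(9)
  trs <- lapply(1:500, function(i)
    resample_trajectory(noisy_shape("circle", 5)))
  tpl <- compute_templates(trs, rep("circle", 500))
  rms <- sqrt(mean((tpl$circle$points - ideal_shape("circle", 100))^2))
  expect_lt(rms, 0.5)
})

test_that("area to template has its exact base cases", {
  a <- ideal_shape("circle", 100)
  expect_equal(area_to_template(a, a), 0)
  seg <- cbind(x = rep(0, 100), y = seq(0, 10, length.out = 100))
  seg2 <- seg; seg2[, 1] <- 2
  expect_equal(area_to_template(seg, seg2), 20, tolerance = 1e-12)
})

test_that("area is symmetric and invariant under a shared translation", {
  set.seed(5)
  for (i in 1:10) {
    a <- resampled_pair()
    expect_equal(area_to_template(a$A, a$B), area_to_template(a$B, a$A),
                 tolerance = 1e-9)
    shift <- matrix(rep(rnorm(2, 0, 50), each = 100), 100, 2)
    expect_equal(area_to_template(a$A + shift, a$B + shift),
                 area_to_template(a$A, a$B), tolerance = 1e-9)
  }
})

test_that("area matches dense numerical integration on monotone pairs", {
  set.seed(31)
  rel_err <- vapply(1:100, function(i) {
    a <- resampled_pair()
    got <- area_to_template(a$A, a$B)
    want <- oracle_area_monotone(a$A, a$B)
    abs(got - want) / want
  }, numeric(1))
  expect_lt(max(rel_err), 0.005)
})

test_that("crossing curves accumulate unsigned lobe areas", {
  t1 <- cbind(x = seq(-1, 1, length.out = 100),
              y = seq(0, 10, length.out = 100))
  t2 <- cbind(x = seq(1, -1, length.out = 100),
              y = seq(0, 10, length.out = 100))
  # two triangular lobes, each of area 5
  expect_equal(area_to_template(t1, t2), 10, tolerance = 1e-9)
})

test_that("corridor accuracy counts points within the band", {
  circ <- ideal_shape("circle", 100)
  expect_equal(corridor_accuracy(circ, "circle"), 1)
  far <- cbind(x = rep(-150, 100), y = seq(400, 0, length.out = 100))
  expect_equal(corridor_accuracy(far, "circle", band = 100), 0)
  mixed <- rbind(circ[1:50, ], far[51:100, ])
  expect_equal(corridor_accuracy(mixed, "circle", band = 100), 0.5,
               tolerance = 0.03)
})

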