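# simulate a distortion table with known fixed effects under sum coding
sim_lmm_table <- function(n_sub = 30, n_rep = 10, b_ctx = 0, b_cong = 0,
                          b_int = 0, sd_sub = 0.5, sd_eps = 1) {
  g <- expand.grid(subject = seq_len(n_sub),
                   context = c("joint", "parallel"),
                   congruency = c("congruent", "incongruent"),
                   rep = seq_len(n_rep), stringsAsFactors = FALSE)
  # contr.sum codes the first level +1, the second -1
  xc <- ifelse(g$context == "joint", 1, -1)
  xg <- ifelse(g$congruency == "congruent", 1, -1)
  u <- rnorm(n_sub, 0, sd_sub)
  g$area_boxcox <- b_ctx * xc + b_cong * xg + b_int * xc * xg +
    u[g$subject] + rnorm(nrow(g), 0, sd_eps)
  g
}

test_that("mixed-model intervals cover zero effects at the nominal rate", {
  set.seed(11)
  hits <- matrix(0, 200, 3)
  for (i in 1:200) {
    fit <- fit_vmi_lmm(sim_lmm_table())
    cf <- fit$coefficients
    rows <- cf$term != "(Intercept)"
    hits[i, ] <- cf$ci_lower[rows] <= 0 & cf$ci_upper[rows] >= 0
  }
  # true coverage must not fall significantly below the 93% floor
  for (j in 1:3)
    expect_gt(binom.test(sum(hits[, j]), 200, 0.93,
                         alternative = "less")$p.value, 0.01)
})

test_that("a planted context effect is recovered inside its interval", {
  set.seed(12)
  cover <- sig <- logical(200)
  for (i in 1:200) {
    fit <- fit_vmi_lmm(sim_lmm_table(b_ctx = -0.5))
    cf <- fit$coefficients
    row <- grep("^context", cf$term)[1]
    cover[i] <- cf$ci_lower[row] <= -0.5 & cf$ci_upper[row] >= -0.5
    sig[i] <- cf$p[row] < 0.05
  }
  expect_gt(binom.test(sum(cover), 200, 0.93,
                       alternative = "less")$p.value, 0.01)
  expect_gt(mean(sig), 0.9)              # |beta|/se is large at these sizes
})

test_that("Satterthwaite degrees of freedom are reported and sensible", {
  set.seed(13)
  fit <- fit_vmi_lmm(sim_lmm_table(n_sub = 12, n_rep = 6))
  expect_true(all(c("beta", "ci_lower", "ci_upper", "t", "df", "p") %in%
                    names(fit$coefficients)))
  expect_true(all(fit$coefficients$df > 0))
  expect_true(fit$converged)
})

test_that("zero random-intercept variance is recovered at the boundary", {
  set.seed(14)
  fit <- fit_vmi_lmm(sim_lmm_table(sd_sub = 0))
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  expect_lt(vc$sdcor[vc$grp == "subject"], 0.15)
})

test_that("sum-coded main effects are sign-symmetric under relabelling", {
  set.seed(15)
  tab <- sim_lmm_table(b_ctx = 0.4)
  f1 <- fit_vmi_lmm(tab)
  tab2 <- tab
  tab2$context <- ifelse(tab$context == "joint", "z_parallel", "a_joint")
  f2 <- fit_vmi_lmm(tab2)
  r1 <- grep("^context", f1$coefficients$term)[1]
  r2 <- grep("^context", f2$coefficients$term)[1]
  expect_equal(abs(f1$coefficients$beta[r1]), abs(f2$coefficients$beta[r2]),
               tolerance = 1e-8)
})

test_that("Poisson count model is calibrated under equal rates", {
  set.seed(16)
  ps <- replicate(400, {
    g <- expand.grid(subject = 1:36, context = c("joint", "parallel"),
                     congruency = c("congruent", "incongruent"),
                     stringsAsFactors = FALSE)
    g$count <- rpois(nrow(g), 1.3)
    fit <- fit_count_glm(g)
    fit$coefficients$p[grep("^context1$", fit$coefficients$term)]
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("a doubled rate on one factor is detected with high power", {
  set.seed(17)
  sig <- replicate(100, {
    g <- expand.grid(subject = 1:36, context = c("joint", "parallel"),
                     congruency = c("congruent", "incongruent"),
                     stringsAsFactors = FALSE)
    lam <- ifelse(g$context == "joint", 2, 1)
    g$count <- rpois(nrow(g), lam)
    fit <- fit_count_glm(g)
    fit$coefficients$p[grep("^context1$", fit$coefficients$term)] < 0.05
  })
  expect_gte(mean(sig), 0.8)
})

test_that("degenerate count patterns are flagged or rejected", {
  g <- expand.grid(subject = 1:4, context = c("joint", "parallel"),
                   congruency = c("congruent", "incongruent"),
                   stringsAsFactors = FALSE)
  g$count <- 0
  expect_error(fit_count_glm(g), "zero")
  g$count <- ifelse(g$context == "joint" & g$congruency == "congruent", 3, 0)
  expect_true(fit_count_glm(g)$unstable)
  g$count[1] <- -1
  expect_error(fit_count_glm(g), "nonnegative")
})
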