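test_that("default design reproduces the session's trial arithmetic", {
  d <- generate_design(design_params(seed = 3))
  expect_equal(nrow(d), 576)
  noncatch <- with(d[!d$is_catch, ], table(context, combination))
  expect_true(all(noncatch == 60))
  catch_block <- with(d[d$is_catch, ], table(context, block))
  expect_true(all(catch_block == 8))
  catch_cell <- with(d[d$is_catch, ], table(context, combination))
  expect_true(all(catch_cell == 12))
})

test_that("cue pairs are balanced within every design cell", {
  d <- generate_design(design_params(seed = 5))
  cue <- with(d[!d$is_catch, ], table(context, combination, cue_pair))
  expect_true(all(cue == 30))
  # cue pair is a block-level property that alternates
  expect_true(all(tapply(d$cue_pair, interaction(d$context, d$block),
                         function(x) length(unique(x))) == 1))
})

test_that("catch trials show the partner drawing the non-cued shape", {
  d <- generate_design(design_params(seed = 2))
  expect_true(all(d$partner_shape[d$is_catch] !=
                    d$partner_cued_shape[d$is_catch]))
  expect_true(all(d$partner_shape[!d$is_catch] ==
                    d$partner_cued_shape[!d$is_catch]))
  # combination letters encode the cued shapes
  expect_true(all(ifelse(substr(d$combination, 1, 1) == "C", "circle",
                         "diamond") == d$own_shape))
})

test_that("partner durations follow the context-specific uniform intervals", {
  d <- generate_design(design_params(seed = 8))
  pj <- d$partner_duration[d$context == "joint"]
  pp <- d$partner_duration[d$context == "parallel"]
  expect_true(all(pj >= 1.8 & pj <= 2.2))
  expect_true(all(pp >= 1.6 & pp <= 2.4))
  # the wider parallel interval is actually used
  expect_true(any(pp < 1.79 | pp > 2.21))
  expect_true(all(d$start_time < 0.8))
})

test_that("a minimal balanced design gives one trial per combination", {
  d <- generate_design(design_params(n_blocks_per_context = 1,
                                     trials_per_block = 4,
                                     catch_per_block = 0))
  expect_equal(nrow(d), 8)
  expect_true(all(table(d$context, d$combination) == 1))
})

test_that("infeasible balance is rejected with a configuration error", {
  expect_error(design_params(trials_per_block = 46), "divisible")
  expect_error(design_params(catch_per_block = 48), "smaller")
  expect_error(design_params(n_blocks_per_context = 1, catch_per_block = 6),
               "balance")
  expect_error(design_params(partner_duration_joint = c(2.2, 1.8)),
               "low < high")
})

test_that("identical seeds give bit-identical designs", {
  expect_identical(generate_design(design_params(seed = 11)),
                   generate_design(design_params(seed = 11)))
  expect_false(identical(generate_design(design_params(seed = 11)),
                         generate_design(design_params(seed = 12))))
})

test_that("usable trials keep detected catches, drop misses and false alarms",
{
  d <- generate_design(design_params(seed = 4))
  u <- usable_trials(d)
  expect_true(all(d$catch_response[d$is_catch & u]))
  expect_true(all(!d$catch_response[!d$is_catch & u]))
  expect_false(any(u[d$is_catch & !d$catch_response]))
})
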