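test_that("reallocation arithmetic preserves totals with largest-remainder rounding", {
  # nothing dropped: identity
  inc <- c(48, 48, 48, 48)
  expect_equal(reallocate(inc, integer(0), rep(1, 3)), inc)
  # one of three doses dropped in the 97/arm design: its 48 remaining
  # patients split 16/16/16 over the continuing arms, total preserved
  out <- reallocate(inc, 2, rep(1, 3))
  expect_equal(out, c(64, 64, 0, 64))
  expect_equal(sum(out), sum(inc))
  # no upscaling: continuing arms unchanged, total shrinks
  out_none <- reallocate(inc, 2, rep(1, 3), rule = "none")
  expect_equal(out_none, c(48, 48, 0, 48))
  # uneven split resolved by largest remainder, exactly preserving totals
  out2 <- reallocate(c(10, 10, 7, 10), 2, rep(1, 3))
  expect_equal(sum(out2), 37)
  expect_equal(out2[3], 0)
  expect_true(all(out2[-3] >= c(10, 10, 10) + 2))
  # allocation-proportional shares
  out3 <- reallocate(c(30, 30, 60), 1, c(1, 2))
  expect_equal(out3, c(40, 0, 80))
  # all arms dropped: flagged, control untouched
  out4 <- reallocate(inc, 1:3, rep(1, 3))
  expect_true(isTRUE(attr(out4, "all_dropped")))
  expect_equal(as.numeric(out4), c(48, 0, 0, 0))
  expect_error(reallocate(inc, 5, rep(1, 3)), "invalid")
})

test_that("single trials are deterministic given the seed", {
  d <- socrates_design()
  a <- simulate_trial(d, c(0, 0.187, 0.187), seed = 42,
                      methods = c("cumulative", "stagewise_dunnett"))
  b <- simulate_trial(d, c(0, 0.187, 0.187), seed = 42,
                      methods = c("cumulative", "stagewise_dunnett"))
  expect_identical(a, b)
  c2 <- simulate_trial(d, c(0, 0.187, 0.187), seed = 43,
                       methods = "cumulative")
  expect_false(identical(a$cumulative, c2$cumulative))
})

test_that("selection rule boundary cases", {
  d_off <- socrates_design(selection_threshold = -Inf)
  st <- simulate_trial(d_off, delta = c(-2, -2, -2), seed = 9)
  expect_equal(st$selected, 1:3)      # rule disabled: nothing dropped
  # overwhelming effects: certain rejection at the first look
  d <- socrates_design()
  for (r in 1:10) {
    st <- simulate_trial(d, delta = rep(10 * 0.52, 3), seed = 200 + r)
    expect_true(any(st$cumulative$rejected))
    expect_equal(st$cumulative$stop_stage, 1L)
    expect_equal(st$cumulative$n_total, sum(planned_n(d)[, 1]))
  }
  # strongly negative effects: every dose dropped, trial ends at stage 1
  st <- simulate_trial(d, delta = rep(-10 * 0.52, 3), seed = 300)
  expect_length(st$selected, 0)
  expect_false(any(st$cumulative$rejected))
  expect_equal(st$cumulative$n_total, sum(planned_n(d)[, 1]))
})

test_that("power ordering across methods at heterogeneous effects", {
  d <- socrates_design()
  oc <- operating_characteristics(
    d, delta = c(0, 0, 0.187),
    methods = c("stagewise_bonferroni", "stagewise_simes",
                "stagewise_dunnett", "cumulative"),
    n_reps = 1200, seed = 17)
  pw <- setNames(oc$power, oc$method)
  se <- setNames(oc$power_se, oc$method)
  slack <- function(a, b) 3 * sqrt(se[a]^2 + se[b]^2)
  expect_gte(pw["cumulative"],
             pw["stagewise_dunnett"] - slack("cumulative", "stagewise_dunnett"))
  expect_gte(pw["stagewise_dunnett"],
             pw["stagewise_simes"] - slack("stagewise_dunnett", "stagewise_simes"))
  expect_gte(pw["stagewise_simes"],
             pw["stagewise_bonferroni"] - slack("stagewise_simes", "stagewise_bonferroni"))
})

test_that("three-stage designs stop earlier on average than two-stage designs", {
  oc2 <- operating_characteristics(socrates_design(2), rep(0.187, 3),
                                   "cumulative", n_reps = 400, seed = 23)
  oc3 <- operating_characteristics(socrates_design(3), rep(0.187, 3),
                                   "cumulative", n_reps = 400, seed = 23)
  expect_lt(oc3$asn, oc2$asn + 3 * sqrt(oc2$asn_se^2 + oc3$asn_se^2))
  expect_lte(oc2$asn, sum(planned_n(socrates_design(2))[, 2]))
  expect_lte(oc3$asn, sum(planned_n(socrates_design(3))[, 3]))
})

test_that("family-wise error is controlled for every method under the global null", {
  d <- socrates_design()
  oc <- operating_characteristics(
    d, delta = 0,
    methods = c("cumulative", "stagewise_dunnett", "stagewise_simes",
                "stagewise_bonferroni", "single_stage_dunnett"),
    n_reps = 1000, seed = 29)
  for (m in seq_len(nrow(oc))) {
    expect_lte(oc$fwer[m], 0.025 + 3 * sqrt(0.025 * 0.975 / 1000))
  }
  # FWER under a partial null configuration as well (strong control)
  ocp <- operating_characteristics(d, delta = c(0, 0, 0.4),
                                   methods = c("cumulative",
                                               "stagewise_dunnett"),
                                   n_reps = 800, seed = 31)
  for (m in 1:2) {
    expect_lte(ocp$fwer[m], 0.025 + 3 * sqrt(0.025 * 0.975 / 800))
  }
})
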