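test_that("conditional error limits and Monte-Carlo agreement", {
  expect_equal(conditional_error(c(0, 0), Inf, c(90, 90)), 0)
  # deep crossing at stage 1 makes stage-2 crossing conditionally certain
  expect_gt(conditional_error(c(500, 500), 300, c(90, 90)), 1 - 1e-6)
  # w1 = (0,0), stage-1 information as in the 97/arm two-look design
  iinc <- rep(48 / (2 * 0.52^2), 2)
  b2 <- 2.4513 * sqrt(97 / (2 * 0.52^2))
  A <- conditional_error(c(0, 0), b2, iinc)
  set.seed(91)
  reps <- 2e5
  z0 <- rnorm(reps)
  W <- sqrt(iinc[1]) * (sqrt(.5) * z0 +
                          sqrt(.5) * cbind(rnorm(reps), rnorm(reps)))
  A_mc <- mean(pmax(W[, 1], W[, 2]) >= b2)
  expect_within(A, A_mc, 3 * sqrt(A_mc * (1 - A_mc) / reps))
})

test_that("boundary recomputation preserves the conditional error", {
  iinc <- rep(88, 3); icum <- rep(178, 3)
  w1 <- c(3, -2, 5)
  A <- conditional_error(w1, 2.45 * sqrt(icum), iinc)
  # identity case: same arms, same sizes
  rb <- recompute_boundary(w1, A, iinc, icum)
  expect_within(rb$z, 2.45, 1e-6)
  expect_lt(rb$residual, 1e-6)
  # dropping an arm without changing sizes can only lower the boundary
  rb2 <- recompute_boundary(w1[c(1, 3)], A, iinc[1:2], icum[1:2])
  expect_lte(rb2$z, 2.45 + 1e-8)
  expect_lt(rb2$residual, 1e-6)
  # dropping two of three with a doubled control increment, checked
  # against a Monte-Carlo inversion oracle
  iinc_new <- 2 * iinc[1]; icum_new <- 90 + iinc_new
  rb3 <- recompute_boundary(w1[3], A, iinc_new, icum_new)
  set.seed(101)
  reps <- 2e5
  Winc <- rnorm(reps, 0, sqrt(iinc_new))
  A_mc <- mean(w1[3] + Winc >= rb3$z * sqrt(icum_new))
  expect_within(A_mc, A, 3 * sqrt(A * (1 - A) / reps))
})

test_that("no-adaptation closed test keeps the planned boundaries and is consonant", {
  d <- socrates_design(selection_threshold = -Inf)   # never drop
  bounds <- mams_boundaries(d)
  zb_full <- bounds$z[7, ]            # k = 3 row ({1,2,3})
  set.seed(111)
  n_direct <- 0
  for (r in 1:40) {
    st <- simulate_trial(d, delta = c(0.3, 0.1, 0), seed = 4000 + r)
    res <- cumulative_closed_test(d, st$obs, selected = st$selected)
    # recomputed boundaries collapse to the planned ones
    if (!is.null(res$intersections$zstar2)) {
      ok <- is.finite(res$intersections$zstar2)
      expect_within(res$intersections$zstar2[ok], bounds$z[ok, 2], 1e-6)
    }
    # consonance: any arm whose cumulative statistic crosses the k = D
    # boundary (t-adjusted) is rejected by the closed test, and the global
    # decision coincides with max-statistic monitoring
    for (j in seq_len(res$stop_stage)) {
      stt <- mamsadapt:::cum_stats(st$obs, j)
      info <- stt$n[1] / (stt$var[1] + stt$var[-1])
      tj <- (stt$mean[-1] - stt$mean[1]) * sqrt(info)
      crit <- qt(pnorm(zb_full[j]), stt$n[1] + stt$n[-1] - 1)
      direct <- tj >= crit
      if (any(direct)) n_direct <- n_direct + 1
      expect_true(all(res$rejected[direct]))
      if (j == res$stop_stage)
        expect_equal(any(res$rejected), any(direct))
    }
  }
  expect_gt(n_direct, 0)
})

test_that("adapted trials satisfy the conditional-error equation and b* <= b when dropping", {
  d_none <- socrates_design(selection_threshold = 0, reallocation = "none")
  bounds <- mams_boundaries(d_none)
  set.seed(121)
  n_checked <- 0
  for (r in 1:40) {
    st <- simulate_trial(d_none, delta = c(0, 0.2, 0.2), seed = 5000 + r)
    if (ncol(st$obs$n) < 2 || length(st$selected) == 3) next
    res <- cumulative_closed_test(d_none, st$obs, selected = st$selected)
    expect_lt(res$max_residual, 1e-6)
    tab <- res$intersections
    drop_hit <- vapply(bounds$subsets, function(I)
      length(intersect(I, st$selected)) < length(I) &&
        length(intersect(I, st$selected)) > 0, TRUE)
    ok <- drop_hit & is.finite(tab$zstar2) & !(tab$rejected_stage %in% 1)
    if (any(ok, na.rm = TRUE)) {
      expect_true(all(tab$zstar2[which(ok)] <= bounds$z[which(ok), 2] + 1e-7))
      n_checked <- n_checked + sum(ok, na.rm = TRUE)
    }
  }
  expect_gt(n_checked, 5)
})

test_that("upscaled adaptation keeps the conditional-error residual tiny", {
  d <- socrates_design()
  oc <- operating_characteristics(d, delta = c(0, 0, 0.187),
                                  methods = "cumulative", n_reps = 200,
                                  seed = 131)
  expect_lt(attr(oc, "max_residual"), 1e-6)
})

test_that("single-arm cumulative design is a classical two-arm group-sequential test", {
  d <- mams_design(1, 2, c(40, 80))
  cb <- max_stat_boundaries(1, c(0.5, 1), 0.025)$z
  set.seed(141)
  for (r in 1:15) {
    st <- simulate_trial(d, delta = 0.45, seed = 6000 + r,
                         known_variance = TRUE)
    res <- cumulative_closed_test(d, st$obs, selected = st$selected,
                                  known_sigma = d$sigma)
    for (j in seq_len(res$stop_stage)) {
      stt <- mamsadapt:::cum_stats(st$obs, j)
      z <- (stt$mean[2] - stt$mean[1]) * sqrt(stt$n[1] / 2)
      if (j < res$stop_stage) expect_lt(z, cb[j])
    }
    j <- res$stop_stage
    stt <- mamsadapt:::cum_stats(st$obs, j)
    z <- (stt$mean[2] - stt$mean[1]) * sqrt(stt$n[1] / 2)
    expect_equal(res$rejected[1], z >= cb[j])
  }
})

test_that("three-stage designs run and four-stage adaptation is refused", {
  d3 <- socrates_design(n_stages = 3)
  st <- simulate_trial(d3, delta = c(0.3, 0.3, 0.3), seed = 77)
  expect_named(st, c("cumulative", "obs", "selected"))
  expect_true(st$cumulative$stop_stage %in% 1:3)
  d4 <- mams_design(2, 4, c(10, 20, 30, 40))
  obs4 <- make_obs(n = list(rep(10, 3), rep(20, 3)),
                   mean = list(rep(0, 3), rep(0, 3)),
                   sd = list(rep(1, 3), rep(1, 3)))
  expect_error(cumulative_closed_test(d4, obs4), "2 or 3 stages")
})
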