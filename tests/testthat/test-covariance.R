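test_that("design validation enforces the declared invariants", {
  expect_error(mams_design(3, 2, c(97, 49)), "increasing")
  expect_error(mams_design(3, 2, c(49, 97), alpha = 0.6), "alpha")
  expect_error(mams_design(3, 2, c(49, 97), sigma = c(1, -1, 1, 1)),
               "positive")
  expect_error(mams_design(3, 2, c(49, 97), weights = c(0.5, 0.5)),
               "h_j")
  d <- mams_design(2, 3, c(10, 20, 30), allocation = c(1, 2))
  expect_equal(sum(d$weights^2), 1, tolerance = 1e-12)
  expect_equal(planned_n(d)["arm2", ], c(stage1 = 20, stage2 = 40,
                                         stage3 = 60))
})

test_that("Fisher information matches its closed form and is monotone", {
  d0 <- mams_design(1, 2, c(2, 4))
  expect_equal(information(d0, 1, 1), 1)          # 2 * (1 + 1)^-1
  soc <- socrates_design()
  expect_equal(information(soc, 1, 1), 49 / (2 * 0.52^2), tolerance = 1e-12)
  expect_within(information(soc, 1, 1), 90.606, 1e-3)
  for (arm in 1:3) {
    expect_gt(information(soc, arm, 2), information(soc, arm, 1))
  }
  expect_error(information(soc, 4, 1), "arm")
  expect_error(information(soc, 1, 3), "stage")
})

test_that("score covariance has the Brownian one-factor structure", {
  d <- mams_design(2, 2, c(30, 60))
  sc <- score_covariance(d)
  # cross-arm correlation 0.5 under equal allocation and variances
  expect_equal(sc$corr[1, 2], 0.5, tolerance = 1e-12)
  # within-arm across-stage correlation sqrt(I1/I2)
  i1 <- information(d, 1, 1); i2 <- information(d, 1, 2)
  expect_equal(sc$corr[1, 3], sqrt(i1 / i2), tolerance = 1e-12)
  expect_equal(sc$corr[1, 3], sqrt(0.5), tolerance = 1e-12)
  # increments are uncorrelated with the earlier cumulative statistic:
  # cov(W_i(2), W_i1) = cov(W_i2, W_i1) - var(W_i1) = 0
  expect_equal(sc$cov[1, 3] - sc$cov[1, 1], 0, tolerance = 1e-12)
  # unequal allocation/variances: cross-arm corr is s0^2 sqrt(L1 L2)
  du <- mams_design(2, 2, c(30, 60), sigma = c(1, 1.3, 0.8),
                    allocation = c(1, 2))
  scu <- score_covariance(du)
  L <- 1 / (1 + c(1.3^2 / 1, 0.8^2 / 2))
  expect_equal(scu$corr[1, 2], sqrt(prod(L)), tolerance = 1e-12)
  expect_error(score_covariance(d, arms = integer(0)), "nonempty")
})

test_that("patient-level simulation reproduces the score covariance", {
  d <- mams_design(2, 2, c(12, 24), sigma = c(1, 1.2, 0.9),
                   allocation = c(1, 1.5))
  delta <- c(0.3, 0.1)
  np <- planned_n(d)
  reps <- 1e5
  set.seed(401)
  mean_arm <- function(a, n) matrix(rnorm(reps * n, 0, d$sigma[a + 1]),
                                    reps, n)
  W <- matrix(0, reps, 4)           # W11 W21 W1(2) W2(2) building blocks
  x0 <- cbind(mean_arm(0, np[1, 1]), mean_arm(0, np[1, 2] - np[1, 1]))
  x1 <- delta[1] + cbind(mean_arm(1, np[2, 1]),
                         mean_arm(1, np[2, 2] - np[2, 1]))
  x2 <- delta[2] + cbind(mean_arm(2, np[3, 1]),
                         mean_arm(2, np[3, 2] - np[3, 1]))
  cum_mean <- function(x, n1) {
    cbind(rowMeans(x[, seq_len(n1)]), rowMeans(x))
  }
  m0 <- cum_mean(x0, np[1, 1]); m1 <- cum_mean(x1, np[2, 1])
  m2 <- cum_mean(x2, np[3, 1])
  I <- rbind(information(d, 1, 1:2), information(d, 2, 1:2))
  Wmat <- cbind((m1[, 1] - m0[, 1]) * I[1, 1], (m2[, 1] - m0[, 1]) * I[2, 1],
                (m1[, 2] - m0[, 2]) * I[1, 2], (m2[, 2] - m0[, 2]) * I[2, 2])
  sc <- score_covariance(d, delta = delta)
  emp <- cov(Wmat)
  se <- sqrt((outer(diag(sc$cov), diag(sc$cov)) + sc$cov^2) / reps)
  expect_true(all(abs(emp - sc$cov) < 3.5 * se))
  expect_true(all(abs(colMeans(Wmat) - sc$mean) < 4 * sqrt(diag(sc$cov) / reps)))
  # incremental statistics are uncorrelated with stage-1 statistics
  winc <- Wmat[, 3:4] - Wmat[, 1:2]
  r <- cor(cbind(Wmat[, 1:2], winc))[1:2, 3:4]
  expect_true(all(abs(r) < 3 / sqrt(reps) * sqrt(1e4)))  # |r| < 0.03
})

test_that("observations round-trip through summary tables", {
  obs <- make_obs(n = list(c(10, 10, 9), c(20, 21, 19)),
                  mean = list(c(0.1, 0.4, 0.2), c(0.05, 0.3, 0.25)),
                  sd = list(c(1, 1.1, 0.9), c(1, 1.05, 0.95)))
  df <- data.frame(arm = rep(0:2, 2), stage = rep(1:2, each = 3),
                   n = c(10, 10, 9, 20, 21, 19),
                   mean = c(0.1, 0.4, 0.2, 0.05, 0.3, 0.25),
                   sd = c(1, 1.1, 0.9, 1, 1.05, 0.95))
  obs2 <- as_observations(df)
  expect_equal(obs, obs2)
  s2 <- cum_stats <- mamsadapt:::cum_stats(obs, 2)
  expect_equal(s2$mean, c(0.05, 0.3, 0.25))
  expect_equal(s2$var, df$sd[4:6]^2)
  inc <- mamsadapt:::inc_stats(obs, 2)
  expect_equal(inc$n, c(10, 11, 10))
  expect_equal(inc$mean[1], (20 * 0.05 - 10 * 0.1) / 10)
  expect_error(as_observations(df[, -3]), "columns")
})
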