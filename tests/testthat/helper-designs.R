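# Shared fixtures and independent oracles.  Everything is generated in
# code; nothing is read from disk.

# absolute-difference expectation (expect_equal tolerances are relative)
expect_within <- function(actual, expected, tol) {
  testthat::expect_lt(max(abs(actual - expected)), tol)
}

# the 388-patient three-dose heart-failure redesign: 97/arm, sigma 0.52,
# drop a dose at the interim when its effect estimate is negative
socrates_design <- function(n_stages = 2, selection_threshold = 0,
                            reallocation = "proportional_upscaling") {
  n_control <- if (n_stages == 2) c(49, 97) else c(32, 65, 97)
  mams_design(n_arms = 3, n_stages = n_stages, n_control = n_control,
              alpha = 0.025, sigma = 0.52,
              selection_threshold = selection_threshold,
              reallocation = reallocation)
}

# independent oracle for two-arm (k = 1) group-sequential boundaries:
# the classical recursive density integration on a trapezoid grid
gs_boundaries_oracle <- function(info_fractions, alpha,
                                 spending = ldobf_spending,
                                 h = 0.002, range = 8.5) {
  J <- length(info_fractions)
  cum_alpha <- spending(info_fractions, alpha)
  alpha_j <- diff(c(0, cum_alpha))
  t_inc <- diff(c(0, info_fractions))
  grid <- seq(-range, range, by = h)
  crit <- numeric(J)
  # work on the score scale with information = info fraction
  dens <- dnorm(grid, sd = sqrt(t_inc[1]))       # stage-1 score density
  crit[1] <- qnorm(1 - alpha_j[1]) * sqrt(info_fractions[1])
  for (j in seq_len(J)[-1]) {
    keep <- grid < crit[j - 1]
    w <- rep(h, sum(keep)); w[1] <- w[length(w)] <- h / 2
    f <- function(b) {
      cross <- pnorm((b - grid[keep]) / sqrt(t_inc[j]), lower.tail = FALSE)
      sum(w * dens[keep] * cross) - alpha_j[j]
    }
    crit[j] <- uniroot(f, c(0, 6), extendInt = "downX", tol = 1e-9)$root
    # propagate the density of the surviving paths
    newdens <- vapply(grid, function(x) {
      sum(w * dens[keep] * dnorm(x - grid[keep], sd = sqrt(t_inc[j])))
    }, 0)
    dens <- newdens
  }
  crit / sqrt(info_fractions)                    # Wald scale
}

# Monte-Carlo draws of correlated (corr rho) standardized maxima
rmax_mvn <- function(n, k, rho = 0.5) {
  z0 <- rnorm(n)
  z <- sqrt(rho) * z0 + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
  apply(z, 1, max)
}

# build a mams_observations object from explicit per-stage cumulative
# summaries (vectors over arms, control first)
make_obs <- function(n, mean, sd) {
  mams_observations(do.call(cbind, n), do.call(cbind, mean),
                    do.call(cbind, sd))
}
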