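# Exact numerical power for the idealized two-active-dose, two-stage
# setting with no early stopping, no selection and no sample-size change,
# plus single-stage Dunnett power and sample size.
#
# Both procedures spend all of alpha at the final analysis.  The cumulative
# procedure rejects when either cumulative score crosses b2, the
# two-comparison Dunnett critical value on the final information; the
# stage-wise procedure rejects when the inverse-normal combination
# h1*z_{p1} + h2*z_{p(2)} of the two stage-wise max-statistic Dunnett
# p-values reaches z_alpha.  Power is a double integral over the stage-1
# scores (Gauss-Hermite, after Cholesky transform) of a bivariate-normal
# rectangle probability of the independent stage-2 increments.

#' Single-look critical value for the maximum of k comparisons
#'
#' Solves `P0(max_g X_g >= c) = alpha` for `k` exchangeable standardized
#' comparison statistics with cross correlation `rho` (the one-sided
#' Dunnett critical value).
#'
#' @param k Number of comparisons.
#' @param alpha One-sided level.
#' @param rho Cross-comparison correlation (default 0.5).
#' @param df Degrees of freedom (`Inf` = normal).
#' @return Critical value on the standardized scale.
#' @export
dunnett_crit <- function(k, alpha, rho = 0.5, df = Inf) {
  R <- matrix(rho, k, k); diag(R) <- 1
  f <- function(c) {
    p <- if (is.finite(df)) mvt_lower(rep(c, k), df = df, corr = R)
    else mvn_lower(rep(c, k), corr = R)
    (1 - p) - alpha
  }
  uniroot(f, c(0, 10), extendInt = "downX", tol = 1e-9)$root
}

# shared scaffolding for the two power integrals
power_setting <- function(delta, alpha, info, rho, nodes) {
  stopifnot(length(info) == 2, info[1] > 0, info[1] < info[2])
  delta <- rep_len(delta, 2)
  I1 <- info[1]; Iinc <- info[2] - info[1]
  R <- matrix(c(1, rho, rho, 1), 2)
  gq <- statmod::gauss.quad(nodes, kind = "hermite")
  # W_1 ~ N(delta * I1, I1 * R); map the product Hermite rule through the
  # Cholesky factor so nodes follow the stage-1 law
  L <- chol(I1 * R)
  zz <- sqrt(2) * gq$nodes
  ww <- gq$weights / sqrt(pi)
  grid <- expand.grid(a = seq_len(nodes), b = seq_len(nodes))
  W <- cbind(zz[grid$a], zz[grid$b]) %*% L +
    rep(1, nrow(grid)) %*% t(delta * I1)
  list(delta = delta, I1 = I1, Iinc = Iinc, R = R, rho = rho,
       W = W, wt = ww[grid$a] * ww[grid$b], alpha = alpha)
}

#' Analytic power of the cumulative two-dose procedure
#'
#' Probability of rejecting the global null for true effects
#' `delta = (delta1, delta2)` with the no-early-stopping cumulative
#' procedure at one-sided level `alpha`.
#'
#' @param delta True effects, length 2 (scalar recycled).
#' @param alpha One-sided level (default 0.05).
#' @param info Cumulative statistical information at the two stages
#'   (default `c(0.5, 1)`).
#' @param rho Cross-dose score correlation (default 0.5).
#' @param nodes Gauss-Hermite nodes per dimension (default 96; absolute
#'   accuracy well below 5e-4).
#' @return Rejection probability.
#' @export
p_cumul <- function(delta, alpha = 0.05, info = c(0.5, 1), rho = 0.5,
                    nodes = 96) {
  s <- power_setting(delta, alpha, info, rho, nodes)
  b2 <- dunnett_crit(2, alpha, rho) * sqrt(info[2])
  sdinc <- sqrt(s$Iinc)
  mu_inc <- s$delta * s$Iinc
  accept <- vapply(seq_len(nrow(s$W)), function(r) {
    mvn_lower(b2 - s$W[r, ], mean = mu_inc, sd = sdinc, corr = s$R)
  }, 0)
  1 - sum(s$wt * accept)
}

#' Analytic power of the stage-wise two-dose procedure
#'
#' Probability of rejecting the global null with the inverse-normal
#' combination of the two stage-wise Dunnett p-values, for the same
#' setting as [p_cumul].  The stage-2 scores are confined to the region
#' below `F2inv(g)` where `F2` is the null CDF of the maximum incremental
#' score and `g = pnorm((z_alpha - h1 * z_{p1}) / h2)`.
#'
#' @inheritParams p_cumul
#' @param weights Inverse-normal weights `(h1, h2)`, `h1^2 + h2^2 = 1`
#'   (default `sqrt(c(0.5, 0.5))`).
#' @return Rejection probability.
#' @export
p_stage <- function(delta, alpha = 0.05, info = c(0.5, 1),
                    weights = sqrt(c(0.5, 0.5)), rho = 0.5, nodes = 96) {
  stopifnot(abs(sum(weights^2) - 1) < 1e-8)
  s <- power_setting(delta, alpha, info, rho, nodes)
  h1 <- weights[1]; h2 <- weights[2]
  za <- qnorm(1 - alpha)
  sd1 <- sqrt(s$I1); sdinc <- sqrt(s$Iinc)
  mu_inc <- s$delta * s$Iinc
  # null CDF of max standardized pair and its inverse (spline over a fine
  # grid; exact TVPACK values at the knots)
  ygrid <- seq(-8, 8, by = 0.01)
  Fg <- vapply(ygrid, function(y) mvn_lower(c(y, y), corr = s$R), 0)
  keep <- c(TRUE, diff(Fg) > 0)          # strictly increasing knots only
  Finv <- splinefun(Fg[keep], ygrid[keep], method = "hyman")
  Flo <- min(Fg[keep]); Fhi <- max(Fg[keep])
  accept <- vapply(seq_len(nrow(s$W)), function(r) {
    m1 <- max(s$W[r, ]) / sd1
    p1 <- 1 - mvn_lower(c(m1, m1), corr = s$R)
    g <- pnorm((za - h1 * qnorm(1 - clip_p(p1))) / h2)
    if (g >= Fhi) return(1)
    if (g <= Flo) return(0)
    q <- Finv(g) * sdinc          # score-scale upper limit for both doses
    mvn_lower(c(q, q), mean = mu_inc, sd = sdinc, corr = s$R)
  }, 0)
  1 - sum(s$wt * accept)
}

#' Single-stage Dunnett power and sample size
#'
#' Global power (probability of rejecting at least one comparison) of a
#' single-stage design comparing `k` arms with a common control under
#' equal allocation: `P(max_g T_g >= c)` with the Dunnett critical value
#' `c` at one-sided level `alpha`.  With `use_t = FALSE` (default) the
#' known-variance multivariate normal law is used; with `use_t = TRUE` the
#' central/shifted multivariate t with `(k+1) n - (k+1)` degrees of
#' freedom.
#'
#' @param n Per-arm sample size.
#' @param k Number of treatment arms.
#' @param delta True effects (scalar recycled to `k`).
#' @param sigma Common response SD.
#' @param alpha One-sided level.
#' @param use_t Use the multivariate-t law instead of the normal.
#' @return `dunnett_power`: the global power. `dunnett_sample_size`: the
#'   smallest integer per-arm `n` reaching `power`.
#' @examples
#' dunnett_power(97, k = 3, delta = 0.187, sigma = 0.52, alpha = 0.025)
#' @export
dunnett_power <- function(n, k, delta, sigma, alpha = 0.025,
                          use_t = FALSE) {
  stopifnot(n >= 2, k >= 1)
  delta <- rep_len(delta, k)
  R <- matrix(0.5, k, k); diag(R) <- 1
  shift <- delta * sqrt(n / 2) / sigma
  if (use_t) {
    df <- (k + 1) * (n - 1)
    cv <- dunnett_crit(k, alpha, df = df)
    p <- with_fixed_seed(mvtnorm::pmvt(
      upper = rep(cv, k), delta = shift, df = as.integer(df), corr = R,
      algorithm = mvtnorm::GenzBretz(maxpts = 250000, abseps = 1e-6,
                                     releps = 0)))
    1 - as.numeric(p)
  } else {
    cv <- dunnett_crit(k, alpha)
    1 - mvn_lower(rep(cv, k) - shift, corr = R)
  }
}

#' @rdname dunnett_power
#' @param power Target global power.
#' @export
dunnett_sample_size <- function(power, k, delta, sigma, alpha = 0.025,
                                use_t = FALSE) {
  stopifnot(power > 0, power < 1)
  if (all(rep_len(delta, k) <= 0))
    stop("target power is unreachable with no positive effect")
  n <- 2
  while (dunnett_power(n, k, delta, sigma, alpha, use_t) < power) {
    n <- n + 1
    if (n > 1e6) stop("target power unreachable at any practical n")
  }
  n
}
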