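# Deterministic multivariate normal / t orthant probabilities.
#
# All boundary, conditional-error and p-value computations in the package
# funnel through these two helpers so that every caller gets the same
# numerical conventions: TVPACK (deterministic to ~1e-14) up to dimension 3,
# and the Genz-Bretz quasi-Monte-Carlo algorithm with an internally fixed
# seed above that, so results are reproducible bit-for-bit per build.

.ORTHANT_SEED <- 907211L

with_fixed_seed <- function(expr, seed = .ORTHANT_SEED) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# P(Z_1 < upper_1, ..., Z_k < upper_k) for Z ~ N(mean, diag(sd) %*% corr %*% diag(sd))
mvn_lower <- function(upper, mean = 0, sd = 1, corr = NULL, abseps = 1e-6) {
  u <- (upper - mean) / sd
  if (any(u == -Inf)) return(0)
  keep <- is.finite(u)
  if (!any(keep)) return(1)
  u <- u[keep]
  k <- length(u)
  if (k == 1L) return(pnorm(u))
  R <- corr[keep, keep, drop = FALSE]
  if (k <= 3L) {
    p <- mvtnorm::pmvnorm(upper = u, corr = R,
                          algorithm = mvtnorm::TVPACK(abseps = 1e-12))
    return(as.numeric(p))
  }
  for (maxpts in c(25000L, 100000L, 500000L)) {
    p <- with_fixed_seed(mvtnorm::pmvnorm(
      upper = u, corr = R,
      algorithm = mvtnorm::GenzBretz(maxpts = maxpts, abseps = abseps,
                                     releps = 0)))
    if (attr(p, "error") <= abseps * 1.5) break
  }
  as.numeric(p)
}

# P(T_1 < upper_1, ..., T_k < upper_k) for central multivariate t
mvt_lower <- function(upper, df, corr = NULL, abseps = 1e-6) {
  if (any(upper == -Inf)) return(0)
  keep <- is.finite(upper)
  if (!any(keep)) return(1)
  u <- upper[keep]
  k <- length(u)
  if (!is.finite(df)) return(mvn_lower(u, corr = corr[keep, keep, drop = FALSE]))
  if (k == 1L) return(pt(u, df = df))
  R <- corr[keep, keep, drop = FALSE]
  if (k <= 3L) {
    p <- mvtnorm::pmvt(upper = u, df = as.integer(df), corr = R,
                       algorithm = mvtnorm::TVPACK(abseps = 1e-12))
    return(as.numeric(p))
  }
  for (maxpts in c(25000L, 100000L, 500000L)) {
    p <- with_fixed_seed(mvtnorm::pmvt(
      upper = u, df = as.integer(df), corr = R,
      algorithm = mvtnorm::GenzBretz(maxpts = maxpts, abseps = abseps,
                                     releps = 0)))
    if (attr(p, "error") <= abseps * 1.5) break
  }
  as.numeric(p)
}

# covariance matrix -> correlation matrix
cov2corr <- function(S) {
  d <- 1 / sqrt(diag(S))
  R <- S * tcrossprod(d)
  diag(R) <- 1
  R
}
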