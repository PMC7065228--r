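# Error spending and group-sequential efficacy boundaries for the maximum
# of correlated score statistics (k treatment-control comparisons), on the
# Wald scale z_j = W_j / sqrt(I_j).  Boundaries solve, stage by stage,
#   P0(no crossing before stage j, max_g z_gj >= u_j) = alpha_j,
# where alpha_j is the increment of the spending function at the stage-j
# information fraction.  With k = 1 these are the classical two-arm
# group-sequential boundaries.

#' Lan-DeMets O'Brien-Fleming-type error spending
#'
#' Cumulative one-sided type-1 error spent at information fraction `t`:
#' `f(t) = 2 - 2 * pnorm(qnorm(1 - alpha/2) / sqrt(t))`, with `f(1) = alpha`.
#'
#' @param t Information fraction(s) in (0, 1].
#' @param alpha Total one-sided type-1 error.
#' @return Cumulative error spent (vectorized over `t`).
#' @export
ldobf_spending <- function(t, alpha) {
  if (any(t <= 0)) stop("information fraction must be positive")
  t <- pmin(t, 1)
  2 - 2 * pnorm(qnorm(1 - alpha / 2) / sqrt(t))
}

spending_fun <- function(spending) {
  if (is.function(spending)) return(spending)
  switch(spending, ldobf = ldobf_spending,
         stop("unknown spending function: ", spending))
}

# correlation of the Wald-scale statistics z_gj over k arms x J stages,
# entry ((j,g),(l,h)): rho_gh * sqrt(t_min/t_max); rho_gh is the common-
# stage cross-arm correlation matrix (0.5 under equal allocation/variance).
wald_corr <- function(k, info_fractions, rho = 0.5) {
  J <- length(info_fractions)
  R_arm <- if (is.matrix(rho)) rho else {
    m <- matrix(rho, k, k); diag(m) <- 1; m
  }
  S <- matrix(0, J * k, J * k)
  for (j in seq_len(J)) for (l in seq_len(J)) {
    tmin <- min(info_fractions[j], info_fractions[l])
    tmax <- max(info_fractions[j], info_fractions[l])
    S[(j - 1) * k + seq_len(k), (l - 1) * k + seq_len(k)] <-
      R_arm * sqrt(tmin / tmax)
  }
  S
}

#' Group-sequential boundaries for the maximum of k comparisons
#'
#' @param k Number of treatment-control comparisons adjusted for.
#' @param info_fractions Increasing information fractions, ending at 1.
#' @param alpha One-sided family-wise type-1 error.
#' @param rho Cross-arm correlation at a common stage: a scalar (default
#'   0.5, equal allocation and variances) or a `k x k` matrix.
#' @param spending Spending function identifier or `function(t, alpha)`.
#' @return An object of class `gs_boundaries`: a data frame with columns
#'   `stage`, `info_fraction`, `alpha_spent` (incremental), `z` (Wald-scale
#'   boundary), carrying `k`, `rho` and `alpha` as attributes.
#' @examples
#' max_stat_boundaries(k = 4, info_fractions = c(0.5, 1), alpha = 0.025)
#' @export
max_stat_boundaries <- function(k, info_fractions, alpha, rho = 0.5,
                                spending = "ldobf") {
  stopifnot(k >= 1)
  J <- length(info_fractions)
  if (J > 1 && any(diff(info_fractions) <= 0))
    stop("information fractions must be strictly increasing")
  if (abs(info_fractions[J] - 1) > 1e-9)
    stop("information fractions must end at 1")
  f <- spending_fun(spending)
  cum_alpha <- f(info_fractions, alpha)
  alpha_j <- diff(c(0, cum_alpha))
  S <- wald_corr(k, info_fractions, rho)
  z <- numeric(J)
  noncross_prev <- 1      # P0(all stages so far below their boundaries)
  for (j in seq_len(J)) {
    dims <- seq_len(j * k)
    Rj <- S[dims, dims, drop = FALSE]
    g <- function(u) {
      nc <- mvn_lower(c(rep(z[seq_len(j - 1)], each = k), rep(u, k)),
                      corr = Rj)
      (noncross_prev - nc) - alpha_j[j]
    }
    lo <- 0; hi <- 12
    if (g(lo) < 0 || g(hi) > 0)
      stop("boundary root not bracketed at stage ", j,
           "; check spending and information fractions")
    z[j] <- uniroot(g, c(lo, hi), tol = 1e-6)$root
    noncross_prev <- mvn_lower(rep(z[seq_len(j)], each = k),
                               corr = S[seq_len(j * k), seq_len(j * k),
                                        drop = FALSE])
  }
  out <- data.frame(stage = seq_len(J), info_fraction = info_fractions,
                    alpha_spent = alpha_j, z = z)
  attr(out, "k") <- k
  attr(out, "rho") <- rho
  attr(out, "alpha") <- alpha
  class(out) <- c("gs_boundaries", "data.frame")
  out
}

#' @export
print.gs_boundaries <- function(x, ...) {
  cat(sprintf(
    "Group-sequential boundaries: max of %d comparison(s), one-sided alpha %g\n",
    attr(x, "k"), attr(x, "alpha")))
  print.data.frame(cbind.data.frame(x,
    nominal_p = signif(pnorm(x$z, lower.tail = FALSE), 4)), row.names = FALSE)
  invisible(x)
}

#' Stage-wise boundary-crossing probabilities
#'
#' Probability that the maximum of `k` Wald-scale statistics first crosses
#' its boundary at each stage, for arbitrary per-arm mean shifts.
#'
#' @param boundaries A [max_stat_boundaries] result, or a numeric vector of
#'   Wald-scale boundaries (then `k`, `info_fractions`, `rho` must be given).
#' @param mean Wald-scale mean shifts: a `k x J` matrix (arm by stage), a
#'   length-`k` vector applied to the final stage and scaled back by
#'   `sqrt(info_fraction)`, or a scalar.
#' @param k,info_fractions,rho See [max_stat_boundaries]; taken from
#'   `boundaries` when it is a `gs_boundaries` object.
#' @return Numeric of length `J + 1`: the per-stage first-crossing
#'   probabilities and, last, the probability of never crossing.
#' @export
max_stat_exit_prob <- function(boundaries, mean = 0, k = NULL,
                               info_fractions = NULL, rho = 0.5) {
  if (inherits(boundaries, "gs_boundaries")) {
    k <- attr(boundaries, "k")
    rho <- attr(boundaries, "rho")
    info_fractions <- boundaries$info_fraction
    z <- boundaries$z
  } else z <- as.numeric(boundaries)
  J <- length(z)
  if (is.matrix(mean)) {
    stopifnot(nrow(mean) == k, ncol(mean) == J)
    mu <- mean
  } else {
    muJ <- rep_len(mean, k)
    mu <- outer(muJ, sqrt(info_fractions))   # Brownian mean scales as sqrt(t)
  }
  S <- wald_corr(k, info_fractions, rho)
  exit <- numeric(J + 1)
  prev <- 1
  for (j in seq_len(J)) {
    dims <- seq_len(j * k)
    nc <- mvn_lower(rep(z[seq_len(j)], each = k) - as.vector(mu[, seq_len(j)]),
                    corr = S[dims, dims, drop = FALSE])
    exit[j] <- prev - nc
    prev <- nc
  }
  exit[J + 1] <- prev
  names(exit) <- c(paste0("stage", seq_len(J)), "never")
  exit
}

#' Small-sample t-scale boundary adjustment
#'
#' Transforms a score-scale boundary `b` into `b* = sqrt(Ihat) *
#' qt(pnorm(b / sqrt(Ihat)), df)`, replacing the normal boundary percentile
#' by the matching Student-t percentile; `b*` converges to `b` as `df` grows.
#' Used when the Fisher information is estimated from the data.
#'
#' @param b Score-scale boundary (vectorized).
#' @param info Estimated Fisher information (positive).
#' @param df Degrees of freedom (`n_0j + n_ij - 1`).
#' @return Adjusted score-scale boundary.
#' @export
t_adjust_boundary <- function(b, info, df) {
  stopifnot(all(info > 0), all(df >= 1))
  sqrt(info) * qt(pnorm(b / sqrt(info)), df)
}
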