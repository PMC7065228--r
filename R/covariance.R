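# Joint distribution of the cumulative score statistics W_ij.
#
# W_ij = deltahat_ij * I_ij behaves as a multivariate Brownian process:
#   E(W_ij)            = delta_i * I_ij
#   var(W_ij)          = I_ij = n_0j * Lambda_i,  Lambda_i = 1/(s0^2 + si^2/lambda_i)
#   cov(W_ij, W_ij')   = I_i,min(j,j')
#   cov(W_gj, W_hj)    = Lambda_g * Lambda_h * s0^2 * n_0j  (g != h)
# Increments between stages are independent of the earlier cumulative
# statistics.

# Lambda_i = (sigma_0^2 + sigma_i^2 / lambda_i)^{-1}, one per treatment arm
lambda_coef <- function(design, sigma = design$sigma,
                        allocation = design$allocation) {
  1 / (sigma[1]^2 + sigma[-1]^2 / allocation)
}

#' Fisher information of a treatment-control comparison
#'
#' Information about `delta_i` from cumulative data up to `stage`:
#' `I_ij = n_0j / (sigma_0^2 + sigma_i^2 / lambda_i)`.
#'
#' @param design A [mams_design].
#' @param arm Treatment arm index (1..`n_arms`); vectorized.
#' @param stage Stage index (1..`n_stages`); vectorized.
#' @return Fisher information (numeric).
#' @export
information <- function(design, arm, stage) {
  stopifnot(inherits(design, "mams_design"))
  if (any(arm < 1 | arm > design$n_arms)) stop("invalid `arm` index")
  if (any(stage < 1 | stage > design$n_stages)) stop("invalid `stage` index")
  design$n_control[stage] * lambda_coef(design)[arm]
}

#' Joint distribution of a block of score statistics
#'
#' Means, variances and correlations of the cumulative score statistics
#' `W_ij` for the requested arms and stages, under true effects `delta`.
#'
#' @param design A [mams_design].
#' @param arms,stages Index subsets (default: all).
#' @param delta True effect vector (length `n_arms`, recycled).
#' @return A list of class `score_distribution` with elements `arms`,
#'   `stages`, `mean`, `cov`, `corr`; entries are ordered arm-fastest within
#'   stage.
#' @export
score_covariance <- function(design, arms = seq_len(design$n_arms),
                             stages = seq_len(design$n_stages),
                             delta = 0) {
  stopifnot(inherits(design, "mams_design"))
  if (length(arms) == 0 || length(stages) == 0)
    stop("`arms` and `stages` must be nonempty")
  if (any(arms < 1 | arms > design$n_arms)) stop("invalid `arms`")
  if (any(stages < 1 | stages > design$n_stages)) stop("invalid `stages`")
  delta <- rep_len(delta, design$n_arms)
  Lam <- lambda_coef(design)
  s0sq <- design$sigma[1]^2
  idx <- expand.grid(arm = arms, stage = stages)
  k <- nrow(idx)
  mu <- delta[idx$arm] * design$n_control[idx$stage] * Lam[idx$arm]
  S <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    g <- idx$arm[a]; h <- idx$arm[b]
    nmin <- design$n_control[min(idx$stage[a], idx$stage[b])]
    S[a, b] <- if (g == h) nmin * Lam[g] else Lam[g] * Lam[h] * s0sq * nmin
  }
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("score covariance is not positive semidefinite; check variances")
  structure(list(arms = arms, stages = stages,
                 labels = paste0("W", idx$arm, ".", idx$stage),
                 mean = mu, cov = S, corr = cov2corr(S)),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("Score-statistic distribution (", length(x$mean), " components)\n",
      sep = "")
  m <- cbind(mean = x$mean, var = diag(x$cov))
  rownames(m) <- x$labels
  print(signif(m, 5))
  cat("correlation:\n")
  print(signif(x$corr, 4))
  invisible(x)
}

# Incremental-data information for stage j increments:
# I_i(j) = (n_0j - n_0,j-1) * Lambda_i
info_increment <- function(design, stage) {
  n_inc <- diff(c(0, design$n_control))[stage]
  n_inc * lambda_coef(design)
}

# Cross-arm correlation of score statistics at a common stage (or of
# incremental statistics): Lambda_g Lambda_h s0^2 n / sqrt(I_g I_h)
# = s0^2 sqrt(Lambda_g Lambda_h), free of n.
cross_arm_corr <- function(sigma0sq, Lam) {
  k <- length(Lam)
  R <- sigma0sq * sqrt(outer(Lam, Lam))
  diag(R) <- 1
  R
}

# Dunnett correlation from sample sizes only (allocation-driven):
# corr(t_g, t_h) = sqrt(n_g n_h / ((n_g + n_0)(n_h + n_0)))
dunnett_corr <- function(n0, n_arms_vec) {
  r <- sqrt(n_arms_vec / (n_arms_vec + n0))
  R <- tcrossprod(r)
  diag(R) <- 1
  R
}
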