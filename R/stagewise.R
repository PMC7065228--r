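# The stage-wise MAMS closed test: multiplicity-adjusted p-values from the
# incremental data of each stage, combined by the inverse-normal rule and
# monitored against classical two-arm group-sequential boundaries.  The
# two-arm boundaries only protect the multiplicity of looking at the same
# hypothesis repeatedly; the across-arm multiplicity is absorbed by the
# adjusted p-values.

#' Inverse-normal combination of stage-wise p-values
#'
#' `Z_j = sum_{k<=j} h_k qnorm(1 - p_k) / sqrt(sum_{k<=j} h_k^2)`.  With
#' prespecified weights each `Z_j` is standard normal under the null even
#' when later-stage sample sizes are data dependent.  P-values are clipped
#' to `[1e-15, 1 - 1e-15]` before the quantile transform.
#'
#' @param p Stage-wise adjusted p-values (length = stages observed so far).
#' @param weights Prespecified weights `h` with `sum(h^2) = 1` over the full
#'   design; only the first `length(p)` entries are used, renormalized.
#' @return The combined Z statistic for the latest stage supplied.
#' @export
inverse_normal_combine <- function(p, weights) {
  j <- length(p)
  stopifnot(j >= 1, length(weights) >= j)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  h <- weights[seq_len(j)]
  sum(h * qnorm(1 - clip_p(p))) / sqrt(sum(h^2))
}

#' Stage-wise MAMS closed test
#'
#' For every nonempty subset `I` of the treatment arms, combines the
#' stage-wise multiplicity-adjusted p-values `p_I(j)` ([stage_pvalue]) by
#' the inverse-normal rule and monitors the combination against the two-arm
#' group-sequential boundaries.  An elementary hypothesis is rejected at
#' stage `j` when every intersection containing it has crossed at some
#' stage up to `j`.  Stage-1 components always use the full subset `I`
#' (dropped arms' stage-1 data retain their role in the adjustment); stage-2
#' and later components are restricted to the selected arms.
#'
#' @inheritParams cumulative_closed_test
#' @param method Adjusted p-value flavor: `"dunnett"`, `"bonferroni"` or
#'   `"simes"`.
#' @return An object of class `mams_test`; `intersections` records the
#'   per-subset combination statistics per stage.
#' @export
stagewise_closed_test <- function(design, obs, selected = NULL,
                                  method = c("dunnett", "bonferroni",
                                             "simes"),
                                  boundaries = NULL) {
  stopifnot(inherits(design, "mams_design"),
            inherits(obs, "mams_observations"))
  method <- match.arg(method)
  if (ncol(obs$n) > design$n_stages)
    stop("observations have more stages than the design")
  if (is.null(boundaries)) boundaries <- mams_boundaries(design)
  if (is.null(selected)) selected <- infer_selected(design, obs)
  res <- stagewise_core(design, obs, selected, boundaries, method,
                        record = TRUE)
  res$method <- paste0("stagewise_", method)
  class(res) <- "mams_test"
  res
}

# core engine (simulator hot path).  `boundaries$z` row 1 is the singleton
# ({1}) row: the classical two-arm boundaries c_j.
stagewise_core <- function(design, obs, selected, boundaries, method,
                           record = FALSE) {
  D <- design$n_arms
  J_obs <- ncol(obs$n)
  subsets <- boundaries$subsets
  nsub <- length(subsets)
  member <- subset_membership(subsets, D)
  cb <- boundaries$z[1, ]                 # k = 1 boundaries
  h <- design$weights

  qsum <- numeric(nsub)
  rejected_sub <- logical(nsub)
  rejected_sub_stage <- rep(NA_integer_, nsub)
  rejected <- logical(D)
  rejected_stage <- rep(NA_integer_, D)
  Zrec <- if (record) matrix(NA_real_, nsub, J_obs) else NULL
  stop_stage <- J_obs

  for (j in seq_len(J_obs)) {
    st <- inc_stats(obs, j)
    for (s in seq_len(nsub)) {
      I_S <- if (j >= 2) intersect(subsets[[s]], selected) else subsets[[s]]
      p <- if (length(I_S) == 0) 1 else
        stagewise_subset_p(st, I_S, design$allocation, method)$p
      qsum[s] <- qsum[s] + h[j] * qnorm(1 - clip_p(p))
    }
    Z <- qsum / sqrt(sum(h[seq_len(j)]^2))
    if (record) Zrec[, j] <- Z
    newly <- !rejected_sub & Z >= cb[j]
    rejected_sub[newly] <- TRUE
    rejected_sub_stage[newly] <- j
    for (i in seq_len(D)) {
      if (!rejected[i] && all(rejected_sub[member[i, ]])) {
        rejected[i] <- TRUE
        rejected_stage[i] <- j
      }
    }
    if (any(rejected)) { stop_stage <- j; break }
  }

  res <- list(rejected = rejected, rejected_stage = rejected_stage,
              stop_stage = stop_stage, max_residual = 0)
  if (record) {
    tab <- data.frame(subset = vapply(subsets, subset_label, ""),
                      k = lengths(subsets),
                      rejected = rejected_sub,
                      rejected_stage = rejected_sub_stage)
    Zd <- as.data.frame(Zrec[, seq_len(stop_stage), drop = FALSE])
    names(Zd) <- paste0("Z", seq_len(stop_stage))
    res$intersections <- cbind(tab, Zd)
    res$c_boundaries <- cb
  }
  res
}
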