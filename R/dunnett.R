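# Multiplicity-adjusted p-values for intersection hypotheses from
# incremental-stage data: exact Dunnett via the multivariate t
# distribution, plus the nonparametric Bonferroni and Simes adjustments.

#' Exact Dunnett p-value for the maximum t statistic
#'
#' `1 - P(all components of a central k-variate t with correlation `corr`
#' and `df` degrees of freedom are below `max_t`)`.  For `k = 1` this is the
#' one-sided univariate t p-value.
#'
#' @param max_t Observed maximum t statistic.
#' @param k Number of comparisons in the intersection.
#' @param df Degrees of freedom (`Inf` for the normal case).
#' @param corr Cross-comparison correlation: scalar (default 0.5) or a
#'   `k x k` positive-definite matrix.
#' @return One-sided adjusted p-value in `[0, 1]`.
#' @export
dunnett_p <- function(max_t, k, df = Inf, corr = 0.5) {
  stopifnot(k >= 1, df >= 1)
  R <- if (is.matrix(corr)) corr else {
    m <- matrix(corr, k, k); diag(m) <- 1; m
  }
  if (nrow(R) != k) stop("`corr` must be k x k")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`corr` must be positive definite")
  1 - mvt_lower(rep(max_t, k), df = df, corr = R)
}

#' Bonferroni and Simes adjusted p-values
#'
#' `bonferroni_p` returns `min(1, k * min(p))`; `simes_p` returns
#' `min_r (k * p_(r) / r)` over the ordered p-values.
#'
#' @param p Vector of marginal one-sided p-values for the comparisons in
#'   the intersection.
#' @return Adjusted p-value in `[0, 1]`.
#' @export
bonferroni_p <- function(p) {
  if (length(p) == 0) stop("empty p-value set")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  min(1, length(p) * min(p))
}

#' @rdname bonferroni_p
#' @export
simes_p <- function(p) {
  if (length(p) == 0) stop("empty p-value set")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  k <- length(p)
  min(1, min(k * sort(p) / seq_len(k)))
}

#' Multiplicity-adjusted stage-wise p-value for an intersection hypothesis
#'
#' Computes the adjusted p-value `p_I(j)` for the intersection of the null
#' hypotheses indexed by `I`, from the incremental data of stage `j`.  At
#' stages after a selection the statistic is restricted to the selected
#' members `I_S = intersect(I, selected)`; an empty `I_S` yields p = 1
#' (conservative, and immaterial for selected arms since every `I`
#' containing a selected arm has it in `I_S`).
#'
#' The Dunnett variant uses incremental t statistics
#' `t_i(j) = deltahat_i(j) * sqrt(Ihat_i(j))` against a central multivariate
#' t with `n_0(j) + sum n_i(j) - |I| - 1` degrees of freedom and a
#' correlation matrix built from the sample sizes (hence the allocation
#' ratios) only.  Bonferroni/Simes combine marginal pooled-variance
#' one-sided two-sample t p-values.
#'
#' @param design A [mams_design].
#' @param obs A [mams_observations] through at least stage `j`.
#' @param I Integer vector of arm indices in the intersection.
#' @param stage Stage index `j`.
#' @param method `"dunnett"`, `"bonferroni"` or `"simes"`.
#' @param selected Arms carried past stage 1 (default: all).
#' @return A list of class `stage_pvalue`: `subset`, `stage`, `method`,
#'   `t` (per-arm incremental t statistics on `I_S`), `df`, `p`.
#' @export
stage_pvalue <- function(design, obs, I, stage,
                         method = c("dunnett", "bonferroni", "simes"),
                         selected = seq_len(design$n_arms)) {
  method <- match.arg(method)
  stopifnot(inherits(design, "mams_design"),
            inherits(obs, "mams_observations"))
  if (length(I) == 0 || any(I < 1 | I > design$n_arms))
    stop("`I` must be a nonempty subset of the treatment arms")
  I_S <- if (stage >= 2) intersect(I, selected) else I
  if (length(I_S) == 0) {
    return(structure(list(subset = I, stage = stage, method = method,
                          t = numeric(0), df = NA_real_, p = 1),
                     class = "stage_pvalue"))
  }
  st <- inc_stats(obs, stage)
  p <- stagewise_subset_p(st, I_S, design$allocation, method)
  structure(list(subset = I, stage = stage, method = method,
                 t = p$t, df = p$df, p = p$p), class = "stage_pvalue")
}

#' @export
print.stage_pvalue <- function(x, ...) {
  cat(sprintf("stage %d %s-adjusted p = %.5g for I = {%s}\n",
              x$stage, x$method, x$p, paste(x$subset, collapse = ",")))
  invisible(x)
}

# core used by stage_pvalue() and the simulator; st = incremental stats
# (full arm set, control first), I_S the restricted subset (nonempty).
stagewise_subset_p <- function(st, I_S, allocation, method) {
  k <- length(I_S)
  n0 <- st$n[1]
  ni <- st$n[I_S + 1L]
  if (method == "dunnett") {
    dhat <- st$mean[I_S + 1L] - st$mean[1]
    info <- n0 / (st$var[1] + st$var[I_S + 1L] / allocation[I_S])
    tstat <- dhat * sqrt(info)
    df <- n0 + sum(ni) - k - 1
    R <- dunnett_corr(n0, ni)
    p <- 1 - mvt_lower(rep(max(tstat), k), df = df, corr = R)
    list(t = tstat, df = df, p = p)
  } else {
    # marginal pooled-variance one-sided two-sample t p-values
    sp2 <- ((n0 - 1) * st$var[1] + (ni - 1) * st$var[I_S + 1L]) / (n0 + ni - 2)
    tstat <- (st$mean[I_S + 1L] - st$mean[1]) / sqrt(sp2 * (1 / n0 + 1 / ni))
    pm <- pt(tstat, df = n0 + ni - 2, lower.tail = FALSE)
    p <- if (method == "bonferroni") bonferroni_p(pm) else simes_p(pm)
    list(t = tstat, df = n0 + ni - 2, p = p)
  }
}
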