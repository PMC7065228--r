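# Patient-level Monte Carlo engine: data generation, interim treatment
# selection, reallocation of dropped arms' enrollment, both closed-testing
# procedures, and operating characteristics (global power, FWER, per-arm
# rejection rates, average sample size).
#
# One trial = one seed.  Per-replicate seeds are drawn up front from the
# master seed, so results do not depend on the order in which replicates
# run; the quasi-Monte-Carlo orthant computations save and restore the RNG
# state and never disturb the data stream.

#' Reallocate dropped arms' planned enrollment
#'
#' With `"proportional_upscaling"`, the unspent planned increments of the
#' dropped arms are redistributed over the continuing arms (control
#' included) proportionally to the original allocation ratios, using
#' largest-remainder integer rounding so each stage's planned total is
#' preserved exactly.  With `"none"` the unspent increments are simply not
#' enrolled.
#'
#' @param planned_inc Planned incremental sample sizes for the remaining
#'   stages: a vector (one stage) or matrix with `n_arms + 1` rows, control
#'   first.
#' @param dropped Indices (1..`n_arms`) of the dropped treatment arms.
#' @param allocation Allocation ratios `lambda_i` of the treatment arms.
#' @param rule `"proportional_upscaling"` or `"none"`.
#' @return Adapted incremental sizes, same shape as `planned_inc`; dropped
#'   rows are zero.  If every treatment arm is dropped under upscaling the
#'   sizes are returned with only the dropped rows zeroed and attribute
#'   `all_dropped = TRUE`.
#' @export
reallocate <- function(planned_inc, dropped, allocation,
                       rule = c("proportional_upscaling", "none")) {
  rule <- match.arg(rule)
  m <- as.matrix(planned_inc)
  D <- nrow(m) - 1L
  stopifnot(length(allocation) == D)
  if (length(dropped) == 0) return(planned_inc)
  if (any(dropped < 1 | dropped > D)) stop("invalid dropped arm index")
  out <- m
  out[dropped + 1L, ] <- 0
  if (rule == "none") {
    if (is.vector(planned_inc)) return(drop(out))
    return(out)
  }
  keep_rows <- setdiff(seq_len(D + 1L), dropped + 1L)
  if (length(keep_rows) == 1L) {          # every treatment arm dropped
    attr(out, "all_dropped") <- TRUE
    if (is.vector(planned_inc)) return(drop(out))
    return(out)
  }
  wts <- c(1, allocation)[keep_rows]
  for (j in seq_len(ncol(m))) {
    extra <- sum(m[dropped + 1L, j])
    share <- extra * wts / sum(wts)
    base <- floor(share)
    rem <- extra - sum(base)
    if (rem > 0) {
      ord <- order(share - base, decreasing = TRUE)[seq_len(rem)]
      base[ord] <- base[ord] + 1
    }
    out[keep_rows, j] <- m[keep_rows, j] + base
  }
  if (is.vector(planned_inc)) drop(out) else out
}

# generate one adaptive trial's data and run the requested procedures
sim_one <- function(design, delta, bounds, methods, t_adjust,
                    known_sigma, single_cv, single_n) {
  D <- design$n_arms
  J <- design$n_stages
  n_plan <- planned_n(design)
  mu <- c(0, delta)
  sig <- design$sigma
  staged <- setdiff(methods, "single_stage_dunnett")

  sx <- sx2 <- nmat <- matrix(0, D + 1L, J)
  # stage 1
  for (a in seq_len(D + 1L)) {
    x <- rnorm(n_plan[a, 1], mu[a], sig[a])
    nmat[a, 1] <- n_plan[a, 1]; sx[a, 1] <- sum(x); sx2[a, 1] <- sum(x * x)
  }
  m1 <- sx[, 1] / nmat[, 1]
  dhat1 <- m1[-1] - m1[1]
  dropped <- which(dhat1 < design$selection_threshold)
  selected <- setdiff(seq_len(D), dropped)
  continue <- length(selected) > 0 && J > 1L

  if (continue) {
    inc_plan <- n_plan[, -1, drop = FALSE] -
      n_plan[, -J, drop = FALSE]
    inc_adapt <- reallocate(inc_plan, dropped, design$allocation,
                            design$reallocation)
    inc_adapt <- as.matrix(inc_adapt)
    for (j in 2:J) {
      for (a in seq_len(D + 1L)) {
        ninc <- inc_adapt[a, j - 1]
        xs <- if (ninc > 0) rnorm(ninc, mu[a], sig[a]) else numeric(0)
        nmat[a, j] <- nmat[a, j - 1] + ninc
        sx[a, j] <- sx[a, j - 1] + sum(xs)
        sx2[a, j] <- sx2[a, j - 1] + sum(xs * xs)
      }
    }
    obs <- obs_from_sums(nmat, sx, sx2)
    n_cum_total <- colSums(nmat)
  } else {
    obs <- obs_from_sums(nmat[, 1, drop = FALSE], sx[, 1, drop = FALSE],
                         sx2[, 1, drop = FALSE])
    n_cum_total <- sum(n_plan[, 1])
  }

  out <- vector("list", length(methods))
  names(out) <- methods
  for (mth in staged) {
    r <- if (mth == "cumulative") {
      cumulative_core(design, obs, selected, bounds, t_adjust = t_adjust,
                      known_sigma = known_sigma)
    } else {
      stagewise_core(design, obs, selected, bounds,
                     sub("^stagewise_", "", mth))
    }
    out[[mth]] <- list(rejected = r$rejected, stop_stage = r$stop_stage,
                       n_total = n_cum_total[r$stop_stage],
                       max_residual = r$max_residual)
  }
  if ("single_stage_dunnett" %in% methods) {
    xs <- matrix(rnorm((D + 1L) * single_n, rep(mu, each = single_n),
                       rep(sig, each = single_n)), single_n, D + 1L)
    ms <- colMeans(xs)
    if (is.null(known_sigma)) {
      vs <- apply(xs, 2, var)
    } else vs <- known_sigma^2
    info <- single_n / (vs[1] + vs[-1] / design$allocation)
    tstat <- (ms[-1] - ms[1]) * sqrt(info)
    rej <- tstat >= single_cv
    out[["single_stage_dunnett"]] <-
      list(rejected = rej, stop_stage = 1L,
           n_total = (D + 1L) * single_n, max_residual = 0)
  }
  out$obs <- obs
  out$selected <- selected
  out
}

#' Simulate a single adaptive MAMS trial
#'
#' Generates patient-level normal responses stage by stage, applies the
#' treatment-selection and reallocation rules at the end of stage 1, stops
#' all enrollment when every dose is dropped or an efficacy rejection
#' occurs, and runs the requested testing procedures on the same data.
#'
#' @param design A [mams_design].
#' @param delta True effects (length `n_arms`, recycled).
#' @param seed Integer seed; a fixed seed reproduces the trial exactly.
#' @param methods Any of `"cumulative"`, `"stagewise_dunnett"`,
#'   `"stagewise_simes"`, `"stagewise_bonferroni"`,
#'   `"single_stage_dunnett"`.
#' @param t_adjust Use the Student-t boundary adjustment with estimated
#'   information (default `TRUE`).
#' @param known_variance Treat the design variances as known: true Fisher
#'   information, normal-scale boundaries.
#' @return A list with one element per method — `rejected` (per arm),
#'   `stop_stage`, `n_total` (enrollment at stopping), `max_residual`
#'   (largest conditional-error equation residual, cumulative method) —
#'   plus `obs` (the generated [mams_observations]) and `selected`.
#' @export
simulate_trial <- function(design, delta, seed,
                           methods = "cumulative", t_adjust = TRUE,
                           known_variance = FALSE) {
  prep <- sim_prep(design, methods, t_adjust, known_variance)
  delta <- rep_len(delta, design$n_arms)
  set.seed(seed)
  sim_one(design, delta, prep$bounds, methods, t_adjust,
          prep$known_sigma, prep$single_cv, prep$single_n)
}

sim_prep <- function(design, methods, t_adjust, known_variance) {
  known_sigma <- if (known_variance) design$sigma else NULL
  bounds <- if (length(setdiff(methods, "single_stage_dunnett")))
    mams_boundaries(design) else NULL
  single_cv <- single_n <- NULL
  if ("single_stage_dunnett" %in% methods) {
    single_n <- design$n_control[design$n_stages]
    k <- design$n_arms
    df <- if (known_variance || !t_adjust) Inf else (k + 1) * (single_n - 1)
    single_cv <- dunnett_crit(k, design$alpha, df = df)
  }
  list(bounds = bounds, known_sigma = known_sigma, single_cv = single_cv,
       single_n = single_n)
}

#' Monte Carlo operating characteristics
#'
#' Replicates [simulate_trial] and summarizes, per method: global power
#' (probability of rejecting at least one elementary hypothesis), FWER
#' (probability of rejecting at least one arm with `delta <= 0`), per-arm
#' rejection rates, per-stage stopping frequencies and average total
#' sample size, all with standard errors.
#'
#' @inheritParams simulate_trial
#' @param n_reps Number of simulated trials.
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @param verbose Report progress every 1000 replicates.
#' @return An object of class `mams_oc` (a data frame, one row per
#'   method) with attributes `per_arm` (rejection-rate matrix),
#'   `stop_freq` and `max_residual`.
#' @export
operating_characteristics <- function(design, delta, methods = "cumulative",
                                      n_reps = 1000, seed = 1,
                                      t_adjust = TRUE,
                                      known_variance = FALSE,
                                      verbose = FALSE) {
  stopifnot(inherits(design, "mams_design"), n_reps >= 1)
  delta <- rep_len(delta, design$n_arms)
  prep <- sim_prep(design, methods, t_adjust, known_variance)
  set.seed(seed)
  trial_seeds <- sample.int(2147483646L, n_reps)

  M <- length(methods)
  any_rej <- null_rej <- matrix(0, n_reps, M, dimnames = list(NULL, methods))
  ntot <- matrix(0, n_reps, M, dimnames = list(NULL, methods))
  arm_rej <- matrix(0, M, design$n_arms,
                    dimnames = list(methods, paste0("arm", 1:design$n_arms)))
  stopf <- matrix(0, M, design$n_stages,
                  dimnames = list(methods, paste0("stage", 1:design$n_stages)))
  maxres <- 0
  is_null <- delta <= 0
  for (r in seq_len(n_reps)) {
    set.seed(trial_seeds[r])
    res <- sim_one(design, delta, prep$bounds, methods, t_adjust,
                   prep$known_sigma, prep$single_cv, prep$single_n)
    if (verbose && r %% 1000 == 0)
      message(sprintf("  %d/%d replicates", r, n_reps))
    for (m in seq_len(M)) {
      rr <- res[[methods[m]]]
      any_rej[r, m] <- any(rr$rejected)
      null_rej[r, m] <- any(rr$rejected & is_null)
      ntot[r, m] <- rr$n_total
      arm_rej[m, ] <- arm_rej[m, ] + rr$rejected
      stopf[m, rr$stop_stage] <- stopf[m, rr$stop_stage] + 1
      maxres <- max(maxres, rr$max_residual)
    }
  }
  pw <- colMeans(any_rej)
  fw <- colMeans(null_rej)
  out <- data.frame(
    method = methods, n_reps = n_reps,
    power = pw, power_se = sqrt(pw * (1 - pw) / n_reps),
    fwer = if (any(is_null)) fw else NA_real_,
    fwer_se = if (any(is_null)) sqrt(fw * (1 - fw) / n_reps) else NA_real_,
    asn = colMeans(ntot),
    asn_se = apply(ntot, 2, sd) / sqrt(n_reps),
    row.names = NULL)
  attr(out, "per_arm") <- arm_rej / n_reps
  attr(out, "stop_freq") <- stopf / n_reps
  attr(out, "max_residual") <- maxres
  attr(out, "delta") <- delta
  class(out) <- c("mams_oc", "data.frame")
  out
}

#' @export
print.mams_oc <- function(x, ...) {
  if (!all(c("power", "power_se", "fwer", "fwer_se", "asn") %in% names(x)))
    return(invisible(print.data.frame(x)))
  cat(sprintf("Operating characteristics (%d simulated trials), delta = (%s)\n",
              x$n_reps[1], paste(attr(x, "delta"), collapse = ", ")))
  print.data.frame(cbind.data.frame(
    x[, c("method", "power", "power_se", "fwer", "fwer_se")],
    asn = round(x$asn, 1), asn_se = signif(x$asn_se, 3)),
    row.names = FALSE, digits = 4)
  cat("per-arm rejection rates:\n")
  print(signif(attr(x, "per_arm"), 4))
  cat("stopping-stage frequencies:\n")
  print(signif(attr(x, "stop_freq"), 4))
  invisible(x)
}
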