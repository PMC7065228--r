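# The adaptive cumulative MAMS closed test.
#
# Step 1: each intersection H0I is monitored by the maximum of the
# cumulative score statistics of its member arms against multiplicity-
# adjusted boundaries (mams_boundaries).  Step 2: after treatment selection
# and/or a change of the stage-2 sample sizes, the later boundaries are
# recomputed so that the conditional probability, given the stage-1 data
# and under H0I, of crossing with the adapted trial equals that of the
# original trial (the Mueller-Schaefer conditional error condition).  An
# elementary hypothesis is rejected only when every intersection containing
# it has been rejected.

#' Conditional error of a max-score final-stage test
#'
#' `P0(max_g (w1_g + W_g(2)) >= b2_g | w1)`: the conditional probability,
#' under the intersection null and given observed stage-1 scores `w1`, that
#' the cumulative score of at least one member arm crosses its stage-2
#' boundary, where the stage-2 increments `W_g(2)` are independent of
#' stage 1 with variances `info_increment`.
#'
#' @param w1 Observed stage-1 score statistics of the arms in the subset.
#' @param b2 Stage-2 score-scale boundary; scalar or per-arm.
#' @param info_increment Incremental information per arm (variance of the
#'   stage-2 score increments).
#' @param corr Cross-arm correlation of the increments (scalar or matrix).
#' @return Probability in `[0, 1]`.
#' @export
conditional_error <- function(w1, b2, info_increment, corr = 0.5) {
  k <- length(w1)
  stopifnot(all(info_increment > 0), length(info_increment) == k)
  b2 <- rep_len(b2, k)
  R <- if (is.matrix(corr)) corr else {
    m <- matrix(corr, k, k); diag(m) <- 1; m
  }
  1 - mvn_lower(b2 - w1, sd = sqrt(info_increment), corr = R)
}

#' Conditional-error-preserving boundary recomputation
#'
#' Solves for the Wald-scale stage-2 boundary `z*` of the adapted trial such
#' that `P0(max_g (w1_g + W*_g(2)) >= z* sqrt(info_cum_new_g) | w1)` equals
#' `target`, the conditional error of the original trial.
#'
#' @param w1 Stage-1 scores of the arms retained in the subset (`I_S`).
#' @param target Conditional error to preserve (from [conditional_error]).
#' @param info_increment_new Adapted incremental information per retained arm.
#' @param info_cum_new Adapted cumulative stage-2 information per retained arm.
#' @param corr Cross-arm correlation of the increments.
#' @return List with `z` (Wald scale), `b` (score scale, per arm) and
#'   `residual` (absolute error of the preserved conditional probability).
#' @export
recompute_boundary <- function(w1, target, info_increment_new, info_cum_new,
                               corr = 0.5) {
  k <- length(w1)
  stopifnot(k >= 1, target >= 0, target <= 1,
            all(info_increment_new > 0), all(info_cum_new > 0))
  R <- if (is.matrix(corr)) corr else {
    m <- matrix(corr, k, k); diag(m) <- 1; m
  }
  si <- sqrt(info_increment_new)
  sc <- sqrt(info_cum_new)
  if (k == 1L) {
    z <- (w1 + si * qnorm(1 - target)) / sc
  } else {
    f <- function(z) {
      (1 - mvn_lower(z * sc - w1, sd = si, corr = R)) - target
    }
    lo <- min((w1 + si * qnorm(1 - target)) / sc) - 2
    hi <- max((w1 + si * qnorm(1 - target)) / sc) + 2
    z <- uniroot(f, c(lo, hi), extendInt = "downX", tol = 1e-9)$root
  }
  res <- abs((1 - mvn_lower(z * sc - w1, sd = si, corr = R)) - target)
  list(z = z, b = z * sc, residual = res)
}

#' Cumulative MAMS closed test
#'
#' Runs the full adaptive cumulative MAMS procedure on observed summary
#' statistics: stage-1 intersection tests, conditional-error boundary
#' recomputation for the adapted continuation (treatment selection and/or
#' new stage sample sizes are read off the observed cumulative `n`), and
#' later-stage decisions.  Supports two- and three-stage designs with
#' adaptation at the end of stage 1.
#'
#' @param design A [mams_design] (`n_stages` 2 or 3).
#' @param obs A [mams_observations]; columns = observed stages.
#' @param selected Arms carried past stage 1.  Default: arms with positive
#'   incremental enrollment at stage 2 (inferred from `obs`).
#' @param t_adjust Apply the small-sample t-scale boundary adjustment
#'   ([t_adjust_boundary]) with estimated information (default `TRUE`).
#' @param known_sigma Optional vector of known response SDs (control
#'   first); when given, true Fisher information is used and no t
#'   adjustment is applied.
#' @param boundaries Optional precomputed [mams_boundaries].
#' @return An object of class `mams_test` with elements `rejected`
#'   (logical per arm), `rejected_stage`, `stop_stage`, `intersections`
#'   (per-subset record: boundaries, recomputed boundaries, rejection
#'   stage, conditional-error residual) and `max_residual`.
#' @export
cumulative_closed_test <- function(design, obs, selected = NULL,
                                   t_adjust = TRUE, known_sigma = NULL,
                                   boundaries = NULL) {
  stopifnot(inherits(design, "mams_design"),
            inherits(obs, "mams_observations"))
  if (!design$n_stages %in% c(2L, 3L) && ncol(obs$n) > 1L)
    stop("adaptive cumulative testing is implemented for 2 or 3 stages")
  if (ncol(obs$n) > design$n_stages)
    stop("observations have more stages than the design")
  if (is.null(boundaries)) boundaries <- mams_boundaries(design)
  if (is.null(selected)) selected <- infer_selected(design, obs)
  res <- cumulative_core(design, obs, selected, boundaries,
                         t_adjust = t_adjust, known_sigma = known_sigma,
                         record = TRUE)
  res$method <- "cumulative"
  class(res) <- "mams_test"
  res
}

infer_selected <- function(design, obs) {
  if (ncol(obs$n) < 2L) return(seq_len(design$n_arms))
  which((obs$n[-1, 2] - obs$n[-1, 1]) > 0)
}

#' @export
print.mams_test <- function(x, ...) {
  cat(sprintf("%s MAMS closed test: stopped at stage %d\n",
              x$method, x$stop_stage))
  D <- length(x$rejected)
  for (i in seq_len(D)) {
    cat(sprintf("  arm %d: %s%s\n", i,
                if (x$rejected[i]) "REJECTED" else "not rejected",
                if (x$rejected[i]) paste0(" (stage ", x$rejected_stage[i], ")")
                else ""))
  }
  if (!is.null(x$intersections)) {
    cat("intersection records:\n")
    print(x$intersections, row.names = FALSE, digits = 5)
  }
  invisible(x)
}

# core engine (also the simulator hot path) ------------------------------
# obs must contain every observed stage; decisions are taken sequentially
# and the procedure stops at the first stage with an elementary rejection.
cumulative_core <- function(design, obs, selected, boundaries,
                            t_adjust = TRUE, known_sigma = NULL,
                            record = FALSE) {
  D <- design$n_arms
  J <- design$n_stages
  J_obs <- ncol(obs$n)
  lam <- design$allocation
  subsets <- boundaries$subsets
  nsub <- length(subsets)
  member <- subset_membership(subsets, D)
  zb <- boundaries$z
  est_mode <- is.null(known_sigma)

  rejected_sub <- logical(nsub)
  rejected_sub_stage <- rep(NA_integer_, nsub)
  rejected <- logical(D)
  rejected_stage <- rep(NA_integer_, D)

  # stage-wise statistics on the estimated-information (t) scale
  stage_t <- function(j) {
    st <- cum_stats(obs, j)
    v <- if (est_mode) st$var else known_sigma^2
    info <- st$n[1] / (v[1] + v[-1] / lam)
    dhat <- st$mean[-1] - st$mean[1]
    list(t = dhat * sqrt(info), w = dhat * info, info = info,
         df = st$n[1] + st$n[-1] - 1, n = st$n, var = v)
  }

  test_stage <- function(j, zcrit_row, s_t) {
    # zcrit_row: per-subset Wald-scale critical value at stage j (Inf = not
    # testable); restricted arms per subset supplied via attr "arms"
    for (s in seq_len(nsub)) {
      if (rejected_sub[s] || !is.finite(zcrit_row[s])) next
      arms <- attr(zcrit_row, "arms")[[s]]
      if (length(arms) == 0) next
      crit <- if (t_adjust && est_mode)
        qt(pnorm(zcrit_row[s]), s_t$df[arms]) else zcrit_row[s]
      if (any(s_t$t[arms] >= crit)) {
        rejected_sub[s] <<- TRUE
        rejected_sub_stage[s] <<- j
      }
    }
    for (i in seq_len(D)) {
      if (!rejected[i] && all(rejected_sub[member[i, ]])) {
        rejected[i] <<- TRUE
        rejected_stage[i] <<- j
      }
    }
  }

  s1 <- stage_t(1L)
  z1 <- structure(zb[, 1], arms = subsets)
  test_stage(1L, z1, s1)
  out <- function(stop_stage, zstar = NULL, resid = NULL) {
    r <- list(rejected = rejected, rejected_stage = rejected_stage,
              stop_stage = stop_stage,
              max_residual = if (length(resid)) max(resid) else 0)
    if (record) {
      r$intersections <- data.frame(
        subset = vapply(subsets, subset_label, ""),
        k = lengths(subsets),
        rejected = rejected_sub,
        rejected_stage = rejected_sub_stage)
      if (!is.null(zstar)) {
        r$intersections <- cbind(r$intersections, zstar)
        r$residuals <- resid
      }
    }
    r
  }
  if (any(rejected) || J_obs == 1L) {
    return(out(if (any(rejected)) 1L else J_obs))
  }

  # ---- adaptation: conditional-error boundary recomputation ----
  # interim (stage-1) variance estimates drive the predicted information
  v1 <- s1$var
  Lamh <- 1 / (v1[1] + v1[-1] / lam)
  Rfull <- cross_arm_corr(v1[1], Lamh)
  n0_plan <- design$n_control
  n0_obs <- obs$n[1, ]
  later <- 2:J
  inc_plan <- diff(n0_plan)              # planned control increments
  inc_star <- diff(n0_obs)               # realized (adapted) increments
  if (J_obs < J)                         # later stages not yet observed
    inc_star <- c(inc_star, inc_plan[J_obs:(J - 1)])
  no_change <- isTRUE(all.equal(inc_plan, inc_star)) && J_obs == J
  n0_eff <- n0_obs[1] + cumsum(c(0, inc_star))   # control n under adaptation
  full_sel <- length(selected) == D
  adapted <- !(no_change && full_sel)

  zstar <- matrix(Inf, nsub, J - 1)      # Wald-scale recomputed boundaries
  arms_later <- vector("list", nsub)
  resid <- numeric(0)
  for (s in seq_len(nsub)) {
    I <- subsets[[s]]
    I_S <- intersect(I, selected)
    arms_later[[s]] <- I_S
    if (rejected_sub[s]) next
    if (!adapted || (length(I_S) == length(I) &&
                     isTRUE(all.equal(inc_plan, inc_star)))) {
      zstar[s, ] <- zb[s, later]
      next
    }
    if (length(I_S) == 0) next           # unrejectable after adaptation
    k <- length(I)
    R_I <- Rfull[I, I, drop = FALSE]
    R_S <- Rfull[I_S, I_S, drop = FALSE]
    w1I <- s1$w[I]
    if (J == 2L) {
      iinc <- inc_plan[1] * Lamh[I]
      A <- conditional_error(w1I, zb[s, 2] * sqrt(n0_plan[2] * Lamh[I]),
                             iinc, R_I)
      rb <- recompute_boundary(s1$w[I_S], A,
                               inc_star[1] * Lamh[I_S],
                               n0_eff[2] * Lamh[I_S], R_S)
      zstar[s, 1] <- rb$z
      resid <- c(resid, rb$residual)
    } else {
      # three stages, adaptation at stage 1: preserve the conditional
      # stage-2 and stage-3 exit probabilities separately
      b2 <- zb[s, 2] * sqrt(n0_plan[2] * Lamh[I])
      b3 <- zb[s, 3] * sqrt(n0_plan[3] * Lamh[I])
      cv <- seq_cov(Lamh[I], v1[1], inc_plan[1], inc_plan[2])
      u2 <- b2 - w1I
      u3 <- b3 - w1I
      Pnc2 <- mvn_lower(u2, sd = sqrt(diag(cv$C22)), corr = cov2corr(cv$C22))
      Pnc23 <- mvn_lower(c(u2, u3), sd = sqrt(diag(cv$Cfull)),
                         corr = cov2corr(cv$Cfull), abseps = 1e-5)
      A2 <- 1 - Pnc2
      A3 <- Pnc2 - Pnc23
      rb2 <- recompute_boundary(s1$w[I_S], A2,
                                inc_star[1] * Lamh[I_S],
                                n0_eff[2] * Lamh[I_S], R_S)
      zstar[s, 1] <- rb2$z
      resid <- c(resid, rb2$residual)
      cvs <- seq_cov(Lamh[I_S], v1[1], inc_star[1], inc_star[2])
      sds <- sqrt(diag(cvs$Cfull))
      Rs <- cov2corr(cvs$Cfull)
      u2s <- rb2$z * sqrt(n0_eff[2] * Lamh[I_S]) - s1$w[I_S]
      Pnc2s <- mvn_lower(u2s, sd = sqrt(diag(cvs$C22)),
                         corr = cov2corr(cvs$C22))
      sc3 <- sqrt(n0_eff[3] * Lamh[I_S])
      f3 <- function(z) {
        (Pnc2s - mvn_lower(c(u2s, z * sc3 - s1$w[I_S]), sd = sds,
                           corr = Rs, abseps = 1e-5)) - A3
      }
      iinc23 <- (inc_star[1] + inc_star[2]) * Lamh[I_S]
      guess <- (s1$w[I_S] + sqrt(iinc23) * qnorm(1 - min(A3, 1 - 1e-12))) / sc3
      z3 <- uniroot(f3, c(min(guess) - 3, max(guess) + 3),
                    extendInt = "downX", tol = 1e-7)$root
      zstar[s, 2] <- z3
      resid <- c(resid, abs(f3(z3)))
    }
  }

  # ---- later-stage decisions ----
  for (j in later[later <= J_obs]) {
    sj <- stage_t(j)
    zrow <- structure(zstar[, j - 1], arms = arms_later)
    test_stage(j, zrow, sj)
    if (any(rejected)) {
      zs <- as.data.frame(zstar)
      names(zs) <- paste0("zstar", later)
      return(out(j, zstar = zs, resid = resid))
    }
  }
  zs <- as.data.frame(zstar)
  names(zs) <- paste0("zstar", later)
  out(J_obs, zstar = zs, resid = resid)
}

# joint covariance, given stage-1 data, of the later incremental score
# partial sums (W_g(2)) and (W_g(2) + W_g(3)) for the listed arms
seq_cov <- function(Lam, s0sq, n_inc2, n_inc3) {
  k <- length(Lam)
  off <- Lam %o% Lam * s0sq
  C22 <- off * n_inc2
  diag(C22) <- Lam * n_inc2
  Css <- off * (n_inc2 + n_inc3)
  diag(Css) <- Lam * (n_inc2 + n_inc3)
  Cfull <- rbind(cbind(C22, C22), cbind(C22, Css))
  list(C22 = C22, Cfull = Cfull)
}
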