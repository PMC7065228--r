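# Per-arm cumulative sufficient statistics at each analysis, plus the
# incremental (between-stage) statistics derived from them.  All closed
# tests consume this container; the simulator fills it from patient-level
# sums and users can build it from a long summary table (arm, stage, n,
# mean, sd) as written by standard interim analysis reports.

#' Stage-wise summary observations
#'
#' @param n,mean,sd Matrices of cumulative per-arm sample sizes, means and
#'   standard deviations, with `n_arms + 1` rows (control first) and one
#'   column per observed stage.
#' @return An object of class `mams_observations` holding cumulative and
#'   incremental sufficient statistics.
#' @export
mams_observations <- function(n, mean, sd) {
  n <- as.matrix(n); mean <- as.matrix(mean); sd <- as.matrix(sd)
  if (!all(dim(n) == dim(mean)) || !all(dim(n) == dim(sd)))
    stop("`n`, `mean`, `sd` must have identical dimensions")
  J <- ncol(n)
  if (J > 1 && any(apply(n, 1, diff) < 0))
    stop("cumulative sample sizes may not decrease")
  # cumulative sums and sums of squares are the sufficient statistics
  sum_x <- n * mean
  sum_x2 <- (pmax(n - 1, 0)) * sd^2 + n * mean^2
  obs <- list(n = n, sum_x = sum_x, sum_x2 = sum_x2)
  class(obs) <- "mams_observations"
  obs
}

# build from accumulated sums directly (simulator path)
obs_from_sums <- function(n, sum_x, sum_x2) {
  structure(list(n = n, sum_x = sum_x, sum_x2 = sum_x2),
            class = "mams_observations")
}

#' Build observations from a long summary table
#'
#' @param df A data frame with columns `arm` (0 = control), `stage`, `n`,
#'   `mean`, `sd`; `n`, `mean`, `sd` cumulative at each stage.
#' @return A `mams_observations` object.
#' @export
as_observations <- function(df) {
  need <- c("arm", "stage", "n", "mean", "sd")
  if (!all(need %in% names(df)))
    stop("summary table needs columns: ", paste(need, collapse = ", "))
  arms <- sort(unique(df$arm))
  stages <- sort(unique(df$stage))
  if (!identical(as.integer(arms), seq(0L, length(arms) - 1L)))
    stop("arms must be 0 (control), 1, ..., D")
  shape <- function(col) {
    m <- matrix(NA_real_, length(arms), length(stages))
    m[cbind(df$arm + 1L, df$stage)] <- df[[col]]
    if (anyNA(m)) stop("summary table must cover every arm at every stage")
    m
  }
  mams_observations(shape("n"), shape("mean"), shape("sd"))
}

# cumulative statistics at one stage ------------------------------------
cum_stats <- function(obs, stage) {
  n <- obs$n[, stage]
  m <- obs$sum_x[, stage] / n
  ss <- obs$sum_x2[, stage] - n * m^2
  v <- ifelse(n > 1, ss / (n - 1), NA_real_)
  list(n = n, mean = m, var = v)
}

# incremental statistics for the data accrued between stage-1 and stage
inc_stats <- function(obs, stage) {
  if (stage == 1L) return(cum_stats(obs, 1L))
  n <- obs$n[, stage] - obs$n[, stage - 1L]
  sx <- obs$sum_x[, stage] - obs$sum_x[, stage - 1L]
  sx2 <- obs$sum_x2[, stage] - obs$sum_x2[, stage - 1L]
  m <- ifelse(n > 0, sx / n, NA_real_)
  ss <- sx2 - ifelse(n > 0, n * m^2, 0)
  v <- ifelse(n > 1, ss / (n - 1), NA_real_)
  list(n = n, mean = m, var = v)
}

# Estimated Fisher information about delta_i from per-arm statistics:
# Ihat_i = n_0 / (s0hat^2 + sihat^2 / lambda_i).  `st` is a list as
# returned by cum_stats()/inc_stats(); with `sigma` supplied the true
# variances are used instead (known-variance mode).
est_information <- function(st, allocation, sigma = NULL) {
  v <- if (is.null(sigma)) st$var else sigma^2
  st$n[1] / (v[1] + v[-1] / allocation)
}

#' @export
print.mams_observations <- function(x, ...) {
  J <- ncol(x$n)
  cat("MAMS observations:", nrow(x$n) - 1L, "treatment arm(s) + control,",
      J, "stage(s)\n")
  for (j in seq_len(J)) {
    st <- cum_stats(x, j)
    cat(sprintf("  stage %d (cumulative): n = %s; mean = %s\n", j,
                paste(st$n, collapse = "/"),
                paste(signif(st$mean, 4), collapse = "/")))
  }
  invisible(x)
}
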