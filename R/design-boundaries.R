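# Per-subset group-sequential boundaries for a design's closed test.
# Subsets with the same size and cross-arm correlation block share a
# boundary, so with equal allocation and equal variances only D distinct
# solves are needed.

#' Closed-test boundaries for every intersection hypothesis
#'
#' Computes the Wald-scale group-sequential boundaries used by the
#' cumulative MAMS closed test for each nonempty subset of the treatment
#' arms (size-`k` subsets are adjusted for `k` comparisons), and the
#' two-arm boundaries (the singleton rows) used by the stage-wise
#' procedure.
#'
#' @param design A [mams_design].
#' @return An object of class `mams_boundaries`: list with `subsets` (list
#'   of arm-index vectors), `z` (matrix, one row per subset, one column per
#'   stage, Wald scale), `alpha_spent`, and `design`.
#' @export
mams_boundaries <- function(design) {
  stopifnot(inherits(design, "mams_design"))
  ckey <- if (is.character(design$spending)) {
    paste(design$n_arms, design$spending, design$alpha,
          paste(design$info_fractions, collapse = ","),
          paste(signif(design$sigma, 12), collapse = ","),
          paste(design$allocation, collapse = ","), sep = "|")
  } else NA_character_
  if (!is.na(ckey) && !is.null(.bounds_cache[[ckey]]))
    return(.bounds_cache[[ckey]])
  D <- design$n_arms
  subsets <- all_subsets(D)
  Lam <- lambda_coef(design)
  R_full <- cross_arm_corr(design$sigma[1]^2, Lam)
  z <- matrix(NA_real_, length(subsets), design$n_stages)
  cache <- list()
  bk <- NULL
  for (s in seq_along(subsets)) {
    I <- subsets[[s]]
    R <- R_full[I, I, drop = FALSE]
    key <- paste(signif(R[upper.tri(R, diag = FALSE)], 10), collapse = "|")
    key <- paste(length(I), key, sep = ":")
    if (is.null(cache[[key]])) {
      bk <- max_stat_boundaries(length(I), design$info_fractions,
                                design$alpha, rho = R,
                                spending = design$spending)
      cache[[key]] <- bk$z
    }
    z[s, ] <- cache[[key]]
  }
  out <- structure(list(subsets = subsets, z = z,
                        alpha_spent = bk$alpha_spent, design = design),
                   class = "mams_boundaries")
  if (!is.na(ckey)) .bounds_cache[[ckey]] <- out
  out
}

# session-scoped memoization of the (expensive, purely design-determined)
# boundary solves
.bounds_cache <- new.env(parent = emptyenv())

#' @export
print.mams_boundaries <- function(x, ...) {
  cat("Closed-test Wald-scale boundaries per intersection subset\n")
  df <- data.frame(subset = vapply(x$subsets, subset_label, ""),
                   k = lengths(x$subsets))
  df <- cbind(df, setNames(as.data.frame(signif(x$z, 6)),
                           paste0("stage", seq_len(ncol(x$z)))))
  print(df, row.names = FALSE)
  invisible(x)
}
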