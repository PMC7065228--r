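#' Specify a multi-arm multi-stage design
#'
#' Declarative description of a MAMS trial in which `n_arms` treatments are
#' each compared with a common control over `n_stages` analyses.  Patients on
#' arm `i` respond N(mu_i, sigma_i^2); the null hypothesis for arm `i` is
#' that its mean effect over control, delta_i = mu_i - mu_0, is zero, tested
#' against the one-sided alternative delta_i > 0.
#'
#' @param n_arms Number of treatment arms `D` (control excluded).
#' @param n_stages Number of analyses `J`.
#' @param n_control Cumulative control-arm sample size at each stage;
#'   strictly increasing, length `J`.  Per-arm sizes are
#'   `round(allocation_i * n_control)` (half away from zero).
#' @param alpha One-sided family-wise type-1 error, in (0, 0.5).
#' @param sigma Response standard deviation(s): a scalar, or a vector of
#'   length `n_arms + 1` ordered control first.
#' @param allocation Treatment:control randomization ratio(s) `lambda_i`:
#'   scalar or length `n_arms`.
#' @param spending Error-spending function: `"ldobf"` (Lan-DeMets
#'   O'Brien-Fleming type, the default) or a `function(t, alpha)` returning
#'   cumulative error spent at information fraction `t`.
#' @param selection_threshold Treatment-selection rule: arm `i` is dropped at
#'   the end of stage 1 if its observed effect estimate is below this value
#'   (response units).  `-Inf` disables selection.
#' @param reallocation `"proportional_upscaling"` (dropped arms' unspent
#'   enrollment is redistributed over continuing arms, control included,
#'   proportionally to the original allocation ratios, preserving total
#'   sample size) or `"none"` (unspent enrollment is simply not enrolled).
#' @param weights Inverse-normal combination weights `h_j` for the
#'   stage-wise procedure, with `sum(h^2) = 1`.  Default: square root of the
#'   planned incremental information share per stage (`1/sqrt(J)` for
#'   equally spaced stages).
#'
#' @return An object of class `mams_design`.
#' @examples
#' # the 388-patient three-dose design: 97/arm, interim at half
#' d <- mams_design(n_arms = 3, n_stages = 2, n_control = c(49, 97),
#'                  sigma = 0.52, selection_threshold = 0)
#' d
#' @export
mams_design <- function(n_arms, n_stages, n_control, alpha = 0.025,
                        sigma = 1, allocation = 1,
                        spending = "ldobf",
                        selection_threshold = -Inf,
                        reallocation = c("proportional_upscaling", "none"),
                        weights = NULL) {
  D <- as.integer(n_arms)
  J <- as.integer(n_stages)
  stopifnot(D >= 1L, J >= 1L)
  n_control <- as.numeric(n_control)
  if (length(n_control) != J)
    stop("`n_control` must have one entry per stage")
  if (J > 1L && any(diff(n_control) <= 0))
    stop("`n_control` must be strictly increasing across stages")
  if (any(n_control < 2))
    stop("`n_control` must be at least 2 per stage")
  if (!(alpha > 0 && alpha < 0.5))
    stop("`alpha` must lie in (0, 0.5)")
  sigma <- rep_len(as.numeric(sigma), D + 1L)
  if (any(sigma <= 0)) stop("all `sigma` must be positive")
  allocation <- rep_len(as.numeric(allocation), D)
  if (any(allocation <= 0)) stop("all allocation ratios must be positive")
  reallocation <- match.arg(reallocation)
  if (is.character(spending)) {
    spending <- match.arg(spending, "ldobf")
  } else if (!is.function(spending)) {
    stop("`spending` must be \"ldobf\" or a function(t, alpha)")
  }
  info_frac <- n_control / n_control[J]
  if (is.null(weights)) {
    weights <- sqrt(diff(c(0, info_frac)))
  }
  weights <- as.numeric(weights)
  if (length(weights) != J || any(weights <= 0))
    stop("`weights` must be positive, one per stage")
  if (abs(sum(weights^2) - 1) > 1e-6)
    stop("`weights` must satisfy sum(h_j^2) = 1")
  weights <- weights / sqrt(sum(weights^2))   # absorb serialization rounding

  d <- structure(list(
    n_arms = D, n_stages = J, n_control = n_control,
    alpha = alpha, sigma = sigma, allocation = allocation,
    spending = spending, selection_threshold = selection_threshold,
    reallocation = reallocation, weights = weights,
    info_fractions = info_frac), class = "mams_design")
  d
}

# round half away from zero (2.5 -> 3), used for lambda_i * n_0j
round_half_up <- function(x) floor(x + 0.5)

#' Planned cumulative sample sizes
#'
#' @param design A [mams_design].
#' @return Matrix `(n_arms + 1) x n_stages` of cumulative per-arm sample
#'   sizes; row 1 is the control arm.
#' @export
planned_n <- function(design) {
  out <- rbind(design$n_control,
               round_half_up(outer(design$allocation, design$n_control)))
  rownames(out) <- c("control", paste0("arm", seq_len(design$n_arms)))
  colnames(out) <- paste0("stage", seq_len(design$n_stages))
  out
}

#' @export
print.mams_design <- function(x, ...) {
  cat("Multi-arm multi-stage design\n")
  cat(sprintf("  %d treatment arm(s) vs control, %d stage(s), one-sided alpha = %g\n",
              x$n_arms, x$n_stages, x$alpha))
  cat(sprintf("  cumulative control n per stage: %s\n",
              paste(x$n_control, collapse = ", ")))
  cat(sprintf("  sigma (control first): %s;  allocation: %s\n",
              paste(signif(x$sigma, 4), collapse = ", "),
              paste(x$allocation, collapse = ", ")))
  cat(sprintf("  spending: %s;  selection threshold: %s;  reallocation: %s\n",
              if (is.function(x$spending)) "<function>" else x$spending,
              format(x$selection_threshold), x$reallocation))
  cat(sprintf("  inverse-normal weights: %s\n",
              paste(signif(x$weights, 4), collapse = ", ")))
  invisible(x)
}

#' Read or write a design configuration file
#'
#' Designs serialize to a flat YAML (or JSON, which YAML parses) mapping
#' whose keys mirror the [mams_design] arguments: `n_arms`, `n_stages`,
#' `n_control`, `alpha`, `sigma`, `allocation`, `spending`,
#' `selection_threshold`, `reallocation`, `weights`.  Unknown keys are
#' rejected.
#'
#' @param path File path.
#' @param design A [mams_design].
#' @return `read_design` returns a [mams_design]; `write_design` returns
#'   `path` invisibly.
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("n_arms", "n_stages", "n_control", "alpha", "sigma",
               "allocation", "spending", "selection_threshold",
               "reallocation", "weights")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown design config key(s): ", paste(unknown, collapse = ", "))
  required <- c("n_arms", "n_stages", "n_control")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("design config is missing key(s): ", paste(missing, collapse = ", "))
  if (!is.null(cfg$selection_threshold))
    cfg$selection_threshold <- as.numeric(cfg$selection_threshold)
  do.call(mams_design, cfg)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "mams_design"))
  x <- design[c("n_arms", "n_stages", "n_control", "alpha", "sigma",
                "allocation", "selection_threshold", "reallocation",
                "weights")]
  x$spending <- if (is.function(design$spending)) "ldobf" else design$spending
  if (!is.finite(x$selection_threshold))
    x$selection_threshold <- as.character(x$selection_threshold)
  yaml::write_yaml(x, path)
  invisible(path)
}
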