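---
title: "Adaptive multi-arm multi-stage designs: models, boundaries and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive multi-arm multi-stage designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamsadapt)
```

## The testing problem

A multi-arm multi-stage (MAMS) trial compares $D$ treatments with one
shared control over $J$ analyses.  Responses on arm $i$ are
$N(\mu_i, \sigma_i^2)$; the elementary null hypotheses are
$H_{0i}: \delta_i = \mu_i - \mu_0 \le 0$, tested one-sided at family-wise
level $\alpha$.  At the first interim the design may drop poorly
performing arms and re-estimate the remaining sample sizes; the testing
machinery must keep strong control of the family-wise error rate (FWER)
under any such data-dependent change.

Everything is built on the score statistics
$W_{ij} = \hat\delta_{ij}\,\mathcal I_{ij}$ with Fisher information
$\mathcal I_{ij} = n_{0j}\,(\sigma_0^2 + \sigma_i^2/\lambda_i)^{-1}$,
where $n_{0j}$ is the cumulative control-arm size at stage $j$ and
$\lambda_i$ the allocation ratio.  Jointly the $W_{ij}$ form a
multivariate Brownian process: $\mathrm{var}(W_{ij}) = \mathcal I_{ij}$,
within-arm covariance $\mathcal I_{i,\min(j,j')}$ across stages, and
cross-arm covariance $\Lambda_g\Lambda_h\sigma_0^2 n_{0j}$ at a common
stage with $\Lambda_i = (\sigma_0^2+\sigma_i^2/\lambda_i)^{-1}$ — a
one-factor structure induced by the shared control arm, giving
correlation $1/2$ under equal allocation and equal variances.
`score_covariance()` exposes this law; a property test checks it against
the empirical covariance of $10^5$ patient-level replicates.

## Two procedures

**Cumulative procedure.**  Each nonempty subset $I$ of arms is monitored
through $\max_{g\in I} W_{gj}$ against group-sequential boundaries
$b_{I1},\dots,b_{IJ}$ that solve the stage-wise exit equations
$P_0(\text{no earlier crossing},\ \max W_{Ij} \ge b_{Ij}) = \alpha_j$,
with $\alpha_j$ the increment of an error-spending function (the
Lan–DeMets O'Brien–Fleming-type shape
$f(t) = 2-2\Phi(\Phi^{-1}(1-\alpha/2)/\sqrt t)$ by default).  An
elementary hypothesis is rejected only when every subset containing it
has crossed (closed testing).  After the interim adaptation — selection
$S$ and a new control increment $n^*_{0(2)}$ with allocation ratios
preserved — each later boundary is recomputed so that the conditional
crossing probability given the stage-1 data is unchanged under the
intersection null:
$$P_0\bigl(\max W^*_{I_S 2} \ge b^*_{I2}\,\big|\,w_{I1}\bigr)
  = P_0\bigl(\max W_{I2} \ge b_{I2}\,\big|\,w_{I1}\bigr),$$
with $I_S = I \cap S$.  This is the conditional-error principle: the
adapted test spends, conditionally on what has been seen, no more than
the original would have.  Dropped arms keep their stage-1 data inside
$w_{I1}$ (and inside the conditioning) but leave the later maxima.  Two
consequences are checked as invariants: the recomputed boundary never
exceeds the planned one when arms are dropped without a sample-size
change, and with no adaptation at all the closed test is consonant — its
global decision coincides with monitoring $\max_i W_{ij}$ against the
$k = D$ boundaries.

**Stage-wise procedure.**  For each subset $I$ and stage $j$ a
multiplicity-adjusted p-value $p_I(j)$ is computed from the *incremental*
data of that stage — exactly (Dunnett) via the central multivariate $t$
distribution of the incremental statistics
$t_i(j) = \hat\delta_{i(j)}\sqrt{\hat{\mathcal I}_{i(j)}}$ with
$n_{0(j)} + \sum_{i\in I} n_{i(j)} - \lVert I\rVert - 1$ degrees of
freedom and allocation-determined correlation, or nonparametrically
(Bonferroni, Simes) from marginal pooled-variance one-sided $t$ tests.
Stages are combined by the inverse-normal rule
$Z_{Ij} = \sum_{k\le j} h_k\Phi^{-1}(1-p_I(k))\big/\sqrt{\sum_{k\le j}h_k^2}$
with prespecified weights, and monitored against the *two-arm* ($k=1$)
group-sequential boundaries: the across-arm multiplicity lives entirely
in the adjusted p-values, the across-stage multiplicity in the
boundaries.  Stage-1 components always use the full subset $I$; later
components restrict to $I_S$, and an empty $I_S$ contributes $p = 1$
(conservative, and irrelevant for selected arms, every subset containing
which intersects $S$).

## Numerical choices

* Orthant probabilities: TVPACK (deterministic, $\sim 10^{-14}$) up to
  dimension 3; above that the Genz–Bretz quasi-Monte-Carlo algorithm with
  an internally fixed seed (results reproducible bit-for-bit), absolute
  tolerance $10^{-6}$ for boundary solves and $10^{-5}$ inside the
  per-trial conditional-error recomputation, where the probability-scale
  error is two orders of magnitude below Monte-Carlo noise.
* Boundary roots: Brent's method on the Wald scale, bracket $[0, 12]$,
  tolerance $10^{-6}$; conditional-error roots to $10^{-9}$ (two-stage,
  closed form when a single arm remains) and $10^{-7}$ (third stage).
  Every recomputed boundary stores the achieved residual of the
  conditional-error equation; the suite requires the maximum over all
  simulated adapted trials to stay below $10^{-6}$.
* p-values are clipped to $[10^{-15}, 1-10^{-15}]$ before
  $\Phi^{-1}$.
* The analytic two-dose power integrals nest an exact bivariate-normal
  rectangle probability of the stage-2 increments inside a tensor-product
  Gauss–Hermite rule (96 nodes per dimension, transformed through the
  Cholesky factor of the stage-1 covariance).  The inverse of the null
  CDF of the stage-2 maximum is a monotone (Hyman) spline through exact
  values on a 0.01 grid over $[-8, 8]$, inverted analytically at the
  clipped tails.  Agreement with $10^6$-replicate simulation is within
  $3$ standard errors at all nine grid points tested; absolute accuracy
  is well inside $5\times10^{-4}$.

## Decisions where the construction was open

* **Degrees of freedom.**  The small-sample boundary transformation
  $b^*_{ij} = \hat{\mathcal I}_{ij}^{1/2}\,
  T^{-1}_{d_{ij}}\!\bigl(\Phi(b_j/\hat{\mathcal I}_{ij}^{1/2})\bigr)$ uses
  $d_{ij} = n_{0j}+n_{ij}-1$, and the stage-wise Dunnett p-value uses
  $n_{0(j)}+\sum n_{i(j)}-\lVert I\rVert-1$.  Both conventions are taken
  as stated in the literature this implements; a $-2$ variant changes the
  simulated error rates by far less than Monte-Carlo noise at these
  sample sizes.
* **More than two stages.**  With $J>2$ the inverse-normal weights
  default to the square root of the planned incremental information
  share ($1/\sqrt J$ for equally spaced looks) and interim monitoring
  uses the renormalized partial sums — the canonical
  independent-increments construction, under which the combination
  statistic has exactly the two-arm group-sequential null law.  For the
  cumulative procedure with adaptation at the first interim, the
  conditional *stage-wise* exit probabilities (stage 2 and stage 3
  separately, given the stage-1 data) are each preserved; this pins down
  both recomputed boundaries and reduces to the two-stage condition when
  $J=2$.  Adaptation at later interims is not supported and is refused
  explicitly.
* **Empty selection.**  If every treatment arm is dropped the trial stops
  at the interim with no further enrollment and no later rejection.
  The average-sample-size behaviour of the simulated designs (including
  the exact $1/4$ probability, under the global null with three
  exchangeable corr-$1/2$ estimates, that all three are negative)
  depends on this choice, and the alternative — continuing a
  control-only cohort — is both clinically implausible and incapable of
  rejecting anything.
* **Single-stage design size.**  The Dunnett sample-size search uses the
  known-variance (multivariate normal) power by default, consistent with
  the score-statistic framework; for the three-dose benchmark
  ($\delta = 0.187$, $\sigma = 0.52$, 80% global power at one-sided
  0.025) it gives 97 per arm.  The multivariate-$t$ variant is available
  (`use_t = TRUE`) and gives 98 at the same target.
* **Rounding.**  Per-arm sizes are
  $\mathrm{round}(\lambda_i n_{0j})$ (half away from zero); reallocated
  increments use largest-remainder rounding so stage totals are
  preserved exactly.

## What the simulator emulates — and what it does not

`simulate_trial()` generates patient-level normal responses stage by
stage, applies the threshold selection rule
($\hat\delta_{i1} < \tau$ drops arm $i$; $\tau$ in response units,
applied only at the first interim), redistributes dropped arms' unspent
enrollment (proportional upscaling, or not at all), stops everything at
the first efficacy rejection, and runs all requested procedures on the
same data so that method comparisons are paired.  The default analysis
mode estimates per-arm variances cumulatively, plugs them into the
estimated information, and compares Student-$t$-scale statistics with
$t$-transformed boundaries; the known-variance mode shows the procedure
exhausting $\alpha$ exactly.  Per-replicate seeds are drawn up front, so
results are independent of execution order.

Passing tests therefore demonstrate the operating characteristics of
*normal responses with common (or prespecified) variances, immediate
response availability, and one adaptation at the first interim*.  They
say nothing about delayed or non-normal endpoints, time trends,
overrunning patients between look and decision, or estimation after
stopping — point estimates and confidence intervals following adaptation
are out of scope.  Binding futility rules and the addition of new arms
mid-trial are likewise not modelled.

Replicate counts used by the checked examples: $2{,}000$ trials for the
two-stage operating characteristics (standard errors about 0.011, with
tolerances widened accordingly), 600–1{,}200 for the three-stage and
multi-method FWER checks, and $10^4$ (two-stage) / $3\times10^3$
(three-stage) in `scripts/acceptance.R`.  These sizes put the Monte-Carlo
error well inside the comparison tolerances while keeping a full run in
the minutes range on one core.

## Known limitations

* Boundary recomputation after adaptation is implemented for designs
  with two or three stages (adaptation at the first interim only) —
  the configurations of practical interest for seamless phase 2–3
  trials; the boundary and spending machinery itself handles any $J$.
* The exact Dunnett adjustment leans on the allocation-determined
  correlation and hence on approximate normality; for heavily skewed
  endpoints the nonparametric Bonferroni/Simes flavors of the stage-wise
  procedure are the robust fallback, at a substantial power cost that
  the simulator quantifies.
* With unequal allocation the integer rounding of $\lambda_i n_{0j}$
  makes realized allocation ratios only approximately constant across
  stages; the information computations always use the realized sizes.
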