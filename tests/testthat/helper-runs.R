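# Memoized simulation runs shared across test files, so repeated checks of
# the same trial configuration reuse one Monte-Carlo experiment.
.run_cache <- new.env(parent = emptyenv())

socrates_oc <- function(delta, methods, n_reps, seed, tau = 0,
                        reallocation = "proportional_upscaling",
                        n_stages = 2, known_variance = FALSE) {
  key <- paste(paste(delta, collapse = ","), paste(methods, collapse = ","),
               n_reps, seed, tau, reallocation, n_stages, known_variance,
               sep = "|")
  if (is.null(.run_cache[[key]])) {
    d <- socrates_design(n_stages = n_stages, selection_threshold = tau,
                         reallocation = reallocation)
    .run_cache[[key]] <- operating_characteristics(
      d, delta = delta, methods = methods, n_reps = n_reps, seed = seed,
      known_variance = known_variance)
  }
  .run_cache[[key]]
}
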