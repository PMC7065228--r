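# Closed-testing bookkeeping: enumeration of the nonempty subsets of the
# treatment-arm set, and the arm-membership matrix used to read elementary
# decisions off the intersection decisions.

all_subsets <- function(D) {
  out <- vector("list", 2^D - 1)
  for (m in seq_len(2^D - 1)) {
    out[[m]] <- which(bitwAnd(m, bitwShiftL(1L, 0:(D - 1))) > 0L)
  }
  out
}

# member[i, s] = TRUE if arm i belongs to subset s
subset_membership <- function(subsets, D) {
  member <- matrix(FALSE, D, length(subsets))
  for (s in seq_along(subsets)) member[subsets[[s]], s] <- TRUE
  member
}

subset_label <- function(I) paste0("{", paste(I, collapse = ","), "}")

clip_p <- function(p) pmin(pmax(p, 1e-15), 1 - 1e-15)
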