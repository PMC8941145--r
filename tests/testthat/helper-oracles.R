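# Independent oracles used across tests. These deliberately avoid the
# package's aggregated-convolution code path.

# Exhaustive per-atom enumeration of the isotopologue distribution: every
# atom of the composition independently takes one of its isotopes; the
# distribution of total neutron shift is accumulated over all per-atom
# assignment tuples. Feasible for small compositions only.
oracle_isotopologue <- function(counts, ria = NULL) {
  iso <- list(
    C = list(shift = c(0L, 1L), prob = c(0.9893, 0.0107)),
    H = list(shift = c(0L, 1L), prob = c(0.999885, 0.000115)),
    N = list(shift = c(0L, 1L), prob = c(0.99636, 0.00364)),
    O = list(shift = c(0L, 1L, 2L), prob = c(0.99757, 0.00038, 0.00205)),
    S = list(shift = c(0L, 1L, 2L, 4L), prob = c(0.9499, 0.0075, 0.0425, 0.0001))
  )
  if (!is.null(ria)) iso$C$prob <- c(1 - ria, ria)

  shifts <- 0L
  probs <- 1
  for (el in names(counts)) {
    n <- counts[[el]]
    if (is.na(n) || n == 0) next
    for (atom in seq_len(n)) {
      k <- length(iso[[el]]$shift)
      shifts <- rep(shifts, each = k) + rep(iso[[el]]$shift, times = length(shifts))
      probs <- rep(probs, each = k) * rep(iso[[el]]$prob, times = length(probs))
    }
  }
  agg <- tapply(probs, shifts, sum)
  out <- numeric(max(as.integer(names(agg))) + 1L)
  out[as.integer(names(agg)) + 1L] <- agg
  out
}

# Random small composition whose enumeration stays tractable
random_small_composition <- function() {
  repeat {
    counts <- c(C = sample(1:5, 1), H = sample(0:5, 1), N = sample(0:2, 1),
                O = sample(0:2, 1), S = sample(0:1, 1))
    atoms <- sum(counts)
    tuples <- prod(c(2, 2, 2, 3, 4)^counts)
    if (atoms <= 15 && tuples <= 3e5) return(counts)
  }
}

as_composition <- function(counts) {
  structure(as.integer(counts[c("C", "H", "N", "O", "S")]),
            names = c("C", "H", "N", "O", "S"),
            class = "elemental_composition")
}
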