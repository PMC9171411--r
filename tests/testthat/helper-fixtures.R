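# Small shared fixtures. Everything is generated in-memory from seeds so the
# suite has no file dependencies beyond temporary files it writes itself.

tiny_truth <- function(seed = 1L) {
  simulate_interactome(n_baits = 6L, n_subfamilies = 3L, n_preys = 300L,
                       edges_per_bait = 10L, seed = seed)
}

tiny_counts <- function(truth = tiny_truth(), seed = 1L, ...) {
  simulate_counts(truth, n_controls = 3L, seed = seed, ...)
}

# A minimal valid count table built by hand: one bait, one control, 2 reps.
hand_counts <- function() {
  tibble::tibble(
    bait = c("RTK001", "RTK001", "RTK001", "RTK001",
             control_tag(), control_tag()),
    method = "APMS",
    condition = "WT",
    replicate = c(1L, 2L, 1L, 2L, 1L, 2L),
    prey = c("P1", "P1", "P2", "P2", "P2", "P2"),
    spectral_count = c(20, 30, 2, 0, 8, 12)
  )
}

# Exact right-tail hypergeometric probability via log-binomials.
hyper_tail_oracle <- function(k, K, N, n) {
  hi <- min(n, K)
  if (k > hi) return(0)
  j <- seq(k, hi)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}
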