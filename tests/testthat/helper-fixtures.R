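# Shared fixtures: default parameter sets, frames and frequencies, built
# once per test run.

gc_params <- dna_params("GC")
at_params <- dna_params("AT")
gc_frame <- helix_frame(gc_params)
at_frame <- helix_frame(at_params)
gc_cf <- characteristic_frequencies(gc_params, gc_frame)
at_cf <- characteristic_frequencies(at_params, at_frame)

# dense periodic ring Hamiltonian of the effective 1D chain at energy E
effective_ring_matrix <- function(n, E, q, params, gamma) {
  ch <- build_effective_chain(n, E, q, params, gamma = gamma, periodic = TRUE)
  H <- diag(ch$diagonal)
  for (i in seq_len(n - 1)) H[i, i + 1] <- H[i + 1, i] <- ch$offdiagonal[i]
  H[1, n] <- H[n, 1] <- ch$offdiagonal[n]
  H
}

# commensurate wavevector for mode index k on a ring of n sites
ring_q <- function(k, n, frame) 2 * pi * k / (n * frame$xi)
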