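# Shared fixture builders for the test suite.  Everything is generated in
# code under fixed seeds; nothing is read from disk unless a test writes
# it first.

# Small, fast parameter set for unit tests that do not probe the default
# study conditions (fewer angle bins; same physics).
small_params <- function(...) {
  model_params(n_angle_bins = 12L, ...)
}

# A pairing with an exact, hand-chosen set of matched site pairs: rod A
# carries all-distinct symbols 1..n; rod B copies the target at `facing`
# sites and uses fresh unique symbols elsewhere, so match[i, j] is TRUE
# exactly at the diagonal positions in `facing`.
pairing_with_facing_matches <- function(facing, n = 17L) {
  seq_a <- seq_len(n)
  seq_b <- n + seq_len(n)
  seq_b[facing] <- seq_a[facing]
  site_pairing(seq_a, seq_b)
}

# Random small chain on an arbitrary energy landscape (bounded well depth,
# so Gillespie mean first-passage stays desk-scale).
random_small_chain <- function(n_states, params = NULL) {
  if (is.null(params))
    params <- model_params(n_angle_bins = n_states,
                           k_rot = exp(runif(1, log(0.5), log(20))))
  U <- -runif(n_states, 0, 4)
  rodsearch:::chain_from_energies(U, params, rotation_enabled = TRUE)
}

# Central run length recomputed by a brute-force scan, independent of the
# package classifier.
brute_central_run <- function(pairing) {
  m <- diag(pairing$match)
  n <- length(m)
  cc <- (n + 1L) %/% 2L
  if (!m[cc]) return(0L)
  best <- 0L
  for (lo in 1:cc) for (hi in cc:n) {
    if (all(m[lo:hi])) best <- max(best, hi - lo + 1L)
  }
  best
}
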