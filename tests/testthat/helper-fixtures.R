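# Shared fixtures, built in code.

# A small annotated corpus with learnable signal, fixed seed.
small_corpus <- function(n_sol = 10, n_bg = 20, seed = 42) {
  make_corpus(n_sol, n_bg, seed = seed)
}

# A quickly trained detector for tests that need a plausible network.
small_fit <- function(seed = 42, epochs = 60) {
  corpus <- small_corpus(seed = seed)
  solenoid_net(corpus$train, epochs = epochs, seed = seed)
}

# Synthetic score profile from explicit position/score pairs (scores default
# to a low background value elsewhere).
fake_profile <- function(positions, scores, length = max(positions) + 50,
                         id = "synthetic") {
  centers <- 20:(length - 19)
  sc <- rep(0.05, length(centers))
  sc[match(positions, centers)] <- scores
  score_profile(centers, sc, residue = rep("A", length(centers)), id = id)
}

# Independent oracle for the periodic chain rule: exhaustive enumeration of
# all position subsequences (positions sorted), longest whose consecutive
# gaps all lie in [lo, hi].
chain_oracle_length <- function(positions, lo = 30, hi = 135) {
  positions <- sort(positions)
  n <- length(positions)
  if (n <= 1L) return(n)
  for (k in seq(n, 2L)) {
    combos <- utils::combn(positions, k)
    d <- combos[-1L, , drop = FALSE] - combos[-k, , drop = FALSE]
    if (any(colSums(d < lo | d > hi) == 0L)) return(k)
  }
  1L
}
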