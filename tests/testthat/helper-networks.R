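# Shared fixtures and independent oracles, all built in code.

# Random strongly connected directed network with Uniform(0.1, 1) weights
# and Uniform(0.5, 2) recovery rates (the harness used across the exact
# identities).
rand_net <- function(n, seed, p_extra = 0.3, recovery = NULL) {
  if (is.null(recovery)) {
    recovery <- withr::with_seed(seed + 777, runif(n, 0.5, 2))
  }
  random_connected_network(n, p_extra = p_extra, recovery = recovery,
                           seed = seed)
}

# Symmetrise a network: (W + W^T) / 2, recovery unchanged.
symmetrise <- function(net) {
  contact_network_from_matrix((net$weights + Matrix::t(net$weights)) / 2,
                              recovery = net$recovery, labels = net$labels)
}

# Brute-force strongly-connected-components oracle (Boolean reachability
# closure), independent of igraph. Returns component membership vector.
brute_scc <- function(W) {
  n <- nrow(W)
  reach <- (as.matrix(W) > 0) | diag(n)
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% (reach * 1) > 0)
  }
  mutual <- reach & t(reach)
  membership <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      comp <- comp + 1L
      membership[mutual[i, ]] <- comp
    }
  }
  membership
}

# Exact probability of accumulating `c` infection events before extinction,
# by backward recursion over the embedded jump chain with an infection-count
# phase: (I - R) h_k = B h_{k+1}, h_c = 1, where R collects recovery jumps
# (phase unchanged) and B infection jumps (phase + 1). Independent of the
# simulator and of the QSD spectral machinery.
first_passage_infections <- function(net, initial, c) {
  sub <- sis_subgenerator(net)
  Q <- as.matrix(sub$Q)
  m <- nrow(Q)
  total <- -diag(Q)
  P <- Q / total
  diag(P) <- 0
  states <- seq_len(m)
  # infection jumps go to a state with one more bit set
  bits <- vapply(states, function(s) sum(bitwAnd(s, 2^(0:20)) > 0), numeric(1))
  up <- outer(bits, bits, function(a, b) b - a) == 1
  B <- P * up
  R <- P * !up
  h <- rep(1, m)
  for (k in seq_len(c)) {
    h <- solve(diag(m) - R, B %*% h)
  }
  idx <- sum(2^(sort(unique(initial)) - 1))
  as.numeric(h[idx])
}

expect_within_3se <- function(estimate, se, truth) {
  expect_lt(abs(estimate - truth), 3 * se + 1e-12)
}
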