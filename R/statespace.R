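# Encoding of the transient state space: a nonempty subset S of the n
# individuals is identified with the integer whose bit (i-1) is set iff
# individual i is infectious; states are ordered by that integer, so the
# all-infected state is the last (index 2^n - 1). The empty set (extinction)
# is absorbing and excluded.

subset_to_state <- function(idx) {
  as.integer(sum(2^(idx - 1)))
}

state_to_subset <- function(state, n) {
  which(bitwAnd(state, 2^(seq_len(n) - 1)) > 0)
}

# Indices (into 1..2^n-1) of transient states intersecting the node set W.
states_meeting <- function(w_idx, n) {
  mask <- subset_to_state(w_idx)
  states <- seq_len(2^n - 1)
  states[bitwAnd(states, mask) > 0L]
}

# Logical membership matrix: (2^n - 1) x n, entry [s, i] true iff node i is
# infectious in state s.
state_bits <- function(n) {
  states <- seq_len(2^n - 1)
  matrix(vapply(seq_len(n), function(i) bitwAnd(states, 2^(i - 1)) > 0L,
                logical(2^n - 1)),
         nrow = 2^n - 1, ncol = n)
}
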