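#' Built-in network generators
#'
#' Fixture-quality generators covering the structures used throughout:
#' a non-periodic square lattice with nearest-neighbour (4-connectivity)
#' symmetric weights, a complete network, and a random strongly connected
#' directed network built as a Hamiltonian cycle (guaranteeing strong
#' connectivity) plus independent extra edges.
#'
#' @param rows,cols Lattice dimensions (positive integers).
#' @param n Number of nodes.
#' @param beta Infection rate attached to every edge (> 0).
#' @param recovery Recovery rate(s); see [contact_network()]. Default 1 for
#'   every individual.
#' @param p_extra Probability of each additional ordered edge beyond the
#'   guaranteeing cycle.
#' @param rate_sampler Function of one integer `m` returning `m` positive
#'   rates for the random generator's edges; default `runif(m, 0.1, 1)`.
#' @param seed Optional integer seed; the same seed reproduces the network
#'   exactly.
#' @return A `contact_network`.
#' @examples
#' lattice_network(5, 5, beta = 0.8)
#' complete_network(3, beta = 5)
#' random_connected_network(6, p_extra = 0.3, seed = 1)
#' @name generators
NULL

#' @rdname generators
#' @export
lattice_network <- function(rows, cols, beta, recovery = 1) {
  check_scalar_number(rows, "rows", 1)
  check_scalar_number(cols, "cols", 1)
  check_scalar_number(beta, "beta", 0, strict = TRUE)
  rows <- as.integer(rows); cols <- as.integer(cols)
  id <- function(r, c) (r - 1L) * cols + c
  from <- integer(0); to <- integer(0)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c < cols) { from <- c(from, id(r, c)); to <- c(to, id(r, c + 1L)) }
      if (r < rows) { from <- c(from, id(r, c)); to <- c(to, id(r + 1L, c)) }
    }
  }
  ef <- c(from, to)
  et <- c(to, from)
  contact_network(tibble(from = ef, to = et, rate = beta),
                  recovery = recovery, nodes = rows * cols)
}

#' @rdname generators
#' @export
complete_network <- function(n, beta, recovery = 1) {
  check_scalar_number(n, "n", 1)
  check_scalar_number(beta, "beta", 0, strict = TRUE)
  n <- as.integer(n)
  if (n == 1) {
    return(contact_network(tibble(from = integer(0), to = integer(0),
                                  rate = numeric(0)),
                           recovery = recovery, nodes = 1L))
  }
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  contact_network(tibble(from = pairs$from, to = pairs$to, rate = beta),
                  recovery = recovery, nodes = n)
}

#' @rdname generators
#' @export
random_connected_network <- function(n, p_extra = 0.3,
                                     rate_sampler = function(m) runif(m, 0.1, 1),
                                     recovery = 1, seed = NULL) {
  check_scalar_number(n, "n", 1)
  check_scalar_number(p_extra, "p_extra", 0)
  n <- as.integer(n)
  if (n == 1) {
    return(contact_network(tibble(from = integer(0), to = integer(0),
                                  rate = numeric(0)),
                           recovery = recovery, nodes = 1L))
  }
  with_seed_(seed, {
    perm <- sample.int(n)
    cyc_from <- perm
    cyc_to <- perm[c(seq_len(n)[-1], 1L)]
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    on_cycle <- paste(pairs$from, pairs$to) %in% paste(cyc_from, cyc_to)
    extra <- !on_cycle & runif(nrow(pairs)) < p_extra
    from <- c(cyc_from, pairs$from[extra])
    to <- c(cyc_to, pairs$to[extra])
    rate <- rate_sampler(length(from))
    if (any(rate <= 0)) abort("`rate_sampler` must return positive rates.")
    contact_network(tibble(from = from, to = to, rate = rate),
                    recovery = recovery, nodes = n)
  })
}
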