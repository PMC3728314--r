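#' Contact networks for Markovian SIS dynamics
#'
#' A contact network is the complete parameterisation of the SIS model: a
#' weighted directed graph whose edge \eqn{(i, j)} carries the rate of the
#' Poisson process by which individual \eqn{i} infects individual \eqn{j}
#' (while \eqn{i} is infectious and \eqn{j} susceptible), together with a
#' strictly positive per-individual recovery rate \eqn{g_i}.
#'
#' `contact_network()` builds a network from a tidy edge table.
#' `contact_network_from_matrix()` builds one from a square rate matrix.
#'
#' @param edges A data frame with columns `from`, `to` and `rate`. `from`
#'   and `to` may be integer node indices (1-based) or character labels;
#'   `rate` must be positive. Self-loops and duplicate edges are errors.
#' @param recovery Recovery rates: a single positive number recycled to all
#'   nodes, a numeric vector of length `n`, or a data frame with columns
#'   `node` and `rate` (nodes by label or index; all nodes must be covered
#'   or a scalar `default` supplied via a `"default"` attribute is not
#'   supported -- supply all nodes).
#' @param nodes Optional node universe: an integer count or a character
#'   vector of labels. Defaults to the nodes seen in `edges`.
#' @param weights A square numeric matrix (base or `Matrix`) of infection
#'   rates, zero diagonal.
#' @param labels Optional character labels, one per node.
#'
#' @return An object of class `contact_network`: a list with elements `n`,
#'   `weights` (sparse `dgCMatrix`), `recovery` and `labels`.
#'
#' @examples
#' net <- contact_network(
#'   tibble::tibble(from = c("a", "b"), to = c("b", "a"), rate = 1),
#'   recovery = 1
#' )
#' net
#' is_strongly_connected(net)
#' @export
contact_network <- function(edges, recovery = 1, nodes = NULL) {
  edges <- as.data.frame(edges)
  required <- c("from", "to", "rate")
  if (!all(required %in% names(edges))) {
    abort("`edges` must have columns `from`, `to` and `rate`.")
  }
  if (is.null(nodes)) {
    seen <- unique(c(as.character(edges$from), as.character(edges$to)))
    if (is.numeric(edges$from) && is.numeric(edges$to)) {
      n <- max(c(edges$from, edges$to, 0L))
      labels <- as.character(seq_len(n))
    } else {
      labels <- sort(seen)
      n <- length(labels)
    }
  } else if (is.numeric(nodes) && length(nodes) == 1) {
    n <- as.integer(nodes)
    labels <- as.character(seq_len(n))
  } else {
    labels <- as.character(nodes)
    if (anyDuplicated(labels)) abort("Node labels must be unique.")
    n <- length(labels)
  }
  from <- resolve_nodes(edges$from, labels, n, "from")
  to <- resolve_nodes(edges$to, labels, n, "to")
  rate <- as.numeric(edges$rate)
  if (any(!is.finite(rate)) || any(rate < 0)) {
    abort("Edge rates must be finite and nonnegative.")
  }
  if (any(from == to)) {
    abort("Self-loops are not allowed (an individual does not infect itself).")
  }
  if (anyDuplicated(cbind(from, to))) {
    abort("Duplicate edges found; each ordered pair may appear at most once.")
  }
  keep <- rate > 0
  weights <- Matrix::sparseMatrix(
    i = from[keep], j = to[keep], x = rate[keep], dims = c(n, n)
  )
  new_contact_network(weights, resolve_recovery(recovery, labels, n), labels)
}

#' @rdname contact_network
#' @export
contact_network_from_matrix <- function(weights, recovery = 1, labels = NULL) {
  weights <- methods::as(methods::as(Matrix::Matrix(weights, sparse = TRUE),
                                     "generalMatrix"), "CsparseMatrix")
  if (nrow(weights) != ncol(weights)) abort("`weights` must be square.")
  n <- nrow(weights)
  if (any(weights@x < 0)) abort("Infection rates must be nonnegative.")
  if (any(Matrix::diag(weights) != 0)) abort("Diagonal entries must be zero.")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (length(labels) != n) abort("`labels` must have one entry per node.")
  weights <- Matrix::drop0(weights)
  new_contact_network(weights, resolve_recovery(recovery, labels, n), labels)
}

new_contact_network <- function(weights, recovery, labels) {
  dimnames(weights) <- NULL
  structure(
    list(n = nrow(weights), weights = weights, recovery = recovery,
         labels = as.character(labels)),
    class = "contact_network"
  )
}

resolve_nodes <- function(x, labels, n, what) {
  if (is.numeric(x)) {
    idx <- as.integer(x)
    if (any(is.na(idx)) || any(idx < 1) || any(idx > n)) {
      abort(sprintf("`%s` contains node indices outside 1..%d.", what, n))
    }
    return(idx)
  }
  idx <- match(as.character(x), labels)
  if (anyNA(idx)) {
    abort(sprintf("`%s` contains unknown node labels: %s.", what,
                  paste(unique(x[is.na(idx)]), collapse = ", ")))
  }
  idx
}

resolve_recovery <- function(recovery, labels, n) {
  if (is.data.frame(recovery)) {
    if (!all(c("node", "rate") %in% names(recovery))) {
      abort("A recovery table needs columns `node` and `rate`.")
    }
    idx <- resolve_nodes(recovery$node, labels, n, "recovery$node")
    if (anyDuplicated(idx)) abort("Duplicate nodes in recovery table.")
    g <- rep(NA_real_, n)
    g[idx] <- as.numeric(recovery$rate)
    if (anyNA(g)) abort("Recovery table must cover every node.")
    recovery <- g
  } else if (length(recovery) == 1) {
    recovery <- rep(as.numeric(recovery), n)
  } else if (length(recovery) != n) {
    abort("`recovery` must be scalar, length-n, or a node/rate table.")
  }
  recovery <- as.numeric(recovery)
  if (any(!is.finite(recovery)) || any(recovery <= 0)) {
    abort("All recovery rates must be finite and strictly positive.")
  }
  recovery
}

#' @export
print.contact_network <- function(x, ...) {
  m <- Matrix::nnzero(x$weights)
  cat(sprintf("<contact_network> %d nodes, %d directed positive-rate edges\n",
              x$n, m))
  cat(sprintf("  recovery rates in [%g, %g]\n",
              min(x$recovery), max(x$recovery)))
  invisible(x)
}

#' @export
format.contact_network <- function(x, ...) {
  sprintf("<contact_network: %d nodes>", x$n)
}

#' Tidy a contact network into its edge table
#'
#' Returns one row per positive-rate directed edge, with node labels.
#'
#' @param x A `contact_network`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `rate`.
#' @export
tidy.contact_network <- function(x, ...) {
  tm <- Matrix::mat2triplet(x$weights)
  ord <- order(tm$i, tm$j)
  tibble(
    from = x$labels[tm$i[ord]],
    to = x$labels[tm$j[ord]],
    rate = tm$x[ord]
  )
}

#' @export
glance.contact_network <- function(x, ...) {
  tibble(
    nodes = x$n,
    edges = Matrix::nnzero(x$weights),
    strongly_connected = is_strongly_connected(x),
    undirected = Matrix::isSymmetric(x$weights),
    min_rate = if (Matrix::nnzero(x$weights)) min(x$weights@x) else NA_real_,
    max_rate = if (Matrix::nnzero(x$weights)) max(x$weights@x) else NA_real_
  )
}

#' Transpose a contact network
#'
#' Reverses every infection route: the transposed network has
#' \eqn{T^\top_{ij} = T_{ji}} while recovery rates and labels are unchanged.
#' The transpose is the bridge between the two quantifiers: invasion
#' probability on a network equals quasi-stationary prevalence on its
#' transpose.
#'
#' @param x A `contact_network`.
#' @return The transposed `contact_network`.
#' @examples
#' net <- complete_network(3, beta = 2)
#' identical(tidy(t(t(net))), tidy(net))
#' @export
t.contact_network <- function(x) {
  new_contact_network(Matrix::t(x$weights), x$recovery, x$labels)
}

#' @rdname t.contact_network
#' @param net A `contact_network`.
#' @export
transpose_network <- function(net) t(net)

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "directed",
                                      weighted = TRUE)
}

#' Strong connectivity of the positive-rate digraph
#'
#' The exact theory (unique QSD, invasion probability, the
#' prevalence-invasion identity) requires that infection can be transmitted,
#' via some route, from any individual to any other: the positive-rate
#' digraph must be strongly connected.
#'
#' @param net A `contact_network`.
#' @return `TRUE` or `FALSE`. A single node is trivially strongly connected.
#' @export
is_strongly_connected <- function(net) {
  if (net$n == 1) return(TRUE)
  igraph::is_connected(as_igraph(net), mode = "strong")
}

#' Largest strongly connected component
#'
#' Extracts the induced sub-network on the largest strongly connected
#' component of the positive-rate digraph. Ties between equally large
#' components are broken in favour of the one containing the smallest
#' original node index.
#'
#' @param net A `contact_network`.
#' @return A list with elements `network` (the induced `contact_network`,
#'   which is strongly connected) and `mapping` (a tibble with columns
#'   `new`, `old`, `label` mapping component node indices back to the
#'   original network).
#' @export
largest_scc <- function(net) {
  comp <- igraph::components(as_igraph(net), mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    first_member <- vapply(best, function(k) min(which(comp$membership == k)),
                           integer(1))
    best <- best[which.min(first_member)]
  }
  old <- which(comp$membership == best)
  sub <- net$weights[old, old, drop = FALSE]
  list(
    network = new_contact_network(
      methods::as(Matrix::Matrix(sub, sparse = TRUE), "CsparseMatrix"),
      net$recovery[old], net$labels[old]
    ),
    mapping = tibble(new = seq_along(old), old = old, label = net$labels[old])
  )
}

#' Rescale all infection rates by a scalar multiplier
#'
#' Multiplying the rate matrix by a global factor models infectious agents
#' of varying transmissibility spreading through the same population;
#' recovery rates are untouched.
#'
#' @param net A `contact_network`.
#' @param multiplier A positive scalar.
#' @return The rescaled `contact_network`.
#' @export
scale_weights <- function(net, multiplier) {
  check_scalar_number(multiplier, "multiplier", 0, strict = TRUE)
  new_contact_network(net$weights * multiplier, net$recovery, net$labels)
}

# Resolve a user-supplied node set (indices or labels) to sorted indices.
resolve_node_set <- function(net, nodes, allow_empty = FALSE) {
  if (is.null(nodes) || length(nodes) == 0) {
    if (allow_empty) return(integer(0))
    abort("A nonempty set of nodes is required.")
  }
  idx <- resolve_nodes(nodes, net$labels, net$n, "nodes")
  idx <- sort(unique(idx))
  idx
}
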