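#' Sub-generator of the SIS master equation
#'
#' Builds the transition-rate matrix of the master equation restricted to
#' the \eqn{2^n - 1} transient (non-extinct) states. For a transient state
#' \eqn{S}: infection of a susceptible \eqn{j} occurs at rate
#' \eqn{\sum_{i \in S} T_{ij}}, recovery of an infectious \eqn{i} at rate
#' \eqn{g_i}; the transition out of a singleton state via its only recovery
#' is the exit into the absorbing (extinct) state. Each diagonal entry is
#' minus the total outflow including exit, so row sums of `Q` plus the exit
#' rates are zero.
#'
#' @param net A strongly connected `contact_network`.
#' @param cap Population cap guarding against accidental exponential
#'   blow-up; `2^n - 1` states are materialised. Default 12 (32,767
#'   states, ~tens of MB as a sparse matrix); raise explicitly if you mean
#'   it.
#' @return An object of class `sis_subgenerator`: list with `Q` (sparse
#'   `dgCMatrix`), `exit` (per-state exit rate), `n`, and the originating
#'   network.
#' @export
sis_subgenerator <- function(net, cap = 12) {
  if (!is_strongly_connected(net)) {
    abort("Exact computations require a strongly connected network.")
  }
  if (net$n > cap) {
    abort(sprintf(
      "n = %d exceeds the exact-computation cap (%d); raise `cap` explicitly.",
      net$n, cap))
  }
  n <- net$n
  m <- 2^n - 1
  states <- seq_len(m)
  bits <- state_bits(n)                       # m x n membership
  pressure <- bits %*% as.matrix(net$weights) # m x n infectious pressure

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  exit <- numeric(m)
  for (i in seq_len(n)) {
    b <- 2^(i - 1)
    # recoveries of node i
    from <- states[bits[, i]]
    to <- from - b
    inside <- to > 0L
    ii <- c(ii, from[inside]); jj <- c(jj, to[inside])
    xx <- c(xx, rep(net$recovery[i], sum(inside)))
    exit[from[!inside]] <- net$recovery[i]    # S = {i}: exit to extinction
    # infections of node i
    sus <- !bits[, i]
    lam <- pressure[sus, i]
    from <- states[sus][lam > 0]
    ii <- c(ii, from); jj <- c(jj, from + b); xx <- c(xx, lam[lam > 0])
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, m))
  Matrix::diag(Q) <- -(Matrix::rowSums(Q) + exit)
  structure(list(Q = Q, exit = exit, n = n, net = net),
            class = "sis_subgenerator")
}

#' @export
print.sis_subgenerator <- function(x, ...) {
  cat(sprintf("<sis_subgenerator> %d nodes, %d transient states\n",
              x$n, nrow(x$Q)))
  invisible(x)
}

#' Quasi-stationary distribution, decay parameter and invasion vector
#'
#' Computes the Perron triple of the sub-generator `Q` of a strongly
#' connected network: the quasi-stationary distribution \eqn{\nu} (left
#' eigenvector, \eqn{\nu Q = -\alpha \nu}, normalised to sum 1), the decay
#' parameter \eqn{\alpha > 0} (the exponential rate at which the process
#' started in the QSD decays to extinction), and the invasion vector
#' \eqn{w} (right eigenvector, \eqn{Q w = -\alpha w}, normalised so the
#' all-infected state has value 1). Entry \eqn{w(A)} is the quasi-invasion
#' probability from initial state \eqn{A}: the limit of the ratio of
#' survival probability from \eqn{A} to survival probability from the
#' all-infected state. Irreducibility of the transient class makes
#' \eqn{-\alpha} real and simple with strictly positive eigenvectors.
#'
#' Dense eigendecomposition is used below 1,300 states; above that a power
#' iteration with Rayleigh-quotient/inverse-iteration refinement on the
#' sparse matrix. Residuals beyond `tol` (max-norm, after normalisation)
#' are an error, never silently returned.
#'
#' @param x A `contact_network` or `sis_subgenerator`.
#' @param cap Passed to [sis_subgenerator()] when `x` is a network.
#' @param tol Residual tolerance for both eigenpairs.
#' @param ... Unused.
#' @return An object of class `sis_qsd` with elements `nu`, `alpha`, `w`,
#'   `spectral_gap`, `residual_nu`, `residual_w`, `n`, `net`.
#' @examples
#' q <- sis_qsd(complete_network(2, beta = 1))
#' q$alpha              # 2 - sqrt(2)
#' tidy(q)              # per-node prevalence and invasion probability
#' @export
sis_qsd <- function(x, ...) UseMethod("sis_qsd")

#' @rdname sis_qsd
#' @export
sis_qsd.contact_network <- function(x, cap = 12, tol = 1e-10, ...) {
  sis_qsd(sis_subgenerator(x, cap = cap), tol = tol)
}

#' @rdname sis_qsd
#' @export
sis_qsd.sis_subgenerator <- function(x, tol = 1e-10, ...) {
  Q <- x$Q
  m <- nrow(Q)
  if (m < 1300) {
    right <- dense_dominant(Q)
    left <- dense_dominant(Matrix::t(Q))
    gap <- right$gap
  } else {
    right <- sparse_dominant(Q, tol)
    left <- sparse_dominant(Matrix::t(Q), tol)
    gap <- NA_real_
  }
  if (abs(right$value - left$value) > 1e-6 * max(1, abs(right$value))) {
    abort("Left and right dominant eigenvalues disagree; eigensolver failed.")
  }
  alpha <- -(right$value + left$value) / 2
  nu <- positive_vector(left$vector, "nu")
  nu <- nu / sum(nu)
  w <- positive_vector(right$vector, "w")
  w <- w / w[m]
  residual_nu <- max(abs(as.numeric(Matrix::crossprod(Q, nu)) + alpha * nu))
  residual_w <- max(abs(as.numeric(Q %*% w) + alpha * w)) / max(w)
  if (residual_nu > tol || residual_w > tol) {
    abort(sprintf(
      "Eigensolver residuals (%.2e, %.2e) exceed tolerance %.1e.",
      residual_nu, residual_w, tol))
  }
  structure(
    list(nu = nu, alpha = alpha, w = w, spectral_gap = gap,
         residual_nu = residual_nu, residual_w = residual_w,
         n = x$n, net = x$net),
    class = "sis_qsd"
  )
}

dense_dominant <- function(Q) {
  e <- eigen(as.matrix(Q))
  re <- Re(e$values)
  k <- which.max(re)
  if (abs(Im(e$values[k])) > 1e-8) {
    abort("Dominant eigenvalue has a nonzero imaginary part.")
  }
  gap <- if (length(re) > 1) re[k] - max(re[-k]) else Inf
  list(value = Re(e$values[k]), vector = Re(e$vectors[, k]), gap = gap)
}

# Power iteration on the nonnegative matrix I + Q/Lambda followed by
# shift-invert refinement; returns the eigenpair of Q with largest real
# part (Perron pair of the irreducible transient class).
sparse_dominant <- function(Q, tol, max_power = 5000, max_refine = 30) {
  m <- nrow(Q)
  lambda_u <- max(-Matrix::diag(Q)) * 1.000001
  v <- rep(1 / m, m)
  val <- NA_real_
  for (k in seq_len(max_power)) {
    v_new <- v + as.numeric(Q %*% v) / lambda_u
    v_new <- v_new / sum(abs(v_new))
    if (k %% 20 == 0) {
      qv <- as.numeric(Q %*% v_new)
      val <- sum(v_new * qv) / sum(v_new * v_new)
      if (max(abs(qv - val * v_new)) / max(abs(v_new)) < 1e-6) break
    }
    v <- v_new
  }
  v <- v_new
  for (k in seq_len(max_refine)) {
    qv <- as.numeric(Q %*% v)
    val <- sum(v * qv) / sum(v * v)
    res <- max(abs(qv - val * v)) / max(abs(v))
    if (res < tol / 10) break
    shift <- val + max(1e-12, abs(val) * 1e-9)
    v <- as.numeric(Matrix::solve(Q - shift * Matrix::Diagonal(m), v))
    v <- v / sqrt(sum(v^2))
  }
  if (res >= tol) {
    abort(sprintf("Sparse eigensolver did not converge (residual %.2e).", res))
  }
  list(value = val, vector = v, gap = NA_real_)
}

positive_vector <- function(v, name) {
  i <- which.max(abs(v))
  v <- v * sign(v[i])
  if (min(v) < -1e-8 * max(v)) {
    abort(sprintf("Eigenvector `%s` is not one-signed; eigensolver failed.",
                  name))
  }
  pmax(v, 0)
}

#' @export
print.sis_qsd <- function(x, ...) {
  cat(sprintf("<sis_qsd> %d nodes, %d transient states\n", x$n, length(x$nu)))
  cat(sprintf("  decay parameter alpha = %.8g\n", x$alpha))
  cat(sprintf("  mean fraction infected in QSD = %.6g\n",
              mean(tidy(x)$prevalence)))
  invisible(x)
}

#' Tidy per-node summary of an exact QSD fit
#'
#' One row per individual: the marginal quasi-prevalence \eqn{p_i} (the
#' probability that \eqn{i} is infectious in the QSD) and the quasi-invasion
#' probability from \eqn{i} alone (on the same network; by duality this
#' equals the prevalence of \eqn{i} on the transposed network).
#'
#' @param x A `sis_qsd` object.
#' @param ... Unused.
#' @return A tibble with columns `node`, `label`, `prevalence`, `invasion`.
#' @export
tidy.sis_qsd <- function(x, ...) {
  tibble(
    node = seq_len(x$n),
    label = x$net$labels,
    prevalence = vapply(seq_len(x$n),
                        function(i) qsd_event_probability(x, i), numeric(1)),
    invasion = vapply(seq_len(x$n),
                      function(i) invasion_probability_exact(x, i), numeric(1))
  )
}

#' @export
glance.sis_qsd <- function(x, ...) {
  tibble(
    nodes = x$n,
    states = length(x$nu),
    alpha = x$alpha,
    spectral_gap = x$spectral_gap,
    mean_prevalence = mean(tidy(x)$prevalence),
    residual_nu = x$residual_nu,
    residual_w = x$residual_w
  )
}

#' Quasi-stationary event probability of a node set
#'
#' The probability, under the quasi-stationary distribution, that at least
#' one individual of `nodes` is infectious: the sum of \eqn{\nu} over
#' transient states intersecting the set. For a single node this is the
#' marginal quasi-prevalence \eqn{p_i}.
#'
#' @param qsd A `sis_qsd` object.
#' @param nodes Nonempty set of node indices or labels.
#' @return A probability in (0, 1].
#' @export
qsd_event_probability <- function(qsd, nodes) {
  idx <- resolve_node_set(qsd$net, nodes)
  sum(qsd$nu[states_meeting(idx, qsd$n)])
}

#' Exact quasi-invasion probability from an initial set
#'
#' The quasi-invasion probability for an outbreak initiated on exactly the
#' members of `nodes`: the limit, as \eqn{t \to \infty}, of the ratio of
#' the survival probability from that initial state to the survival
#' probability from the all-infected state. Realised spectrally as the
#' entry of the invasion vector \eqn{w} at the initial state
#' (quasi-invasion is certain, value 1, from the all-infected state).
#'
#' @inheritParams qsd_event_probability
#' @param nodes Nonempty set of initially infected nodes.
#' @return A probability in (0, 1].
#' @export
invasion_probability_exact <- function(qsd, nodes) {
  idx <- resolve_node_set(qsd$net, nodes)
  qsd$w[subset_to_state(idx)]
}

# Action of expm(Q t) on a nonnegative vector by uniformisation: with
# Lambda >= max(-diag Q), P = I + Q/Lambda is nonnegative, and
# expm(Qt) v = sum_k dpois(k, Lambda t) P^k v  -- all terms positive, so no
# cancellation. Long horizons are split so Lambda*dt <= 200 per chunk,
# keeping exp(-Lambda dt) representable.
expm_action <- function(Q, v, t, tol = 1e-14) {
  if (t == 0) return(v)
  lambda_u <- max(-Matrix::diag(Q)) * (1 + 1e-12)
  if (lambda_u == 0) return(v)
  n_chunk <- max(1, ceiling(lambda_u * t / 200))
  dt <- t / n_chunk
  for (chunk in seq_len(n_chunk)) {
    a <- lambda_u * dt
    term <- v * exp(-a)
    acc <- term
    k <- 0
    repeat {
      k <- k + 1
      term <- (term + as.numeric(Q %*% term) / lambda_u) * (a / k)
      acc <- acc + term
      if (k > a + 10 * sqrt(a) + 10 && max(term) < tol * max(acc, 1e-300)) break
      if (k > 1e6) abort("Uniformisation failed to converge.")
    }
    v <- acc
  }
  v
}

#' Transient event probabilities from the master equation
#'
#' `transient_event_probability()` computes
#' \eqn{P(\xi^A_t \cap W \neq \emptyset)}: the probability that at least
#' one member of `event_nodes` is infectious at time `t`, given that
#' exactly the members of `initial` are infectious at time 0. With
#' `event_nodes` equal to all nodes this is the survival probability of the
#' epidemic. Computed as the action of the matrix exponential of the
#' sub-generator on the indicator of states meeting `event_nodes`.
#'
#' `conditioned_prevalence()` starts all-infected and conditions on
#' survival to `t`; as \eqn{t \to \infty} it converges to
#' [qsd_event_probability()]. `survival_ratio()` is the quotient of the
#' survival probability from `initial` and from all-infected; its
#' \eqn{t \to \infty} limit is [invasion_probability_exact()].
#'
#' @param net A strongly connected `contact_network`.
#' @param initial Nonempty set of initially infectious nodes.
#' @param event_nodes Nonempty node set whose joint infection status is
#'   queried.
#' @param t Time (>= 0).
#' @param cap Exact-computation population cap.
#' @return A probability (or probability ratio for `survival_ratio()`).
#' @examples
#' net <- complete_network(2, beta = 1)
#' transient_event_probability(net, initial = 1, event_nodes = 1:2, t = 1)
#' survival_ratio(net, initial = 1, t = 50)   # ~ 1/sqrt(2)
#' @export
transient_event_probability <- function(net, initial, event_nodes, t,
                                        cap = 12) {
  check_scalar_number(t, "t", 0)
  a_idx <- resolve_node_set(net, initial)
  w_idx <- resolve_node_set(net, event_nodes)
  sub <- sis_subgenerator(net, cap = cap)
  f <- numeric(nrow(sub$Q))
  f[states_meeting(w_idx, net$n)] <- 1
  u <- expm_action(sub$Q, f, t)
  min(1, u[subset_to_state(a_idx)])
}

#' @rdname transient_event_probability
#' @export
conditioned_prevalence <- function(net, event_nodes, t, cap = 12) {
  check_scalar_number(t, "t", 0)
  w_idx <- resolve_node_set(net, event_nodes)
  sub <- sis_subgenerator(net, cap = cap)
  m <- nrow(sub$Q)
  f <- numeric(m); f[states_meeting(w_idx, net$n)] <- 1
  s <- rep(1, m)
  num <- expm_action(sub$Q, f, t)[m]
  den <- expm_action(sub$Q, s, t)[m]
  if (den == 0) abort("Survival probability underflowed; reduce `t`.")
  min(1, num / den)
}

#' @rdname transient_event_probability
#' @export
survival_ratio <- function(net, initial, t, cap = 12) {
  check_scalar_number(t, "t", 0)
  a_idx <- resolve_node_set(net, initial)
  sub <- sis_subgenerator(net, cap = cap)
  m <- nrow(sub$Q)
  u <- expm_action(sub$Q, rep(1, m), t)
  if (u[m] == 0) abort("Survival probability underflowed; reduce `t`.")
  min(1, u[subset_to_state(a_idx)] / u[m])
}
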