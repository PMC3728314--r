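#' Exact verification of the prevalence-invasion relationship
#'
#' For each initial set \eqn{A} in scope, computes the exact quasi-invasion
#' probability on `net` and the exact quasi-stationary event probability of
#' \eqn{A} on the transposed network, which the prevalence-invasion
#' relationship asserts are equal (for undirected networks the transpose is
#' the network itself, so invasion from an individual equals its own
#' quasi-prevalence). The report records every pair and the maximum
#' absolute deviation.
#'
#' @param net A strongly connected `contact_network` within the exact cap
#'   (`scope = "all"` enumerates all \eqn{2^n - 1} subsets; keep
#'   \eqn{n \le 6} there).
#' @param scope `"singletons"` (one row per individual) or `"all"` (one row
#'   per nonempty subset).
#' @param tol Pass tolerance on the maximum deviation.
#' @param cap Exact-computation population cap.
#' @return A tibble of class `sis_relationship` with columns `subset`
#'   (comma-separated node labels), `invasion`, `prevalence_transpose`,
#'   `deviation`, and attributes `max_deviation`, `pass`, `tol`.
#' @examples
#' rep <- verify_relationship_exact(complete_network(2, beta = 1))
#' attr(rep, "max_deviation") < 1e-10
#' @export
verify_relationship_exact <- function(net, scope = c("singletons", "all"),
                                      tol = 1e-8, cap = 12) {
  scope <- match.arg(scope)
  qsd_fwd <- sis_qsd(net, cap = cap)
  qsd_rev <- sis_qsd(t(net), cap = cap)
  sets <- if (scope == "singletons") {
    as.list(seq_len(net$n))
  } else {
    lapply(seq_len(2^net$n - 1), state_to_subset, n = net$n)
  }
  inv <- vapply(sets, function(a) invasion_probability_exact(qsd_fwd, a),
                numeric(1))
  prev <- vapply(sets, function(a) qsd_event_probability(qsd_rev, a),
                 numeric(1))
  out <- tibble(
    subset = vapply(sets, function(a) paste(net$labels[a], collapse = ","),
                    character(1)),
    invasion = inv,
    prevalence_transpose = prev,
    deviation = abs(inv - prev)
  )
  structure(out, class = c("sis_relationship", class(out)),
            max_deviation = max(out$deviation),
            pass = max(out$deviation) < tol, tol = tol, scope = scope)
}

#' @export
glance.sis_relationship <- function(x, ...) {
  tibble(subsets = nrow(x), max_deviation = attr(x, "max_deviation"),
         tol = attr(x, "tol"), pass = attr(x, "pass"),
         scope = attr(x, "scope"))
}

#' Transpose invariance of the decay to extinction
#'
#' A network and its transpose share the same decay parameter \eqn{\alpha},
#' the same survival probability from the all-infected state at every time,
#' and the same probability that individual \eqn{i} is infectious at time
#' \eqn{t} when the outbreak is seeded on \eqn{i} alone. This check
#' verifies all three exactly (eigen and matrix-exponential computations on
#' both orientations).
#'
#' @param net A strongly connected `contact_network` within the exact cap.
#' @param times Time grid for the survival and self-marginal comparisons.
#' @param tol Pass tolerance on every deviation.
#' @param cap Exact-computation population cap.
#' @return A list of class `sis_transpose_check` with elements `alpha`,
#'   `alpha_transpose`, `alpha_deviation`, `survival` (tibble `time`,
#'   `net`, `transpose`, `deviation`), `self_marginal` (tibble `time`,
#'   `node`, `net`, `transpose`, `deviation`), `max_deviation`, `pass`.
#' @export
transpose_decay_check <- function(net, times = c(0.5, 1, 2), tol = 1e-10,
                                  cap = 12) {
  tnet <- t(net)
  all_nodes <- seq_len(net$n)
  q1 <- sis_qsd(net, cap = cap)
  q2 <- sis_qsd(tnet, cap = cap)
  surv_fwd <- vapply(times, function(s)
    transient_event_probability(net, all_nodes, all_nodes, s, cap = cap),
    numeric(1))
  surv_rev <- vapply(times, function(s)
    transient_event_probability(tnet, all_nodes, all_nodes, s, cap = cap),
    numeric(1))
  surv <- tibble(time = times, net = surv_fwd, transpose = surv_rev,
                 deviation = abs(surv_fwd - surv_rev))
  grid <- expand.grid(time = times, node = all_nodes)
  self_fwd <- mapply(function(s, i)
    transient_event_probability(net, i, i, s, cap = cap),
    grid$time, grid$node)
  self_rev <- mapply(function(s, i)
    transient_event_probability(tnet, i, i, s, cap = cap),
    grid$time, grid$node)
  self <- tibble(time = grid$time, node = grid$node,
                 net = self_fwd, transpose = self_rev,
                 deviation = abs(self_fwd - self_rev))
  max_dev <- max(abs(q1$alpha - q2$alpha), surv$deviation, self$deviation)
  structure(
    list(alpha = q1$alpha, alpha_transpose = q2$alpha,
         alpha_deviation = abs(q1$alpha - q2$alpha),
         survival = surv, self_marginal = self,
         max_deviation = max_dev, pass = max_dev < tol, tol = tol),
    class = "sis_transpose_check"
  )
}

#' @export
print.sis_transpose_check <- function(x, ...) {
  cat(sprintf("<sis_transpose_check> alpha = %.10g vs %.10g (|diff| %.2e)\n",
              x$alpha, x$alpha_transpose, x$alpha_deviation))
  cat(sprintf("  max deviation %.2e (tol %.1e): %s\n", x$max_deviation,
              x$tol, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Paired measurement of invasion probability and prevalence
#'
#' Scaled-down version of the scalar-multiplier experiment: for each
#' multiplier \eqn{m}, the infection-rate matrix is scaled by \eqn{m} and
#' two independent Monte-Carlo measurements are made -- the
#' censored-fraction quasi-invasion probability from `seed_node` on the
#' scaled network, and the time-average quasi-prevalence of `seed_node` on
#' the transposed scaled network (the same network when undirected). The
#' prevalence-invasion relationship predicts the pairs fall on the
#' diagonal within sampling error.
#'
#' @param net A strongly connected `contact_network`.
#' @param seed_node The individual seeding invasion (and whose prevalence
#'   is measured on the transpose).
#' @param multipliers Positive scalars applied to the rate matrix.
#' @param n_reps Replicates for the invasion estimator.
#' @param threshold Infection-event censoring threshold `c`.
#' @param total_events,burnin Passed to [estimate_qsd_marginals()].
#' @param seed Master seed; sub-seeds are derived per multiplier.
#' @return A tibble of class `sis_paired_experiment` with one row per
#'   multiplier: `multiplier`, `invasion`, `invasion_se`, `prevalence`,
#'   `prevalence_se`, `dichotomy_ok`.
#' @export
paired_quantifier_experiment <- function(net, seed_node,
                                         multipliers = c(0.5, 0.8, 1, 1.5),
                                         n_reps = 1e4, threshold = 500,
                                         total_events = 1e5, burnin = 0.1,
                                         seed = 1) {
  node <- resolve_node_set(net, seed_node)
  if (length(node) != 1) abort("`seed_node` must be a single individual.")
  rows <- purrr::map(seq_along(multipliers), function(k) {
    m <- multipliers[k]
    scaled <- scale_weights(net, m)
    inv <- withCallingHandlers(
      estimate_invasion_probability(scaled, node, threshold = threshold,
                                    n_reps = n_reps,
                                    seed = derive_seed(seed, 2 * k - 1)),
      warning = function(w) invokeRestart("muffleWarning")
    )
    prev <- estimate_qsd_marginals(t(scaled), total_events = total_events,
                                   burnin = burnin,
                                   seed = derive_seed(seed, 2 * k))
    tibble(
      multiplier = m,
      invasion = inv$estimate, invasion_se = inv$se,
      prevalence = prev$estimate[node], prevalence_se = prev$se[node],
      dichotomy_ok = inv$dichotomy_ok
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("sis_paired_experiment", class(out)),
            seed_node = node, seed = seed)
}
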