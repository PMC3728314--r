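#' Sample a Harris graphical representation
#'
#' Draws one realisation of the percolation (graphical) construction of SIS
#' dynamics on `net` over the horizon `(0, t_max]`: an independent
#' homogeneous Poisson process of "points of cure" with rate \eqn{g_i} on
#' each individual's time line, and of "arrows of infection" with rate
#' \eqn{T_{ij}} for each ordered pair with positive rate. A single
#' realisation simultaneously encodes the epidemic from every initial
#' condition: individual \eqn{j} is infectious at time \eqn{t} iff a
#' time-respecting path, following arrow directions and blocked by cure
#' points, leads from some initially infected time line at 0 to \eqn{(j, t)}.
#'
#' Simultaneous events have probability zero; a stable global order index
#' assigned at sampling breaks any numerical ties deterministically.
#'
#' @param net A `contact_network`.
#' @param t_max Horizon (> 0).
#' @param seed Optional integer seed (uses, then restores, R's RNG).
#' @return An object of class `sis_realisation`: list with `t_max`, `n`,
#'   `cures` (tibble `node`, `time`, `id`), `arrows` (tibble `from`, `to`,
#'   `time`, `id`), and `net`.
#' @examples
#' real <- sample_realisation(complete_network(3, beta = 1), t_max = 2,
#'                            seed = 1)
#' reachable_set(real, initial = 1, t = 2)
#' @export
sample_realisation <- function(net, t_max, seed = NULL) {
  check_scalar_number(t_max, "t_max", 0, strict = TRUE)
  with_seed_(seed, {
    cure_n <- stats::rpois(net$n, net$recovery * t_max)
    cures <- tibble(
      node = rep(seq_len(net$n), cure_n),
      time = runif(sum(cure_n), 0, t_max)
    )
    ed <- tidy(net)
    ei <- resolve_nodes(ed$from, net$labels, net$n, "from")
    ej <- resolve_nodes(ed$to, net$labels, net$n, "to")
    arrow_n <- stats::rpois(length(ei), ed$rate * t_max)
    arrows <- tibble(
      from = rep(ei, arrow_n),
      to = rep(ej, arrow_n),
      time = runif(sum(arrow_n), 0, t_max)
    )
    all_times <- c(cures$time, arrows$time)
    ids <- rank(all_times, ties.method = "first")
    cures$id <- ids[seq_len(nrow(cures))]
    arrows$id <- if (nrow(arrows)) ids[nrow(cures) + seq_len(nrow(arrows))]
                 else integer(0)
    cures <- cures[order(cures$id), ]
    arrows <- arrows[order(arrows$id), ]
    structure(list(t_max = t_max, n = net$n, cures = cures, arrows = arrows,
                   net = net),
              class = "sis_realisation")
  })
}

#' @export
print.sis_realisation <- function(x, ...) {
  cat(sprintf("<sis_realisation> %d nodes, horizon %g: %d cure points, %d infection arrows\n",
              x$n, x$t_max, nrow(x$cures), nrow(x$arrows)))
  invisible(x)
}

# Merged event stream of a realisation up to time t, in sweep order.
merged_events <- function(real, t) {
  ev <- rbind(
    if (nrow(real$cures))
      data.frame(kind = 1L, a = real$cures$node, b = 0L,
                 time = real$cures$time, id = real$cures$id)
    else NULL,
    if (nrow(real$arrows))
      data.frame(kind = 2L, a = real$arrows$from, b = real$arrows$to,
                 time = real$arrows$time, id = real$arrows$id)
    else NULL
  )
  if (is.null(ev)) return(data.frame(kind = integer(0), a = integer(0),
                                     b = integer(0), time = numeric(0),
                                     id = integer(0)))
  ev <- ev[ev$time <= t, , drop = FALSE]
  ev[order(ev$time, ev$id), , drop = FALSE]
}

#' Reachability within a graphical realisation
#'
#' `reachable_set()` computes \eqn{\xi^A_t}: the set of individuals whose
#' time-line point at `t` is joined to time 0 of some member of `initial`
#' by a time-respecting path of the realisation. It performs a
#' chronological sweep: a cure point removes its node from the infected
#' set, an arrow adds its target if its source is currently in the set (an
#' arrow into an already-infected target changes nothing, consistent with
#' the dynamics where infection only applies to susceptibles).
#'
#' `reachable_matrix()` performs one sweep that answers all single-source
#' queries at once: entry \eqn{(i, j)} is `TRUE` iff a path runs from
#' \eqn{(i, 0)} to \eqn{(j, t)}, so row `i` is
#' `reachable_set(real, i, t)` and \eqn{\xi^A_t} for any set is the union
#' of the rows of `A`.
#'
#' @param real A `sis_realisation`.
#' @param initial Initially infected nodes (any subset, empty allowed).
#' @param t Time in `[0, t_max]`.
#' @return `reachable_set()`: an integer vector of infected nodes;
#'   `reachable_matrix()`: an `n` by `n` logical matrix.
#' @export
reachable_set <- function(real, initial, t = real$t_max) {
  if (t > real$t_max || t < 0) abort("`t` must lie in [0, t_max].")
  infected <- rep(FALSE, real$n)
  infected[resolve_node_set(real$net, initial, allow_empty = TRUE)] <- TRUE
  ev <- merged_events(real, t)
  for (k in seq_len(nrow(ev))) {
    if (ev$kind[k] == 1L) {
      infected[ev$a[k]] <- FALSE
    } else if (infected[ev$a[k]]) {
      infected[ev$b[k]] <- TRUE
    }
  }
  which(infected)
}

#' @rdname reachable_set
#' @export
reachable_matrix <- function(real, t = real$t_max) {
  if (t > real$t_max || t < 0) abort("`t` must lie in [0, t_max].")
  reach <- diag(TRUE, real$n)   # reach[, j]: sources with a path to (j, now)
  ev <- merged_events(real, t)
  for (k in seq_len(nrow(ev))) {
    if (ev$kind[k] == 1L) {
      reach[, ev$a[k]] <- FALSE
    } else {
      reach[, ev$b[k]] <- reach[, ev$b[k]] | reach[, ev$a[k]]
    }
  }
  reach
}

#' Time reversal of a graphical realisation
#'
#' Turns the percolation diagram upside down about the horizon: a cure
#' point \eqn{(i, s)} becomes \eqn{(i, h - s)} and an arrow
#' \eqn{(i, j, s)} becomes \eqn{(j, i, h - s)}. The result is distributed
#' as a realisation for the transposed network -- the Poisson processes
#' are the same in reverse -- which is the coupling behind duality.
#' Reversing twice restores the original event multiset.
#'
#' When checking duality at an interior time `horizon < t_max`, the
#' realisation is first restricted to `(0, horizon]` and reversed about
#' `horizon`.
#'
#' @param real A `sis_realisation`.
#' @param horizon Reversal time (defaults to `t_max`); events after it are
#'   dropped.
#' @return A `sis_realisation` on the transposed network.
#' @export
reverse_realisation <- function(real, horizon = real$t_max) {
  if (horizon > real$t_max || horizon <= 0) {
    abort("`horizon` must lie in (0, t_max].")
  }
  cures <- real$cures[real$cures$time <= horizon, , drop = FALSE]
  arrows <- real$arrows[real$arrows$time <= horizon, , drop = FALSE]
  cures$time <- horizon - cures$time
  arrows <- tibble(from = arrows$to, to = arrows$from,
                   time = horizon - arrows$time, id = arrows$id)
  all_times <- c(cures$time, arrows$time)
  all_ids <- c(cures$id, arrows$id)
  # reversed order: later original events come first; original ids break ties
  ids <- rank(all_times, ties.method = "first")
  ord <- order(all_times, -all_ids)
  ids[ord] <- seq_along(ids)
  cures$id <- ids[seq_len(nrow(cures))]
  arrows$id <- if (nrow(arrows)) ids[nrow(cures) + seq_len(nrow(arrows))]
               else integer(0)
  structure(list(t_max = horizon, n = real$n,
                 cures = cures[order(cures$id), ],
                 arrows = arrows[order(arrows$id), ],
                 net = t(real$net)),
            class = "sis_realisation")
}

#' Per-realisation duality check
#'
#' For one sampled realisation, compares the forward indicator "some
#' member of `event_nodes` is reachable at `t` from `initial` at 0" with
#' the backward indicator computed on the time-reversed diagram: "some
#' member of `initial` is reachable at `t` from `event_nodes` at 0" on the
#' transposed network. Duality holds realisation by realisation -- the two
#' indicators are equal exactly, not merely in distribution.
#'
#' @param real A `sis_realisation`.
#' @param initial,event_nodes Nonempty node sets.
#' @param t Time in `(0, t_max]`.
#' @return A one-row tibble with logical columns `forward`, `backward`,
#'   `equal`.
#' @export
duality_check <- function(real, initial, event_nodes, t = real$t_max) {
  a <- resolve_node_set(real$net, initial)
  w <- resolve_node_set(real$net, event_nodes)
  forward <- length(intersect(reachable_set(real, a, t), w)) > 0
  rev <- reverse_realisation(real, horizon = t)
  backward <- length(intersect(reachable_set(rev, w, t), a)) > 0
  tibble(forward = forward, backward = backward,
         equal = forward == backward)
}
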