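test_that("simulate honours stopping rules, empty starts and reproducibility", {
  net <- complete_network(3, beta = 2)
  empty <- sis_simulate(net, integer(0))
  expect_equal(nrow(empty), 0)
  expect_true(attr(empty, "extinct"))
  expect_equal(attr(empty, "extinction_time"), 0)

  tr <- sis_simulate(net, initial = 1:3, max_events = 100, seed = 4)
  expect_true(nrow(tr) == 100 || attr(tr, "extinct"))
  expect_true(all(diff(tr$time) > 0))

  tr2 <- sis_simulate(net, initial = 1:3, max_events = 100, seed = 4)
  expect_identical(tr$time, tr2$time)
  expect_identical(tr$node, tr2$node)

  # event legality: infections hit susceptibles, recoveries hit infectious
  infected <- rep(FALSE, 3); infected[1:3] <- TRUE
  for (k in seq_len(nrow(tr))) {
    if (tr$event[k] == "infection") {
      expect_false(infected[tr$node[k]])
      infected[tr$node[k]] <- TRUE
    } else {
      expect_true(infected[tr$node[k]])
      infected[tr$node[k]] <- FALSE
    }
  }
  expect_setequal(which(infected), attr(tr, "final_infected"))
})

test_that("single-node extinction times are Exponential(1)", {
  n1 <- contact_network_from_matrix(matrix(0, 1, 1))
  tr <- sis_simulate(n1, 1, seed = 1)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$event, "recovery")

  res <- sisnet:::batch_run(n1, 1, n_reps = 10000, seed = 2)
  expect_true(all(res$extinct))
  m <- mean(res$extinction_time)
  se <- sd(res$extinction_time) / sqrt(10000)
  expect_within_3se(m, se, 1)
})

test_that("occupancy from a fabricated trace reproduces the time-average formula", {
  ev <- tibble::tibble(time = 0.5, event = "recovery", node = 1L)
  trace <- structure(ev, class = c("sis_trace", class(ev)),
                     initial = c(1L, 2L), extinct = FALSE,
                     extinction_time = NA_real_, end_time = 1.0,
                     final_infected = 2L, n_infections = 0, seed = 1)
  occ <- occupancy_from_trace(trace)
  expect_equal(occ$estimate, c(0.5, 1))
})

test_that("time-average marginals recover the exact QSD in a feasible regime", {
  # burn-in of 50 events (~10 time units) covers relaxation; extinction is
  # handled by pooled replicates
  net <- complete_network(3, beta = 5)
  est <- estimate_qsd_marginals(net, total_events = 5e5, burnin = 50, seed = 6)
  exact <- tidy(sis_qsd(net))$prevalence
  for (i in 1:3) expect_within_3se(est$estimate[i], est$se[i], exact[i])

  # long-lived system (expected lifetime ~3e6 events >> budget): effectively
  # the paper protocol of one long run with a fractional burn-in
  net6 <- complete_network(6, beta = 5)
  est6 <- estimate_qsd_marginals(net6, total_events = 4e5, burnin = 0.5,
                                 seed = 8)
  exact6 <- tidy(sis_qsd(net6))$prevalence
  expect_lte(attr(est6, "replicates"), 3)
  for (i in 1:6) expect_within_3se(est6$estimate[i], est6$se[i], exact6[i])
})

test_that("marginal estimator raises the practical-relevance diagnostic", {
  # a 2-node system cannot survive a 9e5-event burn-in
  expect_error(
    estimate_qsd_marginals(complete_network(2, beta = 1), total_events = 1e6,
                           burnin = 0.9, seed = 1, max_retries = 20),
    "practical relevance")
})

test_that("censored-fraction invasion estimate matches an exact first-passage oracle", {
  net <- complete_network(3, beta = 5)
  c_thr <- 30
  oracle <- first_passage_infections(net, 1, c_thr)
  est <- suppressWarnings(
    estimate_invasion_probability(net, 1, threshold = c_thr, n_reps = 5000,
                                  seed = 12))
  expect_within_3se(est$estimate, est$se, oracle)

  # no infection can ever occur on a single node
  n1 <- contact_network_from_matrix(matrix(0, 1, 1))
  est1 <- suppressWarnings(
    estimate_invasion_probability(n1, 1, threshold = 1, n_reps = 200, seed = 3))
  expect_equal(est1$estimate, 0)

  # seeded with everyone: P(at least one infection precedes extinction),
  # first-passage oracle with c = 1
  oracle_full <- first_passage_infections(net, 1:3, 1)
  est_full <- suppressWarnings(
    estimate_invasion_probability(net, 1:3, threshold = 1, n_reps = 5000,
                                  seed = 13))
  expect_within_3se(est_full$estimate, est_full$se, oracle_full)
})

test_that("infection-event histograms censor correctly and flag poor dichotomy", {
  n1 <- contact_network_from_matrix(matrix(0, 1, 1))
  h <- infection_event_histogram(n1, 1, max_infections = 10, n_reps = 100,
                                 seed = 1)
  expect_equal(h$count[h$infections == 0], 100)
  expect_equal(sum(h$count), 100)

  net <- complete_network(3, beta = 5)
  h1 <- infection_event_histogram(net, 1, max_infections = 1, n_reps = 500,
                                  seed = 2)
  expect_true(all(h1$infections %in% c(0, 1)))

  # beta = 5 on n = 3: persistence is not dichotomised at c = 300 and the
  # diagnostic must say so
  h300 <- infection_event_histogram(net, 1, max_infections = 300,
                                    n_reps = 1000, seed = 3)
  expect_false(attr(h300, "dichotomy_ok"))
  expect_warning(
    estimate_invasion_probability(net, 1, threshold = 300, n_reps = 500,
                                  seed = 4),
    "dichotomy")
})

test_that("empirical survival curves match the matrix-exponential oracle", {
  net <- lattice_network(2, 2, beta = 0.8)
  times <- c(0.5, 1, 2, 4)
  sc <- empirical_survival_curve(net, 1:4, times = times, n_reps = 20000,
                                 seed = 5)
  expect_true(all(diff(sc$survival) <= 0))
  exact <- vapply(times, function(s)
    transient_event_probability(net, 1:4, 1:4, s), numeric(1))
  for (k in seq_along(times)) {
    expect_within_3se(sc$survival[k], sc$se[k], exact[k])
  }
  sc0 <- empirical_survival_curve(net, 1, times = c(0, 1), n_reps = 500,
                                  seed = 6)
  expect_equal(sc0$survival[1], 1)

  n1 <- contact_network_from_matrix(matrix(0, 1, 1))
  s1 <- empirical_survival_curve(n1, 1, times = 1, n_reps = 20000, seed = 7)
  expect_within_3se(s1$survival, s1$se, exp(-1))
})

test_that("empirical survival ratio plateaus at the exact invasion probability", {
  net <- symmetrise(rand_net(3, seed = 21, recovery = rep(1, 3)))
  net <- scale_weights(net, 3)  # make invasion non-trivial
  q <- sis_qsd(net)
  tt <- 6
  num <- empirical_survival_curve(net, 1, times = tt, n_reps = 30000, seed = 31)
  den <- empirical_survival_curve(net, 1:3, times = tt, n_reps = 30000, seed = 32)
  ratio <- num$survival / den$survival
  se <- ratio * sqrt((num$se / num$survival)^2 + (den$se / den$survival)^2)
  expect_within_3se(ratio, se, invasion_probability_exact(q, 1))
})
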