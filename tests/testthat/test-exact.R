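root2 <- sqrt(2)

test_that("sub-generator matches direct enumeration of the master equation", {
  n1 <- contact_network_from_matrix(matrix(0, 1, 1))
  sub <- sis_subgenerator(n1)
  expect_equal(as.matrix(sub$Q), matrix(-1, 1, 1))
  expect_equal(sub$exit, 1)

  sym <- complete_network(2, beta = 1)
  sub <- sis_subgenerator(sym)
  expect_equal(as.matrix(sub$Q),
               matrix(c(-2, 0, 1, 0, -2, 1, 1, 1, -2), 3, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(sub$exit, c(1, 1, 0))

  asym <- contact_network(tibble::tibble(from = c(1, 2), to = c(2, 1),
                                         rate = c(2, 1)))
  sub <- sis_subgenerator(asym)
  expect_equal(as.matrix(sub$Q),
               matrix(c(-3, 0, 2, 0, -2, 1, 1, 1, -2), 3, byrow = TRUE),
               ignore_attr = TRUE)

  # row sums + exit = 0 on random networks
  for (s in 1:5) {
    sub <- sis_subgenerator(rand_net(5, seed = s))
    expect_lt(max(abs(Matrix::rowSums(sub$Q) + sub$exit)), 1e-12)
    singles <- 2^(0:4)
    expect_true(all(sub$exit[singles] > 0))
    expect_true(all(sub$exit[-singles] == 0))
  }

  chain <- contact_network(tibble::tibble(from = 1, to = 2, rate = 1), nodes = 2)
  expect_error(sis_subgenerator(chain), "strongly connected")
  expect_error(sis_subgenerator(complete_network(13, beta = 1)), "cap")
})

test_that("QSD triple matches the closed-form 2-node solution", {
  q1 <- sis_qsd(contact_network_from_matrix(matrix(0, 1, 1)))
  expect_equal(q1$nu, 1)
  expect_equal(q1$alpha, 1)
  expect_equal(q1$w, 1)

  q <- sis_qsd(complete_network(2, beta = 1))
  a <- 1 / (2 + root2)
  expect_equal(q$alpha, 2 - root2, tolerance = 1e-12)
  expect_equal(q$nu, c(a, a, root2 * a), tolerance = 1e-12)
  expect_equal(q$w, c(1 / root2, 1 / root2, 1), tolerance = 1e-12)
})

test_that("QSD invariants hold on random strongly connected networks", {
  for (s in 1:10) {
    n <- 2 + (s %% 5)
    q <- sis_qsd(rand_net(n, seed = 100 + s))
    m <- 2^n - 1
    Q <- sis_subgenerator(rand_net(n, seed = 100 + s))$Q
    expect_gt(q$alpha, 0)
    expect_true(all(q$nu > 0))
    expect_true(all(q$w > 0))
    expect_equal(sum(q$nu), 1, tolerance = 1e-12)
    expect_equal(q$w[m], 1)
    expect_gt(q$spectral_gap, 0)
    expect_lt(max(abs(as.numeric(Matrix::crossprod(Q, q$nu)) + q$alpha * q$nu)),
              1e-10)
    expect_lt(max(abs(as.numeric(Q %*% q$w) + q$alpha * q$w)), 1e-10)
  }
})

test_that("sparse and dense eigensolvers agree where both apply", {
  net <- rand_net(8, seed = 42)   # 255 states: dense path
  qd <- sis_qsd(net)
  sub <- sis_subgenerator(net)
  right <- sisnet:::sparse_dominant(sub$Q, 1e-10)
  left <- sisnet:::sparse_dominant(Matrix::t(sub$Q), 1e-10)
  expect_equal(-right$value, qd$alpha, tolerance = 1e-9)
  w <- sisnet:::positive_vector(right$vector, "w"); w <- w / w[length(w)]
  nu <- sisnet:::positive_vector(left$vector, "nu"); nu <- nu / sum(nu)
  expect_equal(w, qd$w, tolerance = 1e-8)
  expect_equal(nu, qd$nu, tolerance = 1e-8)
})

test_that("QSD event probability sums the right states", {
  q <- sis_qsd(complete_network(2, beta = 1))
  expect_equal(qsd_event_probability(q, 1:2), 1)
  expect_equal(qsd_event_probability(q, 1), root2 / 2, tolerance = 1e-12)
  q1 <- sis_qsd(contact_network_from_matrix(matrix(0, 1, 1)))
  expect_equal(qsd_event_probability(q1, 1), 1)
  expect_error(qsd_event_probability(q, integer(0)), "nonempty")
})

test_that("exact invasion probability is the invasion-vector entry", {
  q <- sis_qsd(complete_network(2, beta = 1))
  expect_equal(invasion_probability_exact(q, 1:2), 1)
  expect_equal(invasion_probability_exact(q, 1), root2 / 2, tolerance = 1e-12)
  q1 <- sis_qsd(contact_network_from_matrix(matrix(0, 1, 1)))
  expect_equal(invasion_probability_exact(q1, 1), 1)
  # invasion from the full set is certain on any network
  for (s in 1:5) {
    n <- 2 + s
    q <- sis_qsd(rand_net(n, seed = 200 + s))
    expect_equal(invasion_probability_exact(q, seq_len(n)), 1)
  }
})

test_that("transient event probabilities match a dense expm oracle", {
  net <- complete_network(2, beta = 1)
  expect_equal(transient_event_probability(net, 1, 1, 0), 1)
  n1 <- contact_network_from_matrix(matrix(0, 1, 1))
  for (s in c(0.3, 1, 2)) {
    expect_equal(transient_event_probability(n1, 1, 1, s), exp(-s),
                 tolerance = 1e-12)
  }
  for (s in 1:5) {
    net <- rand_net(4, seed = 300 + s)
    Q <- as.matrix(sis_subgenerator(net)$Q)
    for (t in c(0.5, 1.3)) {
      E <- as.matrix(Matrix::expm(Q * t))
      for (case in list(list(a = 1, w = 1:4), list(a = c(1, 3), w = 2))) {
        f <- numeric(15)
        f[sisnet:::states_meeting(case$w, 4)] <- 1
        oracle <- (E %*% f)[sisnet:::subset_to_state(case$a)]
        expect_equal(
          transient_event_probability(net, case$a, case$w, t), oracle,
          tolerance = 1e-10)
      }
    }
  }
  expect_error(transient_event_probability(net, 1, 1, -1))
})

test_that("finite-time duality: P(xi^A_t meets W) equals the transposed statement", {
  for (s in 1:8) {
    n <- 2 + (s %% 4)
    net <- rand_net(n, seed = 400 + s)
    tnet <- t(net)
    sets <- list(1, seq_len(n), sort(unique(c(1, n))))
    for (t in c(0.4, 1, 2.5)) {
      for (A in sets) for (W in sets) {
        expect_equal(transient_event_probability(net, A, W, t),
                     transient_event_probability(tnet, W, A, t),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("conditioned prevalence and survival ratio converge to the QSD limits", {
  net <- complete_network(2, beta = 1)
  expect_equal(conditioned_prevalence(net, 1, 0), 1)
  n1 <- contact_network_from_matrix(matrix(0, 1, 1))
  expect_equal(conditioned_prevalence(n1, 1, 3.7), 1)
  expect_equal(survival_ratio(n1, 1, 3.7), 1)
  expect_equal(survival_ratio(net, 1:2, 12.3), 1)

  expect_equal(conditioned_prevalence(net, 1, 50), root2 / 2, tolerance = 1e-6)
  expect_equal(survival_ratio(net, 1, 50), root2 / 2, tolerance = 1e-6)

  # limits on a directed random network against the spectral values
  net <- rand_net(4, seed = 11)
  q <- sis_qsd(net)
  expect_equal(survival_ratio(net, 2, 60), invasion_probability_exact(q, 2),
               tolerance = 1e-6)
  expect_equal(conditioned_prevalence(net, 2, 60), qsd_event_probability(q, 2),
               tolerance = 1e-6)
})
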