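test_that("calcium trace follows its closed form", {
  expect_equal(update_calcium(2, 0, dt_s = 3, tau_ca_s = 5, beta_ca = 0.2),
               2 * exp(-3 / 5))
  expect_equal(update_calcium(0, 1, dt_s = 1e-9, tau_ca_s = 5, beta_ca = 0.2),
               0.2, tolerance = 1e-6)
  tr <- calcium_trace(times = c(1, 2, 4), t_eval = 5, tau_ca_s = 2, beta_ca = 0.5)
  expect_equal(tr, 0.5 * sum(exp(-(5 - c(1, 2, 4)) / 2)))
})

test_that("engine calcium equals the closed-form trace of the recorded spikes", {
  cfg <- tiny_config(nu_ext_hz = 22000)
  net <- tiny_network(cfg)
  sim <- simulate_network(net, cfg, duration_s = 3, seed = 2,
                          record_spikes = TRUE, hsp = FALSE)
  for (i in c(1, 17, 80)) {
    ts <- sim$spikes$time_s[sim$spikes$id == i]
    expect_equal(sim$net$state$ca[i],
                 calcium_trace(ts, 3, cfg$tau_ca_s, cfg$beta_ca),
                 tolerance = 1e-8)
  }
})

test_that("stationary calcium mean equals beta * tau_ca * rate", {
  cfg <- tiny_config(nu_ext_hz = 22000)
  net <- tiny_network(cfg)
  # discard a transient of several tau_ca, then compare the population mean
  sim <- simulate_network(net, cfg, duration_s = 40, seed = 6,
                          record_spikes = TRUE, hsp = FALSE)
  n_E <- net$n_E
  late <- sim$spikes[sim$spikes$time_s > 30 & sim$spikes$id <= n_E, ]
  rate <- nrow(late) / (10 * n_E)
  expect_gt(rate, 1)
  expected <- cfg$beta_ca * cfg$tau_ca_s * rate
  sd_ca <- cfg$beta_ca * sqrt(rate * cfg$tau_ca_s / 2)
  expect_lt(abs(mean(sim$net$state$ca[seq_len(n_E)]) - expected),
            4 * sd_ca / sqrt(n_E))
})

test_that("the linear growth rule is homeostatic and clipped at zero", {
  # at the setpoint nothing changes
  expect_equal(grow_elements(5, ca = 8, nu_g = 2, eps = 8, dt_s = 0.1), 5)
  # silence -> maximal growth nu_g * dt
  expect_equal(grow_elements(5, ca = 0, nu_g = 2, eps = 8, dt_s = 0.1), 5.2)
  # twice the setpoint -> equal-magnitude shrinkage
  expect_equal(grow_elements(5, ca = 16, nu_g = 2, eps = 8, dt_s = 0.1), 4.8)
  # shrinkage cannot push counts below zero
  expect_equal(grow_elements(0.1, ca = 16, nu_g = 2, eps = 8, dt_s = 1), 0)
  # monotone under clamped calcium: strictly up below, strictly down above
  z <- 3
  for (k in 1:10) {
    z2 <- grow_elements(z, ca = 4, nu_g = 1, eps = 8, dt_s = 0.1)
    expect_gt(z2, z); z <- z2
  }
  for (k in 1:10) {
    z2 <- grow_elements(z, ca = 12, nu_g = 1, eps = 8, dt_s = 0.1)
    expect_lt(z2, z); z <- z2
  }
})

test_that("free elements pair into exactly min(free axons, free dendrites) synapses", {
  # neuron 1 holds two free axons; neurons 2 and 3 hold one free dendrite each
  A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(3, 3))
  res <- rewire(A, z_axon = c(2, 0, 0), z_dend = c(0, 1, 1), seed = 42)
  expect_equal(sum(res$A), 2)
  expect_equal(as.numeric(res$A[2, 1]), 1)
  expect_equal(as.numeric(res$A[3, 1]), 1)
  expect_equal(res$events$type, c("form", "form"))
})

test_that("self-pairings are skipped: no autapse can form", {
  A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(2, 2))
  for (seed in 1:20) {
    res <- rewire(A, z_axon = c(1, 0), z_dend = c(1, 0), seed = seed)
    expect_equal(sum(res$A), 0)
  }
  # with a valid partner present the free pair is still used up correctly
  res <- rewire(A, z_axon = c(1, 0), z_dend = c(1, 1), seed = 1)
  expect_equal(as.numeric(res$A[2, 1]), 1)
  expect_equal(sum(Matrix::diag(res$A)), 0)
})

test_that("deletion removes uniformly random synapses and frees the partner element", {
  # neuron 1 has 3 synapses onto 2, 3, 4 but capacity for only 2
  picks <- integer(0)
  for (seed in 1:300) {
    A <- Matrix::sparseMatrix(i = c(2, 3, 4), j = c(1, 1, 1), x = 1,
                              dims = c(4, 4))
    res <- rewire(A, z_axon = c(2, 0, 0, 0), z_dend = c(0, 1, 1, 1),
                  seed = seed)
    expect_equal(Matrix::colSums(res$A)[1], 2, ignore_attr = TRUE)
    del <- res$events[res$events$type == "delete", ]
    expect_equal(nrow(del), 1L)
    picks <- c(picks, del$post)
    # the orphaned dendritic element is free again (not rebound: no free axon)
    expect_equal(sum(res$A), 2)
  }
  freq <- tabulate(picks, 4)[2:4] / length(picks)
  expect_gt(stats::chisq.test(tabulate(picks, 4)[2:4])$p.value, 1e-4)
  expect_true(all(abs(freq - 1 / 3) < 0.1))
})

test_that("rewiring bookkeeping matches a brute-force ledger on tiny networks", {
  # independent R-side ledger: element capacities bound by floor(z), exact
  # conservation between the synapse multiset and its row/column sums
  set.seed(99)
  for (trial in 1:20) {
    n <- 5
    A <- Matrix::Matrix(matrix(rpois(n * n, 0.8), n, n), sparse = TRUE)
    Matrix::diag(A) <- 0
    z_a <- Matrix::colSums(A)
    z_d <- Matrix::rowSums(A)
    for (step in 1:10) {
      # scripted element trajectories (growth/shrinkage between rewirings)
      z_a <- pmax(0, z_a + runif(n, -1.5, 1.5))
      z_d <- pmax(0, z_d + runif(n, -1.5, 1.5))
      res <- rewire(A, z_a, z_d, seed = trial * 100 + step)
      A2 <- res$A
      bound_a <- Matrix::colSums(A2)
      bound_d <- Matrix::rowSums(A2)
      # capacity ceilings hold exactly after every step
      expect_true(all(bound_a <= floor(z_a) + 1e-9))
      expect_true(all(bound_d <= floor(z_d) + 1e-9))
      # no autapse ever
      expect_equal(sum(Matrix::diag(A2)), 0)
      # event log replays the transition exactly
      ev <- res$events
      dA <- Matrix::sparseMatrix(
        i = ev$post, j = ev$pre,
        x = ifelse(ev$type == "form", 1, -1), dims = c(n, n))
      expect_equal(as.matrix(A + dA), as.matrix(A2))
      # formation is exhaustive: afterwards one of the free pools is empty
      # (or only self-pairings remained)
      free_a <- floor(z_a) - bound_a
      free_d <- floor(z_d) - bound_d
      stranded <- sum(free_a) > 0 && sum(free_d) > 0
      if (stranded) {
        expect_true(length(unique(c(which(free_a > 0), which(free_d > 0)))) == 1)
      }
      A <- A2
    }
  }
})

test_that("element ledgers and synapse counts stay consistent through a live run", {
  cfg <- default_config("test", growth_s = 10)
  net <- suppressWarnings(grow_network(cfg, seed = 3))
  ba <- tabulate(net$ee_pre, nbins = net$n_E)
  bd <- tabulate(net$ee_post, nbins = net$n_E)
  # the run ends on a structural-update boundary, so capacities hold
  expect_true(all(ba <= floor(net$state$z_axon) + 1e-9))
  expect_true(all(bd <= floor(net$state$z_dend) + 1e-9))
  A <- connectivity_matrix(net)
  expect_equal(as.numeric(Matrix::colSums(A)), as.numeric(ba))
  expect_equal(as.numeric(Matrix::rowSums(A)), as.numeric(bd))
  expect_equal(sum(Matrix::diag(A)), 0)
})
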