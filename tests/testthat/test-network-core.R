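test_that("a silent network rests at the fixed point V = 0", {
  cfg <- tiny_config()
  net <- tiny_network(cfg)
  sim <- simulate_network(net, cfg, duration_s = 0.5, seed = 3,
                          record_spikes = TRUE, hsp = FALSE)
  expect_equal(sim$net$state$v_mv, rep(0, 125))
  expect_equal(nrow(sim$spikes), 0L)
})

test_that("a single presynaptic spike depolarizes the target by J after one delay", {
  cfg <- tiny_config()
  net <- tiny_network(cfg)
  net <- set_synapses(net, pre = 1L, post = 2L)
  net$state$v_mv[1] <- cfg$v_theta_mv + 1  # force one spike at the first step
  # run exactly delay + one step: the EPSP lands on the last step, so the
  # target potential equals J with no decay applied yet
  sim <- simulate_network(net, cfg, duration_s = (cfg$delay_ms + cfg$dt_ms) / 1e3,
                          seed = 3, record_spikes = TRUE, hsp = FALSE)
  expect_equal(sim$spikes$id, 1L)
  expect_equal(sim$spikes$time_s, cfg$dt_ms / 1e3)
  expect_equal(sim$net$state$v_mv[2], cfg$j_mv)
  # presynaptic neuron was reset and is refractory
  expect_equal(sim$net$state$v_mv[1], cfg$v_reset_mv)
  expect_gt(sim$net$state$ref_ms[1], 0)
})

test_that("DC drive settles at exactly delta_Vm on a threshold-free membrane", {
  cfg <- tiny_config()
  net <- tiny_network(cfg)
  for (dvm in c(0.6, -0.6, 2.8)) {
    seg <- make_dc_drive(dvm, mask = seq_len(125), start_s = 0, stop_s = 2)
    sim <- simulate_network(net, cfg, duration_s = 2, seed = 3,
                            segments = list(seg), thresholds = FALSE, hsp = FALSE)
    expect_equal(sim$net$state$v_mv, rep(dvm, 125), tolerance = 1e-6)
  }
})

test_that("zero-rate Poisson drive delivers no events; event counts match Poisson statistics", {
  cfg <- tiny_config(dt_ms = 0.2)
  net <- tiny_network(cfg)
  seg0 <- make_poisson_drive(0, 0.1, mask = 1:10, start_s = 0, duration_s = 1)
  sim0 <- simulate_network(net, cfg, duration_s = 1, seed = 5,
                           segments = list(seg0), hsp = FALSE, diagnostics = TRUE)
  expect_equal(sim0$seg_counts, 0)
  expect_error(make_poisson_drive(-10, 0.1, 1:10, 0, 1), "non-negative")

  # learning-strength drive: 1.5 kHz for 150 s -> mean count 225000/neuron
  seg <- make_poisson_drive(1500, 0.1, mask = 1:10, start_s = 0, duration_s = 150)
  sim <- simulate_network(net, cfg, duration_s = 150, seed = 5,
                          segments = list(seg), thresholds = FALSE, hsp = FALSE,
                          diagnostics = TRUE)
  mean_count <- sim$seg_counts / 10
  se <- sqrt(225000 / 10)
  expect_lt(abs(mean_count - 225000), 4 * se)
})

test_that("identical seeds reproduce runs bit-for-bit; different seeds do not", {
  cfg <- default_config("test", growth_s = 5)
  run <- function(seed) {
    net <- suppressWarnings(grow_network(cfg, seed = seed, record_spikes = TRUE))
    net
  }
  a <- run(11); b <- run(11); c <- run(12)
  expect_identical(a$meta$spikes, b$meta$spikes)
  expect_identical(a$ee_pre, b$ee_pre)
  expect_identical(a$ee_post, b$ee_post)
  expect_identical(a$state$v_mv, b$state$v_mv)
  expect_false(identical(a$meta$spikes, c$meta$spikes))
})

test_that("no neuron violates the absolute refractory period", {
  cfg <- tiny_config(nu_ext_hz = 25000)  # strong drive, high rates
  net <- tiny_network(cfg)
  sim <- simulate_network(net, cfg, duration_s = 2, seed = 9,
                          record_spikes = TRUE, hsp = FALSE)
  expect_gt(nrow(sim$spikes), 100)
  isi <- unlist(tapply(sim$spikes$time_s, sim$spikes$id, diff))
  expect_true(all(isi * 1000 >= cfg$t_ref_ms - 1e-9))
})

test_that("threshold-free stationary mean V equals the shot-noise mean nu*tau*J", {
  cfg <- tiny_config()
  net <- tiny_network(cfg)
  seg <- make_poisson_drive(800, 0.25, mask = seq_len(125), start_s = 0,
                            duration_s = 20)
  sim <- simulate_network(net, cfg, duration_s = 20, seed = 21,
                          segments = list(seg), thresholds = FALSE, hsp = FALSE)
  expected <- 800 * (cfg$tau_m_ms / 1000) * 0.25  # 2.0 mV
  expect_equal(mean(sim$net$state$v_mv), expected, tolerance = 0.05)
})

test_that("configuration errors are caught before reaching the engine", {
  expect_error(tiny_config(dt_ms = 2), "delay")
  cfg <- tiny_config()
  net <- tiny_network(cfg)
  bad <- make_dc_drive(0.2, mask = 999L, start_s = 0, stop_s = 1)
  expect_error(simulate_network(net, cfg, 0.5, segments = list(bad)),
               "invalid neuron id")
})

test_that("growth duration zero leaves the E-E matrix empty and activity far below setpoint", {
  cfg <- default_config("test", growth_s = 0)
  net <- grow_network(cfg, seed = 4)
  expect_length(net$ee_pre, 0)
  sim <- simulate_network(net, cfg, duration_s = 5, seed = 4, hsp = FALSE)
  rate <- mean(sim$win_counts[nrow(sim$win_counts), seq_len(net$n_E)]) /
    cfg$window_s
  expect_lt(rate, 0.75 * cfg$target_rate_hz)
})
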