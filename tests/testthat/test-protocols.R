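test_that("montage masks satisfy their invariants over random instances", {
  set.seed(31)
  for (k in 1:20) {
    n_E <- sample(100:400, 1)
    n_eng <- 2 * sample(5:20, 1)
    eng <- sample.int(n_E, n_eng)
    u <- build_montage("uniform", eng, n_E, seed = k)
    expect_setequal(u$dc_ids, seq_len(n_E))
    tg <- build_montage("targeted", eng, n_E, seed = k)
    expect_setequal(tg$dc_ids, eng)
    uf <- build_montage("unfocused", eng, n_E, seed = k)
    expect_length(uf$dc_ids, n_eng)
    expect_length(intersect(uf$dc_ids, eng), n_eng / 2)
    expect_length(setdiff(uf$dc_ids, eng), n_eng / 2)
    expect_equal(anyDuplicated(uf$dc_ids), 0L)
  }
  expect_error(build_montage("ring", 1:10, 100), "arg")
  expect_error(build_montage("targeted", integer(0), 100), "non-empty")
})

test_that("schedules tile the protocol phases with zero gaps", {
  cfg <- default_config("paper")
  eng <- seq_len(1000)
  m <- build_montage("targeted", eng, 10000)
  before <- experiment_plan(cfg, "before", delta_vm_mv = 0.4)
  expect_equal(before$dc_window, c(750, 900))
  expect_equal(before$learn_window, c(900, 1050))
  expect_equal(before$t_end_s, 1200)
  during <- experiment_plan(cfg, "during", delta_vm_mv = 0.4)
  expect_equal(during$dc_window, during$learn_window)
  expect_equal(during$dc_window, c(750, 900))
  after <- experiment_plan(cfg, "after", delta_vm_mv = 0.4)
  expect_equal(after$learn_window, c(750, 900))
  expect_equal(after$dc_window, c(900, 1050))
  none <- experiment_plan(cfg, "none")
  expect_null(none$dc_window)
  segs <- build_schedule(after, m)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$type, "poisson")
  expect_equal(segs[[1]]$rate_hz, 1500)
  expect_equal(segs[[1]]$weight_mv, 0.1)
  expect_equal(segs[[2]]$type, "dc")
  expect_setequal(segs[[2]]$mask, eng)
  # phase windows are each 150 s and disjoint for before/after
  expect_equal(diff(after$learn_window), 150, ignore_attr = TRUE)
  expect_equal(diff(after$dc_window), 150, ignore_attr = TRUE)
  expect_lte(after$learn_window[2], after$dc_window[1])
  expect_error(experiment_plan(cfg, "none", snapshot_s = 10), "before the end")
})

test_that("DC amplitudes outside the weak range need the strong-stimulation flag", {
  cfg <- default_config("paper")
  expect_error(experiment_plan(cfg, "during", delta_vm_mv = 0.7), "allow_strong")
  cfg$allow_strong <- TRUE
  plan <- experiment_plan(cfg, "during", delta_vm_mv = 2.8)
  expect_equal(plan$delta_vm_mv, 2.8)
  plan2 <- experiment_plan(cfg, "during", delta_vm_mv = -2.8)
  expect_equal(plan2$delta_vm_mv, -2.8)
})

test_that("zero-amplitude DC reproduces the control run bit-for-bit", {
  cfg <- default_config("test", growth_s = 5, learn_s = 5, dc_s = 5,
                        relax_end_s = 20)
  net <- suppressWarnings(grow_network(cfg, seed = 2))
  sz <- config_sizes(cfg)
  eng <- seq_len(sz$n_engram)
  snap <- c(10, 20)
  m0 <- build_montage("none", eng, sz$n_E)
  mu <- build_montage("uniform", eng, sz$n_E)
  ctl <- run_experiment(net, cfg,
                        experiment_plan(cfg, "none", snapshot_s = snap),
                        m0, seed = 77)
  dc0 <- run_experiment(net, cfg,
                        experiment_plan(cfg, "during", delta_vm_mv = 0,
                                        snapshot_s = snap),
                        mu, seed = 77)
  expect_identical(ctl$net$ee_pre, dc0$net$ee_pre)
  expect_identical(ctl$net$ee_post, dc0$net$ee_post)
  expect_identical(ctl$net$state$v_mv, dc0$net$state$v_mv)
  expect_equal(final_gamma(ctl), final_gamma(dc0))
})

test_that("run_experiment rejects a network whose clock mismatches the plan", {
  cfg <- default_config("test", growth_s = 5)
  net <- suppressWarnings(grow_network(cfg, seed = 2))
  cfg2 <- default_config("test", growth_s = 10)
  plan <- experiment_plan(cfg2, "none")
  m <- build_montage("none", 1:50, net$n_E)
  expect_error(run_experiment(net, cfg2, plan, m), "does not match")
})

test_that("sweep output has one labelled row per grid point per seed", {
  cfg <- default_config("test", growth_s = 5, learn_s = 5, dc_s = 5,
                        relax_end_s = 20)
  grid <- data.frame(montage = c("none", "targeted"),
                     timing = c("none", "during"),
                     delta_vm_mv = c(0, 0.4))
  sw <- suppressWarnings(run_sweep(cfg, grid, seeds = 1:2))
  expect_equal(nrow(sw), 4L)
  expect_setequal(names(sw),
                  c("montage", "timing", "delta_vm_mv", "seed", "gamma_engram",
                    "gamma_overlap", "gamma_nonoverlap", "gamma_network",
                    "rate_engram_final_hz"))
  expect_true(all(is.finite(sw$gamma_engram)))
  # unfocused montage populates the overlap/non-overlap readouts
  grid2 <- data.frame(montage = "unfocused", timing = "during",
                      delta_vm_mv = 0.2)
  sw2 <- suppressWarnings(run_sweep(cfg, grid2, seeds = 1))
  expect_true(is.finite(sw2$gamma_overlap) && is.finite(sw2$gamma_nonoverlap))
})
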