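test_that("steady-state detection applies the 1% / 5% fluctuation thresholds", {
  ctl <- sim_control(ma_window = 200, ss_window = 200)
  n <- 1200
  expect_true(steady_state_reached(rep(100, n), rep(50, n), ctl))
  # slow +-20% swings in the group count survive the moving average and
  # breach the 5% band: not steady
  swing20 <- 50 * (1 + 0.2 * sin(2 * pi * seq_len(n) / 600))
  expect_false(steady_state_reached(rep(100, n), swing20, ctl))
  # +-10% swings breach the tighter 1% wild-type band
  swing10 <- 100 * (1 + 0.1 * sin(2 * pi * seq_len(n) / 600))
  expect_false(steady_state_reached(swing10, rep(50, n), ctl))
  # fewer samples than one moving-average + evaluation window: not evaluable
  expect_false(steady_state_reached(rep(100, 300), rep(50, 300), ctl))
})

test_that("runs are reproducible from a single seed", {
  p <- base_params(m = 1, mu = 0.02, k_cells = 40, k_total = 3000, b0 = 0.01)
  st <- frag_strategy(0.1, 0.8)
  s1 <- simulate_community(p, st, n_groups = 10, t_max = 150, seed = 99,
                           control = quick_control())
  s2 <- simulate_community(p, st, n_groups = 10, t_max = 150, seed = 99,
                           control = quick_control())
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$final, s2$final)
})

test_that("event tallies reconcile the cell ledger exactly", {
  cfgs <- list(
    list(p = base_params(m = 1, mu = 0.05, k_cells = 40, k_total = 4000,
                         b0 = 0.02), st = frag_strategy(0.1, 0.8)),
    list(p = base_params(m = 2, mu = 0.02, k_cells = 40, k_total = 4000,
                         b0 = 0.01, sigma = 0.5, nu = 0.02),
         st = frag_strategy(0.3, 0.6)),
    list(p = base_params(m = 2, mu = 0.1, k_cells = 30, k_total = 2000,
                         b0 = 0.01, nu = 0.05), st = frag_strategy(0.5, 0.5)))
  for (k in seq_along(cfgs)) {
    p <- cfgs[[k]]$p
    sim <- simulate_community(p, cfgs[[k]]$st, n_groups = 8, t_max = 400,
                              seed = 20 + k, control = quick_control())
    ev <- sim$events
    init_cells <- 8 * sum(init_community(p, 1)$groups[[1]])
    final_cells <- sum(vapply(sim$final, sum, numeric(1)))
    expect_identical(
      final_cells,
      init_cells + ev[["birth_wt"]] + ev[["birth_mut"]] - ev[["death"]] -
        ev[["extinction_cells"]])
  }
})

test_that("an isolated group fluctuates around the mean-field equilibrium", {
  p <- base_params(m = 1, mu = 0, b0 = 0, sigma = 0, k_total = Inf, nu = 0)
  sim <- simulate_community(p, frag_strategy(0.5, 0.5), n_groups = 1,
                            t_max = 1200, seed = 5,
                            control = quick_control(chunk = 400))
  ns <- sim$trajectory$n_cells[sim$trajectory$time > 100]
  se <- fragmodes:::batch_means_se(ns, 20)
  expect_lt(abs(mean(ns) - single_group_stationary_mean(0.1, 100)),
            3 * se + 1e-9)
})

test_that("the constant-death variant forces fission at the carrying capacity", {
  p <- base_params(m = 1, mu = 0, k_cells = 30, k_total = 5000, b0 = 0.005,
                   death_variant = "constant_with_forced_fission")
  sim <- simulate_community(p, frag_strategy(0.5, 0.5), n_groups = 5,
                            t_max = 300, seed = 8, control = quick_control())
  expect_gt(sim$events[["forced_fission"]], 0)
  expect_true(all(vapply(sim$final, sum, numeric(1)) < 30))
})

test_that("migration moves cells without changing the community census", {
  p <- base_params(m = 2, mu = 0, k_cells = 40, b0 = 0, sigma = 0,
                   k_total = Inf, nu = 0.05)
  sim <- simulate_community(p, frag_strategy(0.5, 0.5), n_groups = 6,
                            t_max = 200, seed = 12, control = quick_control())
  ev <- sim$events
  expect_gt(ev[["migration"]], 0)
  expect_identical(ev[["fission"]] + ev[["extinction"]], 0)
  init_cells <- 6 * 20
  final_cells <- sum(vapply(sim$final, sum, numeric(1)))
  expect_identical(final_cells,
                   init_cells + ev[["birth_wt"]] + ev[["birth_mut"]] -
                     ev[["death"]])
})

test_that("communities without wild-type rescue melt down to extinction", {
  p <- base_params(m = 1, mu = 0.3, k_cells = 30, b0 = 0, sigma = 0,
                   k_total = Inf)
  sim <- simulate_community(p, frag_strategy(0.5, 0.5), n_groups = 5,
                            t_max = 5000, seed = 1, control = quick_control())
  expect_equal(sim$termination, "extinct")
  expect_length(sim$final, 0)
})

test_that("group size is near-invariant to species number under the normalization", {
  exact <- single_group_stationary_mean(0.1, 100)
  means <- vapply(c(1, 2, 3), function(m) {
    p <- base_params(m = m, mu = 0, b0 = 0, sigma = 0, k_total = Inf)
    sim <- simulate_community(p, frag_strategy(0.5, 0.5), n_groups = 1,
                              t_max = 800, seed = 30 + m,
                              control = quick_control(chunk = 400))
    mean(sim$trajectory$n_cells[sim$trajectory$time > 100])
  }, numeric(1))
  expect_true(all(abs(means - exact) < 6))
})
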