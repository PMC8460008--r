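test_that("the mutation-rate schedule is geometric and descending", {
  s <- mu_schedule()
  expect_equal(s[1], 1)
  expect_true(all(diff(log10(s)) < 0))
  expect_equal(log10(s[2]) - log10(s[1]), -0.25)
  expect_equal(min(s), 1e-4)
  s2 <- mu_schedule(1, 1e-3, 10^(-0.5))
  expect_equal(length(s2), 7)
})

test_that("nearest-neighbour averaging uses admissible von-Neumann neighbours only", {
  g <- strategy_grid(seq(0.1, 0.5, by = 0.1), seq(0.1, 0.9, by = 0.1))
  g$value <- 1
  sm <- neighbour_average(g, "value")
  expect_equal(sm$value, rep(1, nrow(g)))  # constant field unchanged
  # single hot point spreads only to its grid neighbours
  g$value <- ifelse(g$s == 0.2 & g$n == 0.5, 5, 0)
  sm <- neighbour_average(g, "value")
  hot <- sm$s == 0.2 & sm$n == 0.5
  # interior point with 4 admissible neighbours: mean of itself + 4 zeros
  expect_equal(sm$value[hot], 1)
  # the binary-fission corner has fewer neighbours
  corner <- g$s == 0.5 & g$n == 0.5
  g$value <- ifelse(corner, 3, 0)
  sm <- neighbour_average(g, "value")
  nb_count <- sum(sm$value > 0) - 1
  expect_lte(nb_count, 2)
  expect_equal(sm$value[corner], 3 / (1 + nb_count))
})

test_that("strategy scans flag invalid points and reproduce bit-for-bit", {
  grid <- tibble::tibble(s = c(0.1, 0.3), n = c(0.8, 0.2))  # second invalid
  p <- base_params(m = 1, mu = 0, k_cells = 30, k_total = 2000, b0 = 0.02)
  r1 <- strategy_scan(grid, p, replicates = 2, n_groups = 5, t_max = 120,
                      control = quick_control(), seed = 5)
  r2 <- strategy_scan(grid, p, replicates = 2, n_groups = 5, t_max = 120,
                      control = quick_control(), seed = 5)
  expect_identical(r1, r2)
  expect_equal(sum(r1$valid, na.rm = TRUE), 2)  # 1 valid strategy x 2 reps
  expect_true(all(r1$termination[!r1$valid] == "not_run"))
  expect_equal(nrow(r1), 3)
})

test_that("the maximum-mutation-rate protocol reports the descending-schedule threshold", {
  p <- base_params(m = 1, k_cells = 30, k_total = 20000, b0 = 0.02)
  st <- frag_strategy(1 / 30, 1 - 1 / 30)
  r <- max_mutation_rate(st, p, replicates = 2,
                         schedule = c(0.5, 0.05, 0.005, 5e-4),
                         n_groups = 10, t_max = 700,
                         control = quick_control(), seed = 3)
  expect_equal(nrow(r$replicates), 2)
  ok <- !is.na(r$replicates$mu_max)
  expect_true(any(ok))
  # the reported value is the first persistent entry of the schedule
  expect_true(all(r$replicates$mu_max[ok] %in% c(0.5, 0.05, 0.005, 5e-4)))
  expect_equal(r$mean_log10_mu_max, mean(log10(r$replicates$mu_max)))
})

test_that("a schedule whose top rate is sustainable raises the ceiling flag", {
  p <- base_params(m = 1, k_cells = 30, k_total = 20000, b0 = 0.02)
  st <- frag_strategy(1 / 30, 1 - 1 / 30)
  r <- max_mutation_rate(st, p, replicates = 1, schedule = c(1e-3, 1e-4),
                         n_groups = 10, t_max = 700,
                         control = quick_control(), seed = 4)
  if (!is.na(r$replicates$mu_max[1]) && r$replicates$mu_max[1] == 1e-3)
    expect_equal(r$replicates$status[1], "ceiling")
})

test_that("a sweep at the baseline axis value reduces to the plain protocol", {
  p <- base_params(m = 1, k_cells = 30, k_total = 20000, b0 = 0.02)
  strat <- tibble::tibble(s = 1 / 30, n = 1 - 1 / 30)
  sw <- sensitivity_sweep("sigma", values = 0, strategies = strat, params = p,
                          replicates = 2, schedule = c(0.05, 0.005),
                          n_groups = 10, t_max = 700,
                          control = quick_control(), seed = 7)
  direct <- max_mutation_rate(frag_strategy(strat$s, strat$n), p,
                              replicates = 2, schedule = c(0.05, 0.005),
                              n_groups = 10, t_max = 700,
                              control = quick_control(),
                              seed = 7 + 10000L + 100L)
  expect_equal(sw$mu_max, direct$replicates$mu_max)
  expect_equal(sw$status, direct$replicates$status)
})
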