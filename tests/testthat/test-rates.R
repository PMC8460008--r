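test_that("mutant birth rate follows the cross-feeding product rule", {
  p1 <- sim_params(m = 1)
  expect_equal(mutant_birth_rate(group_census(wt = 50, mut = 50), 1, p1), 0.5)

  p2 <- sim_params(m = 2)
  g2 <- group_census(wt = c(50, 50))
  expect_identical(mutant_birth_rate(g2, 1, p2), 1)

  # growth requires cooperating partners of every other species
  p3 <- sim_params(m = 3)
  g3 <- group_census(wt = c(10, 0, 10), mut = c(0, 5, 0))
  expect_identical(mutant_birth_rate(g3, 1, p3), 0)
  # ... but not conspecific cooperators when m > 1
  expect_gt(mutant_birth_rate(g3, 2, p3), 0)

  expect_error(mutant_birth_rate(group_census(wt = 0), 1, p1), "non-empty")
})

test_that("wild-type birth rate pays the cost of cooperation", {
  g <- group_census(wt = c(50, 50))
  expect_equal(wildtype_birth_rate(g, 1, sim_params(m = 2, gamma = 0)),
               mutant_birth_rate(g, 1, sim_params(m = 2, gamma = 0)))
  expect_equal(wildtype_birth_rate(g, 1, sim_params(m = 2, gamma = 0.1)), 0.9)
  g0 <- group_census(wt = c(0, 0), mut = c(5, 5))
  expect_equal(wildtype_birth_rate(g0, 1, sim_params(m = 2, gamma = 0.5)), 0)
})

test_that("death, fission, extinction and migration rates match their forms", {
  p <- sim_params(k_cells = 100, b0 = 0.01, sigma = 0, k_total = 10000,
                  nu = 0.01)
  expect_equal(death_rate(group_census(wt = 100), p), 1)
  expect_equal(death_rate(group_census(wt = 1), p), 0.01)
  pc <- sim_params(k_cells = 100,
                   death_variant = "constant_with_forced_fission")
  expect_equal(death_rate(group_census(wt = 37), pc), 0.01)

  expect_equal(fission_rate(group_census(wt = 55), p), 0.01)
  p2 <- sim_params(k_cells = 100, b0 = 0, sigma = 1)
  expect_equal(fission_rate(group_census(wt = 50), p2), 0.5)
  p3 <- sim_params(k_cells = 100, b0 = 0.01, sigma = 2)
  expect_equal(fission_rate(group_census(wt = 100), p3), 2.01)

  expect_equal(extinction_rate(10000, p), 1)
  expect_equal(extinction_rate(0, p), 0)
  expect_equal(extinction_rate(5000, sim_params(k_total = 30000)), 1 / 6)
  expect_equal(extinction_rate(5000, sim_params(k_total = Inf)), 0)

  expect_equal(migration_rate(group_census(wt = 80), p, n_groups = 2), 0.8)
  expect_equal(migration_rate(group_census(wt = 80), sim_params(nu = 0)), 0)
  # no destination: a lone group has a silent migration channel
  expect_equal(migration_rate(group_census(wt = 80), p, n_groups = 1), 0)
})

test_that("the m^(m-1) normalization gives a symmetric all-cooperator rate of exactly 1", {
  for (m in 1:5) {
    p <- sim_params(m = m, k_cells = 2 * m * 10)
    g <- group_census(wt = rep(10, m))
    expect_identical(mutant_birth_rate(g, 1, p), 1)
  }
})

test_that("mutants always outgrow conspecific wild-type cells when cooperation is costly", {
  for (seed in 1:20) {
    gs <- random_groups(m = 3, n_groups = 1, seed = seed)[[1]]
    p <- sim_params(m = 3, gamma = 0.2)
    for (j in 1:3) {
      bm <- mutant_birth_rate(gs, j, p)
      if (bm > 0) expect_lt(wildtype_birth_rate(gs, j, p), bm)
    }
  }
})

test_that("R-level rate table and the compiled engine's rates agree exactly", {
  for (m in c(1, 2, 3)) {
    groups <- random_groups(m, n_groups = 8, seed = 40 + m)
    for (variant in c("density_dependent", "constant_with_forced_fission")) {
      p <- sim_params(m = m, gamma = 0.13, k_cells = 77, b0 = 0.02,
                      sigma = 0.7, k_total = 5000, nu = 0.015,
                      death_variant = variant)
      r_tbl <- event_rate_table(groups, p)
      c_tbl <- fragmodes:::rate_table_cpp(flatten_groups(groups),
                                          fragmodes:::params_for_engine(p), 1L)
      for (col in c("birth_wt", "birth_mut", "death", "migration",
                    "fission", "total")) {
        expect_identical(r_tbl[[col]], unname(c_tbl[, col]),
                         label = sprintf("%s (m=%d, %s)", col, m, variant))
      }
    }
  }
})

test_that("all rates are non-negative on arbitrary valid states", {
  for (seed in 1:10) {
    groups <- random_groups(m = 2, n_groups = 5, seed = seed)
    p <- sim_params(m = 2, gamma = 0.3, nu = 0.02, sigma = 0.5)
    tbl <- event_rate_table(groups, p)
    expect_true(all(as.matrix(tbl) >= 0))
  }
})
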