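test_that("the strategy triangle is closed and its corners are admissible", {
  expect_true(strategy_valid(0.5, 0.5))    # binary fission
  expect_true(strategy_valid(0.01, 0.01))  # single-cell reproduction
  expect_true(strategy_valid(0.01, 0.99))  # complete fragmentation
  expect_false(strategy_valid(0.3, 0.2))   # lower triangle: impossible
  expect_false(strategy_valid(0.2, 0.9))   # above the upper diagonal
  expect_false(strategy_valid(0.6, 0.7))   # s beyond 1/2
  expect_false(strategy_valid(0, 0.5))     # open at zero
  expect_error(frag_strategy(0.3, 0.2), "invalid")
})

test_that("strategy grids keep only admissible points unless asked otherwise", {
  g <- strategy_grid(seq(0.1, 0.5, by = 0.1), seq(0.1, 0.9, by = 0.2))
  expect_true(all(strategy_valid(g$s, g$n)))
  gk <- strategy_grid(seq(0.1, 0.5, by = 0.1), seq(0.1, 0.9, by = 0.2),
                      keep_invalid = TRUE)
  expect_true(any(!gk$valid))
  expect_equal(nrow(dplyr::filter(gk, valid)), nrow(g))
})

test_that("the upper transect runs from complete fragmentation to binary fission", {
  tr <- upper_transect(6, s_min = 0.02)
  expect_equal(nrow(tr), 6)
  expect_equal(tr$n, 1 - tr$s)
  expect_true(all(strategy_valid(tr$s, tr$n)))
  expect_equal(tr$s[6], 0.5)
})

test_that("archetypes sit at the corners of the triangle", {
  a <- strategy_archetypes(group_size = 100)
  expect_true(all(strategy_valid(a$s, a$n)))
  expect_equal(a$s[a$archetype == "binary_fission"], 0.5)
  expect_equal(a$n[a$archetype == "complete_fragmentation"], 0.99)
})
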