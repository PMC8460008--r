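test_that("the default trait grid covers the closed triangle including all archetypes", {
  g <- trait_grid()
  expect_true(all(g$bins$s <= g$bins$n + 1e-9))
  expect_true(all(g$bins$n <= 1 - g$bins$s + 1e-9))
  # archetype corners are representable
  expect_true(any(g$bins$s > 0.45 & abs(g$bins$n - 0.5) < 0.05))  # binary fission
  expect_true(any(g$bins$s < 0.05 & g$bins$n > 0.95))             # complete frag
  expect_true(any(g$bins$s < 0.05 & g$bins$n < 0.05))             # single cell
  # every admissible bin has at least one admissible neighbour
  self_moves <- rowSums(g$moves != g$bins$bin)
  expect_true(all(self_moves >= 1))
  # all mutation targets are admissible bins
  expect_true(all(g$moves >= 1 & g$moves <= nrow(g$bins)))
})

test_that("trait mutation is adjacent-bin with boundary projection along n", {
  g <- trait_grid()
  set.seed(1)
  # no mutation: identity
  for (b in sample(nrow(g$bins), 10))
    expect_identical(mutate_trait(b, 0, 0, g), b)
  # an s-only mutation from an interior bin moves exactly one s-step
  interior <- which(g$bins$s > 0.1 & g$bins$n > g$bins$s + 0.1 &
                      g$bins$n < 1 - g$bins$s - 0.1)
  b <- interior[1]
  for (i in 1:20) {
    b2 <- mutate_trait(b, 1, 0, g)
    expect_equal(abs(g$bins$is[b2] - g$bins$is[b]), 1)
    expect_equal(g$bins$in_[b2], g$bins$in_[b])
  }
  # a bin on the upper boundary pushed further up stays on the boundary
  upper <- which(abs(g$bins$n - (1 - g$bins$s)) < 0.026)
  for (b in upper) {
    tgt <- g$moves[b, "n_up"]
    expect_true(g$bins$n[tgt] <= 1 - g$bins$s[tgt] + 1e-9)
  }
})

test_that("the group strategy is the cell-count-weighted mean trait", {
  g <- trait_grid()
  b1 <- nearest_bin(g, 0.125, 0.225)
  b2 <- nearest_bin(g, 0.125, 0.775)
  counts <- numeric(nrow(g$bins))
  counts[b1] <- 5
  st <- group_mean_strategy(counts, g)
  expect_equal(st$s, g$bins$s[b1])
  expect_equal(st$n, g$bins$n[b1])
  counts[b2] <- 5
  st <- group_mean_strategy(counts, g)
  expect_equal(st$n, (g$bins$n[b1] + g$bins$n[b2]) / 2)
  # 3 cells at n = 0.225, 1 cell at n = 0.625: mean n = 0.325
  b3 <- nearest_bin(g, 0.125, 0.625)
  counts <- numeric(nrow(g$bins))
  counts[b1] <- 3
  counts[b3] <- 1
  expect_equal(group_mean_strategy(counts, g)$n, 0.325)
})

test_that("without trait mutation the population stays monomorphic", {
  p <- base_params(m = 1, mu = 0, k_cells = 40, k_total = 3000, b0 = 0.01,
                   mu_s = 0, mu_n = 0)
  evo <- simulate_evolution(p, trait_grid(), frag_strategy(0.325, 0.625),
                            n_groups = 10, t_end = 200, snapshot_every = 100,
                            seed = 2)
  per_time <- dplyr::count(evo$snapshots, time)
  expect_true(all(per_time$n == 1))
  expect_equal(unique(evo$snapshots$s), 0.325)
  expect_equal(unique(evo$snapshots$n), 0.625)
})

test_that("trait censuses survive fragmentation and migration intact", {
  p <- base_params(m = 1, mu = 0, k_cells = 40, k_total = 3000, b0 = 0.05,
                   nu = 0.05, mu_s = 0.05, mu_n = 0.05)
  evo <- simulate_evolution(p, trait_grid(), frag_strategy(0.3, 0.6),
                            n_groups = 10, t_end = 300, snapshot_every = 300,
                            seed = 3)
  ev <- evo$events
  # ledger: births - deaths - extinctions reconcile the final census
  final_cells <- sum(vapply(evo$final, sum, numeric(1)))
  expect_identical(final_cells,
                   10 * 20 + ev[["birth_wt"]] + ev[["birth_mut"]] -
                     ev[["death"]] - ev[["extinction_cells"]])
})
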