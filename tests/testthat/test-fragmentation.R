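test_that("forced draws reproduce the printed partition arithmetic", {
  set.seed(1)
  st <- frag_strategy(0.3, 0.7)
  # one offspring of 5, parent keeps 5
  fr <- fragment_group(c(a = 10), st, force_n_offspring = 5,
                       force_s_offspring = 5)
  expect_equal(fr$g_offspring, 1)
  expect_equal(sum(fr$offspring[[1]]), 5)
  expect_equal(sum(fr$parent), 5)
  # ceil(7 / 3) = 3 offspring of sizes 3, 3, 1
  fr <- fragment_group(c(a = 10), st, force_n_offspring = 7,
                       force_s_offspring = 3)
  expect_equal(fr$g_offspring, 3)
  expect_equal(vapply(fr$offspring, sum, integer(1)), c(3L, 3L, 1L))
  # all cells transmitted: the last group is relabelled as the parent
  fr <- fragment_group(c(a = 4), st, force_n_offspring = 4,
                       force_s_offspring = 1)
  expect_true(fr$parent_relabelled)
  expect_equal(sum(fr$parent), 1)
  expect_equal(length(fr$offspring), 3)
  expect_equal(sum(fr$parent) + sum(vapply(fr$offspring, sum, integer(1))), 4)
})

test_that("fragmentation conserves every census category exactly", {
  set.seed(7)
  for (i in 1:50) {
    census <- rpois(6, 3)
    if (sum(census) == 0) census[1] <- 1
    s <- runif(1, 0.05, 0.45)
    st <- frag_strategy(s, runif(1, s, 1 - s))
    fr <- fragment_group(census, st)
    back <- fr$parent
    for (o in fr$offspring) back <- back + o
    expect_identical(as.integer(back), as.integer(census))
    expect_true(all(vapply(fr$offspring, sum, integer(1)) > 0))
    expect_gt(sum(fr$parent), 0)
  }
})

test_that("cell sampling without replacement is exhaustive and conservative", {
  set.seed(3)
  expect_equal(sample_census(c(A = 3), 3), c(A = 3L))
  for (i in 1:20) {
    census <- c(wt = 5L, mut = 3L, other = 2L)
    k <- sample(0:10, 1)
    d <- sample_census(census, k)
    expect_equal(sum(d), k)
    expect_true(all(d >= 0 & d <= census))
  }
})

test_that("binary fission splits odd groups into near-halves (modal outcome)", {
  set.seed(11)
  st <- frag_strategy(0.5, 0.5)
  shapes <- replicate(3000, {
    fr <- fragment_group(c(a = 11), st)
    paste(sort(c(sum(fr$parent), vapply(fr$offspring, sum, integer(1)))),
          collapse = ",")
  })
  mode_shape <- names(sort(table(shapes), decreasing = TRUE))[1]
  expect_equal(mode_shape, "5,6")
})

test_that("archetype corners behave as named", {
  set.seed(13)
  # single-cell reproduction: modal outcome is one 1-cell offspring
  st1 <- frag_strategy(1 / 20, 1 / 20)
  g1 <- replicate(2000, {
    fr <- fragment_group(c(a = 20), st1)
    length(fr$offspring) == 1 && sum(fr$offspring[[1]]) == 1
  })
  expect_gt(mean(g1), 0.5)
  # complete fragmentation: offspring are typically all singletons and
  # nearly the whole parent disperses
  st2 <- frag_strategy(1 / 20, 1 - 1 / 20)
  draws <- t(replicate(2000, {
    fr <- fragment_group(c(a = 20), st2)
    sizes <- vapply(fr$offspring, sum, integer(1))
    c(all_singletons = all(sizes == 1), transmitted = sum(sizes))
  }))
  expect_gt(mean(draws[, "all_singletons"]), 0.5)
  expect_gte(stats::median(draws[, "transmitted"]), 17)
})
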