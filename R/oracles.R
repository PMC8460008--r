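#' Mean-field equilibrium group size
#'
#' In a symmetric all-wild-type group with no group-level events and no
#' mutation, the per-capita birth rate is `(1 - gamma)` (the `m^(m-1)`
#' normalization makes the all-cooperator symmetric rate 1 for every `m`)
#' and the per-capita death rate is `N / k_cells`, so birth balances death
#' at `N* = (1 - gamma) * k_cells`, independent of the number of species.
#'
#' @param gamma Cost of cooperation.
#' @param k_cells Within-group carrying capacity.
#' @param m Number of species (does not affect the value; accepted to make
#'   the m-invariance explicit).
#' @return The deterministic equilibrium group size.
#' @examples
#' meanfield_equilibrium(0.1, 100)   # 90
#' @export
meanfield_equilibrium <- function(gamma, k_cells, m = 1) {
  stopifnot(gamma >= 0, gamma < 1, k_cells > 0, m >= 1)
  (1 - gamma) * k_cells
}

#' Exact stationary mean size of an isolated all-cooperator group
#'
#' An isolated symmetric all-wild-type group (no mutation, no group events)
#' is a one-dimensional birth--death chain with per-capita birth rate
#' `(1 - gamma)` and per-capita death rate `n / k_cells`. Its
#' (quasi-)stationary law follows from the standard product formula for
#' birth--death chains, `pi_n proportional to prod lambda_{k-1} / mu_k`
#' (absorption at zero is negligible at these sizes). The mean of this law
#' sits slightly below the deterministic balance point
#' `(1 - gamma) * k_cells` (see [meanfield_equilibrium()]): demographic
#' noise in a logistic death rate depresses the mean by approximately
#' `Var(N) / N*`, i.e. about one cell at `k_cells = 100`. This exact law is
#' the oracle for time-averaged group sizes; the deterministic value is its
#' large-`k_cells` limit. The value is independent of the number of species
#' (the `m^(m-1)` normalization).
#'
#' @param gamma Cost of cooperation.
#' @param k_cells Within-group carrying capacity.
#' @param n_max Truncation of the state space (defaults to `4 * k_cells`).
#' @return The exact stationary mean group size.
#' @examples
#' single_group_stationary_mean(0.1, 100)   # just below 90
#' @export
single_group_stationary_mean <- function(gamma, k_cells, n_max = 4 * k_cells) {
  stopifnot(gamma >= 0, gamma < 1, k_cells > 0)
  n <- seq_len(ceiling(n_max))
  # log pi_n via cumulative products of lambda_{n-1} / mu_n
  steps <- log((1 - gamma) * n[-length(n)]) - log(n[-1]^2 / k_cells)
  logpi <- c(0, cumsum(steps))
  w <- exp(logpi - max(logpi))
  sum(n * w) / sum(w)
}

#' Analytic truncated-Poisson pmf
#'
#' Exact renormalized Poisson probabilities on `{1..max_support}`: the
#' analytic twin of the compiled sampler behind [rtpois()], computed through
#' `stats::dpois` (an independent code path).
#'
#' @param lambda Poisson expectation parameter (> 0).
#' @param max_support Support upper end (integer >= 1).
#' @return Numeric probability vector of length `max_support`, summing to 1.
#' @examples
#' truncated_poisson_pmf(1, 2)   # c(2/3, 1/3)
#' @export
truncated_poisson_pmf <- function(lambda, max_support) {
  stopifnot(lambda > 0, max_support >= 1)
  p <- stats::dpois(seq_len(max_support), lambda)
  p / sum(p)
}

#' Brute-force distribution of fragmentation outcomes
#'
#' Enumerates every `(N_offspring, S_offspring)` pair with its exact
#' truncated-Poisson product probability, maps each pair to its
#' deterministic partition shape (the multiset of offspring group sizes
#' implied by `G_offspring = ceiling(N_offspring / S_offspring)`, with the
#' parent-relabelling rule applied when all cells are transmitted), and
#' aggregates. Serves as the exhaustive oracle for [fragment_group()] at
#' small N.
#'
#' @param N Parent group size.
#' @param strategy A [frag_strategy()].
#' @return A tibble with `shape` (offspring sizes as a string, e.g.
#'   `"3,3,1"`), `n_parent` (cells left in the parent), and `prob`;
#'   probabilities sum to 1.
#' @export
fragment_distribution_bruteforce <- function(N, strategy) {
  stopifnot(N >= 1)
  rows <- list()
  p_n <- truncated_poisson_pmf(strategy$n * N, N)
  for (n_off in seq_len(N)) {
    p_s <- truncated_poisson_pmf(strategy$s * N, n_off)
    for (s_off in seq_len(n_off)) {
      g_off <- ceiling(n_off / s_off)
      sizes <- c(rep(s_off, g_off - 1), n_off - (g_off - 1) * s_off)
      n_parent <- N - n_off
      if (n_parent == 0) {        # relabel the last group as the parent
        n_parent <- sizes[length(sizes)]
        sizes <- sizes[-length(sizes)]
      }
      shape <- paste(sort(sizes, decreasing = TRUE), collapse = ",")
      rows[[length(rows) + 1]] <- tibble::tibble(
        shape = shape, n_parent = n_parent,
        prob = p_n[n_off] * p_s[s_off])
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$shape, .data$n_parent) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop")
}

#' Run the built-in oracle validation suite
#'
#' Compares simulated quantities against independent analytic or exhaustive
#' oracles: the truncated-Poisson sampler against the analytic pmf
#' (chi-square), the fragmentation kernel against the brute-force partition
#' distribution (total-variation distance), the cell-sampling kernel
#' against an enumerated hypergeometric probability, and the single-group
#' stochastic mean size against the mean-field equilibrium. Passing
#' tolerances are 3 Monte-Carlo standard errors (or the stated
#' distributional thresholds).
#'
#' @param n_draws Monte-Carlo sample size for the distributional checks.
#' @param seed Seed for the validation runs.
#' @return A tibble (one row per check): `quantity`, `analytic`,
#'   `simulated`, `mc_se`, `pass`.
#' @export
validate_oracles <- function(n_draws = 1e5, seed = 1) {
  set.seed(seed)
  out <- list()
  # truncated-Poisson sampler vs analytic pmf (chi-square p-values)
  cases <- list(c(2, 3), c(0.5, 10), c(5, 8), c(10, 6), c(45, 60))
  for (cs in cases) {
    pmf <- truncated_poisson_pmf(cs[1], cs[2])
    draws <- rtpois(n_draws, cs[1], cs[2])
    obs <- tabulate(draws, nbins = cs[2])
    rare <- pmf * n_draws < 5    # pool ultra-rare cells into one class
    x <- c(obs[!rare], if (any(rare)) sum(obs[rare]))
    pp <- c(pmf[!rare], if (any(rare)) sum(pmf[rare]))
    pval <- suppressWarnings(stats::chisq.test(x, p = pp)$p.value)
    out[[length(out) + 1]] <- tibble::tibble(
      quantity = sprintf("rtpois chi-square p (lambda=%g, max=%d)", cs[1], cs[2]),
      analytic = 1, simulated = pval, mc_se = NA_real_, pass = pval > 0.001)
  }
  # fragmentation kernel vs brute-force partition distribution (TV distance);
  # the sampling floor of the TV statistic scales as 1/sqrt(draws), so the
  # acceptance bound (0.01 at 1e5 draws) is rescaled accordingly
  tv_bound <- 0.01 * sqrt(1e5 / n_draws)
  for (spec in list(list(N = 8, s = 0.25, n = 0.6), list(N = 12, s = 0.1, n = 0.9))) {
    st <- frag_strategy(spec$s, spec$n)
    brute <- fragment_distribution_bruteforce(spec$N, st)
    census <- c(a = spec$N)
    sim_shapes <- vapply(seq_len(n_draws), function(i) {
      fr <- fragment_group(census, st)
      sizes <- vapply(fr$offspring, sum, integer(1))
      paste(paste(sort(sizes, decreasing = TRUE), collapse = ","),
            sum(fr$parent), sep = "|")
    }, character(1))
    emp <- table(sim_shapes) / length(sim_shapes)
    key <- paste(brute$shape, brute$n_parent, sep = "|")
    p_emp <- as.numeric(emp[key]); p_emp[is.na(p_emp)] <- 0
    tv <- 0.5 * (sum(abs(brute$prob - p_emp)) + sum(emp[!names(emp) %in% key]))
    out[[length(out) + 1]] <- tibble::tibble(
      quantity = sprintf("fragment TV distance (N=%d, s=%g, n=%g)",
                         spec$N, spec$s, spec$n),
      analytic = 0, simulated = tv, mc_se = NA_real_, pass = tv < tv_bound)
  }
  # hypergeometric kernel: P(draw 2 wt | census wt=2, mut=2, k=2) = 1/6
  both_wt <- mean(vapply(seq_len(n_draws %/% 5), function(i) {
    d <- sample_census(c(wt = 2, mut = 2), 2)
    d["wt"] == 2
  }, logical(1)))
  se <- sqrt((1 / 6) * (5 / 6) / (n_draws %/% 5))
  out[[length(out) + 1]] <- tibble::tibble(
    quantity = "P(both wild-type) in 2-of-4 draw", analytic = 1 / 6,
    simulated = both_wt, mc_se = se, pass = abs(both_wt - 1 / 6) <= 3 * se)
  # stationary size of a single isolated group vs the exact birth-death law
  p <- sim_params(m = 1, gamma = 0.1, mu = 0, b0 = 0, sigma = 0,
                  k_total = Inf, nu = 0)
  sim <- simulate_community(p, frag_strategy(0.5, 0.5), n_groups = 1,
                            t_max = 2000, control = sim_control(chunk = 500))
  ns <- sim$trajectory$n_cells[sim$trajectory$time > 100]
  bm <- batch_means_se(ns, 20)
  exact <- single_group_stationary_mean(0.1, 100)
  out[[length(out) + 1]] <- tibble::tibble(
    quantity = "single-group mean size vs exact stationary law",
    analytic = exact, simulated = mean(ns),
    mc_se = bm, pass = abs(mean(ns) - exact) <= 3 * bm)
  # the exact law converges to the deterministic balance (1-gamma)*k_cells;
  # at k_cells = 100 the demographic correction is about one cell
  out[[length(out) + 1]] <- tibble::tibble(
    quantity = "exact stationary mean vs mean-field limit",
    analytic = meanfield_equilibrium(0.1, 100), simulated = exact,
    mc_se = NA_real_,
    pass = abs(exact - meanfield_equilibrium(0.1, 100)) < 0.05 * 100)
  dplyr::bind_rows(out)
}

# standard error of a time-average from batch means (autocorrelated series)
batch_means_se <- function(x, n_batches = 20) {
  n <- length(x)
  b <- n %/% n_batches
  means <- vapply(seq_len(n_batches),
                  function(i) mean(x[((i - 1) * b + 1):(i * b)]), numeric(1))
  stats::sd(means) / sqrt(n_batches)
}
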