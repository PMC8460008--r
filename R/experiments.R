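#' Geometric mutation-rate schedule
#'
#' The maximum-mutation-rate protocol descends from the highest possible
#' mutation rate (`mu = 1`) through a geometric grid; the default ratio is
#' `10^(-1/4)` down to `1e-4`.
#'
#' @param mu_max,mu_min Endpoints of the schedule.
#' @param ratio Multiplicative step (< 1).
#' @return Decreasing numeric vector of mutation rates.
#' @export
mu_schedule <- function(mu_max = 1, mu_min = 1e-4, ratio = 10^(-1 / 4)) {
  stopifnot(mu_max > mu_min, ratio > 0, ratio < 1)
  n <- floor(log(mu_min / mu_max) / log(ratio) + 1e-9) + 1
  mu_max * ratio^(seq_len(n) - 1)
}

#' Equilibrium scan over a grid of fragmentation strategies
#'
#' Runs the simulator for every admissible strategy in `strategies` (one run
#' per replicate) and records the steady-state community size, group count
#' and wild-type fraction. Inadmissible `(s, n)` points are kept in the
#' output but flagged (`valid = FALSE`) and not run; runs cut off by guards
#' are flagged `excluded`, never silently dropped.
#'
#' @param strategies A data frame with columns `s` and `n` (e.g. from
#'   [strategy_grid()] or [upper_transect()]).
#' @param params A [sim_params()].
#' @param replicates Replicate runs per strategy.
#' @param n_groups,t_max,control Passed to [simulate_community()].
#' @param seed Base seed; replicate `r` of strategy row `i` uses
#'   `seed + 1000 * i + r`, recorded in the output.
#' @return A tibble, one row per strategy x replicate, with steady-state
#'   `n_cells`, `n_groups`, `wt_fraction`, `termination`, `excluded`,
#'   `persistent`, and the run seed.
#' @export
strategy_scan <- function(strategies, params, replicates = 1,
                          n_groups = 100, t_max = 10000,
                          control = sim_control(), seed = 1) {
  strategies <- tibble::as_tibble(strategies)
  stopifnot(all(c("s", "n") %in% names(strategies)))
  purrr::pmap_dfr(
    list(seq_len(nrow(strategies)), strategies$s, strategies$n),
    function(i, s, n) {
      if (!strategy_valid(s, n)) {
        return(tibble::tibble(s = s, n = n, replicate = NA_integer_,
                              seed = NA_integer_, valid = FALSE,
                              n_cells = NA_real_, n_groups = NA_real_,
                              wt_fraction = NA_real_,
                              termination = "not_run", excluded = FALSE,
                              persistent = NA))
      }
      purrr::map_dfr(seq_len(replicates), function(r) {
        run_seed <- seed + 1000L * i + r
        sim <- simulate_community(params, frag_strategy(s, n),
                                  n_groups = n_groups, t_max = t_max,
                                  control = control, seed = run_seed)
        tibble::tibble(s = s, n = n, replicate = r, seed = run_seed,
                       valid = TRUE,
                       n_cells = sim$steady$n_cells,
                       n_groups = sim$steady$n_groups,
                       wt_fraction = sim$steady$wt_fraction,
                       termination = sim$termination,
                       excluded = sim$excluded,
                       persistent = is_persistent(sim))
      })
    })
}

#' Maximum sustainable mutation rate of a fragmentation strategy
#'
#' For each replicate, starts at the top of the mutation-rate schedule
#' (`mu = 1` by default) and progressively lowers `mu` until the community
#' first reaches a non-zero steady state; that `mu` is the replicate's
#' `mu_max` (the largest mutation rate the strategy withstands before
#' mutational meltdown). A community that persists already at the top of
#' the schedule is flagged `"ceiling"`; one that goes extinct at every
#' scheduled `mu` is flagged `"below_floor"` (`mu_max = NA`). The aggregate
#' is the mean across replicates of `log10(mu_max)`.
#'
#' @param strategy A [frag_strategy()].
#' @param params A [sim_params()]; its `mu` is overridden by the schedule.
#' @param replicates Number of replicates (default 10).
#' @param schedule Decreasing vector of mutation rates ([mu_schedule()]).
#' @param n_groups,t_max,control Passed to [simulate_community()].
#' @param seed Base seed (replicate `r` uses `seed + r`).
#' @return A list with `replicates` (tibble: `replicate`, `mu_max`,
#'   `status`, `n_runs`, `seed`) and `mean_log10_mu_max`.
#' @export
max_mutation_rate <- function(strategy, params, replicates = 10,
                              schedule = mu_schedule(), n_groups = 100,
                              t_max = 10000, control = sim_control(),
                              seed = 1) {
  stopifnot(all(diff(schedule) < 0))
  rows <- purrr::map_dfr(seq_len(replicates), function(r) {
    run_seed <- seed + r
    set.seed(run_seed)
    mu_max <- NA_real_
    status <- "below_floor"
    n_runs <- 0L
    for (k in seq_along(schedule)) {
      p <- params
      p$mu <- schedule[k]
      sim <- simulate_community(p, strategy, n_groups = n_groups,
                                t_max = t_max, control = control)
      n_runs <- n_runs + 1L
      if (is_persistent(sim)) {
        mu_max <- schedule[k]
        status <- if (k == 1) "ceiling" else "ok"
        break
      }
    }
    tibble::tibble(replicate = r, mu_max = mu_max, status = status,
                   n_runs = n_runs, seed = run_seed)
  })
  list(strategy = strategy, replicates = rows,
       mean_log10_mu_max = mean(log10(rows$mu_max)))
}

#' Sensitivity sweep: maximum mutation rate vs sigma or nu
#'
#' Runs [max_mutation_rate()] over a strategy grid for each value of the
#' swept axis (`sigma`, the size-dependence of the fission rate, or `nu`,
#' the per-capita migration rate), stacking the per-replicate results into
#' one long table.
#'
#' @param axis `"sigma"` or `"nu"`.
#' @param values Values of the swept parameter.
#' @param strategies Data frame of `(s, n)` strategies.
#' @param params Base [sim_params()].
#' @param ... Passed on to [max_mutation_rate()].
#' @param seed Base seed.
#' @return A long tibble: one row per axis value x strategy x replicate,
#'   plus the aggregate `mean_log10_mu_max` per axis value x strategy.
#' @export
sensitivity_sweep <- function(axis = c("sigma", "nu"), values, strategies,
                              params, ..., seed = 1) {
  axis <- match.arg(axis)
  strategies <- tibble::as_tibble(strategies)
  purrr::map_dfr(seq_along(values), function(vi) {
    p <- params
    p[[axis]] <- values[vi]
    purrr::map_dfr(seq_len(nrow(strategies)), function(i) {
      res <- max_mutation_rate(frag_strategy(strategies$s[i], strategies$n[i]),
                               p, ...,
                               seed = seed + 10000L * vi + 100L * i)
      dplyr::mutate(res$replicates,
                    axis = axis, value = values[vi],
                    s = strategies$s[i], n = strategies$n[i],
                    mean_log10_mu_max = res$mean_log10_mu_max,
                    .before = 1)
    })
  })
}

#' Nearest-neighbour average over a strategy grid
#'
#' Replaces each grid point's value by the mean over itself and its
#' admissible von-Neumann neighbours (the adjacent points along the s and n
#' grid axes that are present in the table); points outside the triangle
#' are absent and never contribute.
#'
#' @param tbl A tibble with columns `s`, `n` and the value column.
#' @param value Name of the value column (string).
#' @return `tbl` with the value column replaced by its smoothed version
#'   (original kept as `<value>_raw`).
#' @export
neighbour_average <- function(tbl, value) {
  stopifnot(value %in% names(tbl))
  su <- sort(unique(tbl$s))
  nu_ <- sort(unique(tbl$n))
  is <- match(tbl$s, su)
  in_ <- match(tbl$n, nu_)
  v <- tbl[[value]]
  key <- paste(is, in_)
  lookup <- stats::setNames(seq_along(key), key)
  sm <- vapply(seq_along(v), function(i) {
    nb <- c(paste(is[i] - 1, in_[i]), paste(is[i] + 1, in_[i]),
            paste(is[i], in_[i] - 1), paste(is[i], in_[i] + 1))
    idx <- c(i, unname(lookup[nb[nb %in% key]]))
    mean(v[idx], na.rm = TRUE)
  }, numeric(1))
  tbl[[paste0(value, "_raw")]] <- v
  tbl[[value]] <- sm
  tbl
}
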