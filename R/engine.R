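#' Control settings for the simulation loop
#'
#' @param ma_window Width (in samples, i.e. time units) of the moving
#'   average applied to all outputs before steady-state detection.
#' @param ss_window Number of trailing moving-averaged points over which the
#'   steady-state criterion is evaluated.
#' @param tol_wt Relative root-mean-square fluctuation threshold for the
#'   total wild-type cell count (default 1%).
#' @param tol_groups Relative fluctuation threshold for the group count
#'   (default 5%).
#' @param chunk Length (time units) of one compiled-engine call between
#'   steady-state checks.
#' @param max_events Guard on the total number of events in a run.
#' @param growth_guard Multiple of `k_total` at which the unbounded-growth
#'   guard triggers (such runs are flagged `excluded`).
#' @return A list of class `sim_control`.
#' @export
sim_control <- function(ma_window = 200, ss_window = 200, tol_wt = 0.01,
                        tol_groups = 0.05, chunk = 100, max_events = 5e8,
                        growth_guard = 50) {
  structure(list(ma_window = ma_window, ss_window = ss_window,
                 tol_wt = tol_wt, tol_groups = tol_groups, chunk = chunk,
                 max_events = max_events, growth_guard = growth_guard),
            class = "sim_control")
}

#' Steady-state criterion
#'
#' Operational steady state: over the last `ss_window` points of the
#' moving-averaged series, the root-mean-square deviation of the total
#' wild-type cell count is below `tol_wt` (1%) of its time-averaged value,
#' and that of the group count below `tol_groups` (5%). With fewer than
#' `ma_window + ss_window - 1` samples the criterion is not evaluable and
#' returns `FALSE`. A series that is identically zero counts as steady
#' (an all-mutant or empty quasi-stationary state); persistence checks are
#' made separately on the steady-state wild-type count.
#'
#' @param n_wt Sampled total wild-type cell counts (one per time unit).
#' @param n_groups Sampled group counts.
#' @param control A [sim_control()].
#' @return Logical flag.
#' @export
steady_state_reached <- function(n_wt, n_groups, control = sim_control()) {
  rel_fluct <- function(x) {
    if (length(x) < control$ma_window + control$ss_window - 1) return(Inf)
    ma <- zoo::rollmean(x, control$ma_window, align = "right")
    w <- utils::tail(ma, control$ss_window)
    mu <- mean(w)
    if (mu == 0) return(0)
    sqrt(mean((w - mu)^2)) / mu
  }
  rel_fluct(n_wt) < control$tol_wt && rel_fluct(n_groups) < control$tol_groups
}

# ---- internal: census flattening between R (2 x m matrices) and the engine
flatten_group <- function(census, nbins = 1L, bin = 1L) {
  m <- ncol(census)
  v <- integer(2L * m * nbins)
  for (t in 0:1) for (j in seq_len(m))
    v[((t * m) + j - 1L) * nbins + bin] <- census[t + 1L, j]
  v
}

unflatten_group <- function(v, m, nbins = 1L) {
  a <- array(v, dim = c(nbins, m, 2))
  group_census(wt = colSums(matrix(a[, , 1], nrow = nbins)),
               mut = colSums(matrix(a[, , 2], nrow = nbins)))
}

sample_colnames <- function(m) {
  c("time", "n_groups", "n_cells", "n_wt", "n_mut",
    paste0("n_species", seq_len(m)), "mean_s", "mean_n")
}

# shared chunked driver for fixed-strategy and evolution runs
run_engine <- function(groups, params, s, n, evolution, bin_s, bin_n, moves,
                       t_max, control, stop_at_steady = TRUE) {
  par <- params_for_engine(params)
  m <- params$m
  cols <- sample_colnames(m)
  nbins <- length(bin_s)
  # initial (t = 0) sample row
  agg <- aggregate_flat(groups, m, nbins, bin_s, bin_n)
  traj <- matrix(c(0, agg), nrow = 1, dimnames = list(NULL, cols))
  t <- 0
  events <- NULL
  termination <- NULL
  repeat {
    t_end <- min(t + control$chunk, t_max)
    res <- run_chunk_cpp(groups, t, t_end, par, s, n, evolution,
                         bin_s, bin_n, moves, control$max_events)
    if (nrow(res$samples) > 0) {
      colnames(res$samples) <- cols
      traj <- rbind(traj, res$samples)
    }
    groups <- res$groups
    t <- res$time
    events <- if (is.null(events)) res$events else events + res$events
    if (res$status == 1) { termination <- "extinct"; break }
    if (res$status == 3) { termination <- "frozen"; break }
    if (res$status == 2) { termination <- "event_guard"; break }
    if (is.finite(params$k_total) &&
        traj[nrow(traj), "n_cells"] > control$growth_guard * params$k_total) {
      termination <- "unbounded"; break
    }
    if (stop_at_steady &&
        steady_state_reached(traj[, "n_wt"], traj[, "n_groups"], control)) {
      termination <- "steady_state"; break
    }
    if (t >= t_max) { termination <- "t_max"; break }
  }
  list(trajectory = traj, groups = groups, time = t, events = events,
       termination = termination)
}

# community aggregates from flat censuses: n_groups, n_cells, n_wt, n_mut,
# per-species totals, mean_s, mean_n
aggregate_flat <- function(groups, m, nbins, bin_s, bin_n) {
  G <- length(groups)
  tot <- Reduce(`+`, groups, accumulate = FALSE)
  if (is.null(tot)) tot <- integer(2 * m * nbins)
  a <- array(tot, dim = c(nbins, m, 2))
  wt_sp <- colSums(matrix(a[, , 1], nrow = nbins))
  mut_sp <- colSums(matrix(a[, , 2], nrow = nbins))
  per_bin <- rowSums(matrix(a, nrow = nbins))
  N <- sum(per_bin)
  c(G, N, sum(wt_sp), sum(mut_sp), wt_sp + mut_sp,
    if (N > 0) sum(per_bin * bin_s) / N else NA_real_,
    if (N > 0) sum(per_bin * bin_n) / N else NA_real_)
}

#' Simulate a community under a fixed fragmentation strategy
#'
#' Runs the exact Gillespie process over all event channels (wild-type and
#' mutant cell birth per species and group, cell death, migration, group
#' fission, group extinction), sampling the community state every time unit,
#' until it reaches the operational steady state (see
#' [steady_state_reached()]), goes extinct, trips the unbounded-growth
#' guard, or hits `t_max`. The last two terminations are flagged `excluded`.
#'
#' @param params A [sim_params()].
#' @param strategy A [frag_strategy()].
#' @param n_groups Number of initial groups (each starts with
#'   `floor(k_cells/2)` wild-type cells; see [init_community()]).
#' @param t_max Maximum simulated time (in units of the shortest cell
#'   generation).
#' @param control A [sim_control()].
#' @param seed Optional integer seed; a single seed fully determines the run.
#' @param init Optional `community` object overriding the default
#'   initialization.
#' @return An object of class `fragsim` with elements `trajectory` (tibble:
#'   `time`, `n_groups`, `n_cells`, `n_wt`, `n_mut`, per-species totals),
#'   `termination`, `excluded`, `steady` (trailing-window means), `events`
#'   (event tallies), `final` (list of [group_census()]), `params`,
#'   `strategy`, `seed`.
#' @examples
#' \donttest{
#' p <- sim_params(mu = 0, k_total = 2000)
#' sim <- simulate_community(p, frag_strategy(0.02, 0.98),
#'                           n_groups = 20, t_max = 600, seed = 1)
#' sim$termination
#' }
#' @export
simulate_community <- function(params, strategy, n_groups = 100,
                               t_max = 10000, control = sim_control(),
                               seed = NULL, init = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  comm <- init %||% init_community(params, n_groups = n_groups)
  groups <- lapply(comm$groups, flatten_group)
  res <- run_engine(groups, params, s = strategy$s, n = strategy$n,
                    evolution = FALSE, bin_s = 0, bin_n = 0,
                    moves = matrix(0L, 1, 4), t_max = t_max,
                    control = control, stop_at_steady = TRUE)
  finish_fragsim(res, params, strategy, control, seed, nbins = 1L)
}

finish_fragsim <- function(res, params, strategy, control, seed, nbins,
                           grid = NULL) {
  traj <- tibble::as_tibble(res$trajectory)
  if (nbins == 1L) traj$mean_s <- traj$mean_n <- NULL
  n <- nrow(traj)
  w <- min(control$ss_window, n)
  tailm <- function(x) mean(utils::tail(x, w))
  steady <- tibble::tibble(
    n_groups = tailm(traj$n_groups), n_cells = tailm(traj$n_cells),
    n_wt = tailm(traj$n_wt), n_mut = tailm(traj$n_mut),
    wt_fraction = if (tailm(traj$n_cells) > 0)
      tailm(traj$n_wt) / tailm(traj$n_cells) else NA_real_)
  final <- if (nbins == 1L)
    lapply(res$groups, unflatten_group, m = params$m, nbins = 1L)
  else res$groups
  structure(list(
    trajectory = traj, termination = res$termination,
    excluded = res$termination %in% c("t_max", "unbounded", "event_guard"),
    steady = steady, events = res$events, time = res$time,
    final = final, params = params, strategy = strategy, grid = grid,
    seed = seed), class = "fragsim")
}

#' @export
print.fragsim <- function(x, ...) {
  cat(sprintf("<fragsim> t = %g, termination: %s%s\n", x$time, x$termination,
              if (x$excluded) " (excluded)" else ""))
  if (!is.null(x$strategy) && inherits(x$strategy, "frag_strategy"))
    cat(sprintf("  strategy: s = %g, n = %g\n", x$strategy$s, x$strategy$n))
  cat(sprintf("  steady-window means: G = %.1f, N_total = %.1f, wt = %.1f (%.1f%% wild-type)\n",
              x$steady$n_groups, x$steady$n_cells, x$steady$n_wt,
              100 * x$steady$wt_fraction))
  invisible(x)
}

#' Did a run end in a non-zero (persistent) steady state?
#'
#' Persistence means the steady-state criterion fired with a positive
#' moving-averaged wild-type count. Runs ending by extinction are
#' non-persistent; runs cut off at `t_max` with a live wild-type population
#' are counted as persistent but carry the `excluded` flag.
#'
#' @param sim A `fragsim` object.
#' @return Logical.
#' @export
is_persistent <- function(sim) {
  (sim$termination == "steady_state" && sim$steady$n_wt > 0) ||
    (sim$termination == "t_max" && sim$steady$n_wt > 0)
}
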