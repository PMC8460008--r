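#' Discretized (s, n) phenotype grid for evolving fragmentation modes
#'
#' In evolution mode every cell carries a heritable phenotype vector (s, n).
#' For computational efficiency the phenotype space is discretized into
#' rectangular bins; mutations move between adjacent bins, and bin centers
#' are used as phenotype values. The admissible region is the closed
#' triangle `s <= n <= 1 - s`. The default resolution (10 s-bins on
#' (0, 0.5], 20 n-bins on (0, 1]) uses equal bin widths of 0.05 on both
#' axes, which keeps all three archetype corners admissible.
#'
#' @param bins_s,bins_n Number of bins on the s and n axes.
#' @return An object of class `trait_grid`: a list with `bins` (tibble of
#'   admissible bins: `bin`, `is`, `in_`, `s`, `n`), `moves` (matrix of
#'   adjacent-bin transition targets with boundary projection along n),
#'   and the axis definitions.
#' @examples
#' g <- trait_grid()
#' nrow(g$bins)       # admissible bins
#' @export
trait_grid <- function(bins_s = 10, bins_n = 20) {
  s_centers <- (seq_len(bins_s) - 0.5) * (0.5 / bins_s)
  n_centers <- (seq_len(bins_n) - 0.5) * (1 / bins_n)
  full <- tidyr::expand_grid(is = seq_len(bins_s), in_ = seq_len(bins_n))
  full$s <- s_centers[full$is]
  full$n <- n_centers[full$in_]
  eps <- 1e-9
  full$adm <- full$s <= full$n + eps & full$n <= 1 - full$s + eps
  bins <- dplyr::filter(full, .data$adm)
  bins$bin <- seq_len(nrow(bins))
  if (nrow(bins) == 0) stop("no admissible bins at this resolution")
  # lookup from (is, in_) to admissible-bin index
  key <- matrix(NA_integer_, bins_s, bins_n)
  key[cbind(bins$is, bins$in_)] <- bins$bin
  # project along the n-direction: nearest admissible n-bin at column is
  project_n <- function(is, in_) {
    cand <- which(!is.na(key[is, ]))
    if (length(cand) == 0) return(NA_integer_)
    key[is, cand[which.min(abs(cand - in_))]]
  }
  moves <- matrix(0L, nrow(bins), 4,
                  dimnames = list(NULL, c("s_up", "s_down", "n_up", "n_down")))
  for (b in seq_len(nrow(bins))) {
    is <- bins$is[b]; in_ <- bins$in_[b]
    step_s <- function(d) {
      is2 <- is + d
      if (is2 < 1 || is2 > bins_s) return(bins$bin[b])  # off-grid: stay
      tgt <- project_n(is2, in_)   # off-triangle: place on boundary along n
      if (is.na(tgt)) bins$bin[b] else tgt  # empty column: cancel the s-step
    }
    step_n <- function(d) {
      in2 <- in_ + d
      if (in2 < 1 || in2 > bins_n) return(bins$bin[b])
      tgt <- key[is, in2]
      if (is.na(tgt)) project_n(is, in2) else tgt
    }
    moves[b, ] <- c(step_s(1L), step_s(-1L), step_n(1L), step_n(-1L))
  }
  structure(list(bins = dplyr::select(bins, "bin", "is", "in_", "s", "n"),
                 moves = moves, bins_s = bins_s, bins_n = bins_n,
                 s_centers = s_centers, n_centers = n_centers),
            class = "trait_grid")
}

#' @export
print.trait_grid <- function(x, ...) {
  cat(sprintf("<trait_grid> %d x %d bins, %d admissible\n",
              x$bins_s, x$bins_n, nrow(x$bins)))
  invisible(x)
}

#' Nearest admissible bin to a phenotype (s, n)
#'
#' @param grid A [trait_grid()].
#' @param s,n Phenotype coordinates.
#' @return The admissible bin index.
#' @export
nearest_bin <- function(grid, s, n) {
  d2 <- (grid$bins$s - s)^2 + (grid$bins$n - n)^2
  grid$bins$bin[which.min(d2)]
}

#' Mutate a trait bin (adjacent-bin moves with boundary projection)
#'
#' With probability `mu_s` the offspring moves one bin in the s-direction
#' (direction uniform), and independently with probability `mu_n` one bin in
#' the n-direction, in that order; a simultaneous double mutation is
#' possible. A move that would leave the admissible triangle is projected
#' along the n-direction onto the boundary of the allowed space (an s-step
#' into a column with no admissible bin is cancelled).
#'
#' @param bin Parent's admissible bin index.
#' @param mu_s,mu_n Per-birth trait mutation probabilities.
#' @param grid A [trait_grid()].
#' @return The offspring's (admissible) bin index.
#' @export
mutate_trait <- function(bin, mu_s, mu_n, grid) {
  if (mu_s > 0 && stats::runif(1) < mu_s)
    bin <- grid$moves[bin, if (stats::runif(1) < 0.5) "s_up" else "s_down"]
  if (mu_n > 0 && stats::runif(1) < mu_n)
    bin <- grid$moves[bin, if (stats::runif(1) < 0.5) "n_up" else "n_down"]
  bin
}

#' Emergent group strategy: cell-count-weighted mean trait
#'
#' The fragmentation strategy a group uses at fission is the mean (s, n)
#' phenotype of its member cells. Because the admissible triangle is convex
#' the mean of admissible bin centers is itself admissible; the n-clamp is a
#' numerical safeguard consistent with the mutation-boundary rule.
#'
#' @param counts Cell counts per admissible bin (length `nrow(grid$bins)`).
#' @param grid A [trait_grid()].
#' @return A [frag_strategy()].
#' @export
group_mean_strategy <- function(counts, grid) {
  stopifnot(length(counts) == nrow(grid$bins), sum(counts) > 0)
  s <- sum(counts * grid$bins$s) / sum(counts)
  n <- sum(counts * grid$bins$n) / sum(counts)
  n <- min(max(n, s), 1 - s)
  frag_strategy(s, n)
}

#' Simulate the evolution of the fragmentation mode
#'
#' Full two-level dynamics with trait-resolved censuses: each cell carries an
#' (s, n) bin, offspring inherit it up to adjacent-bin mutations at rates
#' `mu_s`, `mu_n` (from `params`), and a group's fragmentation strategy at
#' each fission event is the current mean trait of its cells. The community
#' mean trait is recorded every time unit and the full trait histogram at
#' every `snapshot_every` time units. The run proceeds to `t_end` (no
#' steady-state stopping; extinction terminates early).
#'
#' @param params A [sim_params()] with `mu_s` and/or `mu_n` > 0.
#' @param grid A [trait_grid()].
#' @param init_strategy Starting phenotype: a [frag_strategy()] (all cells
#'   start in the nearest admissible bin).
#' @param n_groups Number of initial groups.
#' @param t_end Simulated time horizon.
#' @param snapshot_every Interval between trait-distribution snapshots.
#' @param control A [sim_control()].
#' @param seed Optional integer seed.
#' @return An object of class `fragevo`: `trajectory` (tibble with `time`,
#'   community totals, `mean_s`, `mean_n`), `snapshots` (long tibble:
#'   `time`, `s`, `n`, `count`), `termination`, `final` (per-bin censuses),
#'   `grid`, `params`, `seed`.
#' @export
simulate_evolution <- function(params, grid = trait_grid(),
                               init_strategy = frag_strategy(0.5, 0.5),
                               n_groups = 100, t_end = 1e5,
                               snapshot_every = 1000,
                               control = sim_control(), seed = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(grid, "trait_grid"))
  if (!is.null(seed)) set.seed(seed)
  nb <- nrow(grid$bins)
  b0 <- nearest_bin(grid, init_strategy$s, init_strategy$n)
  comm <- init_community(params, n_groups = n_groups)
  groups <- lapply(comm$groups, flatten_group, nbins = nb, bin = b0)
  par <- params_for_engine(params)
  cols <- sample_colnames(params$m)
  agg <- aggregate_flat(groups, params$m, nb, grid$bins$s, grid$bins$n)
  traj <- matrix(c(0, agg), nrow = 1, dimnames = list(NULL, cols))
  snaps <- list(snapshot_bins(groups, grid, time = 0))
  t <- 0
  events <- NULL
  termination <- "t_end"
  moves0 <- grid$moves - 1L  # 0-based for the engine
  repeat {
    chunk_end <- min(t + snapshot_every, t_end)
    res <- run_chunk_cpp(groups, t, chunk_end, par, 0, 0, TRUE,
                         grid$bins$s, grid$bins$n, moves0,
                         control$max_events)
    if (nrow(res$samples) > 0) {
      colnames(res$samples) <- cols
      traj <- rbind(traj, res$samples)
    }
    groups <- res$groups
    t <- res$time
    events <- if (is.null(events)) res$events else events + res$events
    if (res$status == 1) { termination <- "extinct"; break }
    if (res$status == 2) { termination <- "event_guard"; break }
    if (res$status == 3) { termination <- "frozen"; break }
    snaps[[length(snaps) + 1]] <- snapshot_bins(groups, grid, time = t)
    if (is.finite(params$k_total) &&
        traj[nrow(traj), "n_cells"] > control$growth_guard * params$k_total) {
      termination <- "unbounded"; break
    }
    if (t >= t_end) break
  }
  structure(list(trajectory = tibble::as_tibble(traj),
                 snapshots = dplyr::bind_rows(snaps),
                 termination = termination, events = events, time = t,
                 final = groups, grid = grid, params = params,
                 init_strategy = init_strategy, seed = seed),
            class = "fragevo")
}

snapshot_bins <- function(groups, grid, time) {
  nb <- nrow(grid$bins)
  m <- length(groups[[1]]) / (2 * nb)
  tot <- Reduce(`+`, groups)
  per_bin <- rowSums(matrix(tot, nrow = nb))
  keep <- per_bin > 0
  tibble::tibble(time = time, s = grid$bins$s[keep], n = grid$bins$n[keep],
                 count = per_bin[keep])
}

#' @export
print.fragevo <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("<fragevo> t = %g (%s), mean strategy (s, n) = (%.3f, %.3f)\n",
              x$time, x$termination, last$mean_s, last$mean_n))
  invisible(x)
}
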