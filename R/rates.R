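#' Per-group cell census
#'
#' A group is described by its per-species counts of wild-type (cooperator)
#' and mutant (cheater) cells. This is the unit of state on which all rate
#' functions operate.
#'
#' @param wt Integer vector of wild-type counts, one entry per species.
#' @param mut Integer vector of mutant counts (defaults to all zero).
#' @return An integer matrix of class `group_census` with rows `wt`, `mut`
#'   and one column per species.
#' @examples
#' g <- group_census(wt = c(25, 25), mut = c(0, 3))
#' group_size(g)
#' @export
group_census <- function(wt, mut = rep(0L, length(wt))) {
  stopifnot(length(wt) == length(mut), all(wt >= 0), all(mut >= 0),
            all(wt == round(wt)), all(mut == round(mut)))
  m <- matrix(as.integer(c(wt, mut)), nrow = 2, byrow = TRUE,
              dimnames = list(c("wt", "mut"), NULL))
  class(m) <- c("group_census", class(m))
  m
}

#' @rdname group_census
#' @param group A `group_census`.
#' @export
group_size <- function(group) sum(group)

#' Cell-level and group-level rate functions
#'
#' The reference (R-level) implementations of the model's rates; the compiled
#' engine mirrors them exactly (see [event_rate_table()] for the audit).
#'
#' * `mutant_birth_rate()`: per-capita birth rate of a mutant of species `j`.
#'   With one species it is the wild-type fraction `n_wt / N_i`; with `m`
#'   species it is `m^(m-1) * prod_{k != j} (n_wt_k / N_i)`, so growth needs
#'   cooperating partners of all other species, and the `m^(m-1)` factor makes
#'   the all-cooperator symmetric rate exactly 1 for every `m`.
#' * `wildtype_birth_rate()`: `(1 - gamma)` times the mutant rate, `gamma`
#'   being the cost of cooperation.
#' * `death_rate()`: per-capita death rate; `N_i / k_cells` under the
#'   density-dependent default, `1 / k_cells` under the constant-death
#'   variant (which pairs with forced fission at `k_cells`).
#' * `fission_rate()`: per-group rate `b0 + sigma * N_i / k_cells`.
#' * `extinction_rate()`: per-group rate `N_total / k_total`, identical for
#'   every group.
#' * `migration_rate()`: total per-group emigration rate `N_i * nu`; zero
#'   when the community holds a single group (there is no destination).
#'
#' @param group A [group_census()].
#' @param j Species index in `1..m`.
#' @param params A [sim_params()] object.
#' @param n_total Total number of cells in the community.
#' @param n_groups Number of groups currently in the community.
#' @return A single non-negative rate.
#' @examples
#' p <- sim_params(m = 2, gamma = 0.1)
#' g <- group_census(wt = c(50, 50))
#' mutant_birth_rate(g, 1, p)    # symmetric all-cooperator optimum: 1
#' wildtype_birth_rate(g, 1, p)  # 0.9
#' @export
mutant_birth_rate <- function(group, j, params) {
  N <- group_size(group)
  stopifnot("group must be non-empty" = N > 0,
            j >= 1, j <= params$m)
  wt <- unname(group["wt", ])
  if (params$m == 1) return(wt[1] / N)
  # accumulate in the same order as the compiled engine so the audit of
  # cached-vs-recomputed rates can demand exact equality
  r <- as.numeric(params$m)^(params$m - 1)
  for (k in seq_len(params$m)[-j]) r <- r * (wt[k] / N)
  r
}

#' @rdname mutant_birth_rate
#' @export
wildtype_birth_rate <- function(group, j, params) {
  (1 - params$gamma) * mutant_birth_rate(group, j, params)
}

#' @rdname mutant_birth_rate
#' @export
death_rate <- function(group, params) {
  N <- group_size(group)
  stopifnot("group must be non-empty" = N > 0)
  if (params$death_variant == "density_dependent") N / params$k_cells
  else 1 / params$k_cells
}

#' @rdname mutant_birth_rate
#' @export
fission_rate <- function(group, params) {
  params$b0 + params$sigma * group_size(group) / params$k_cells
}

#' @rdname mutant_birth_rate
#' @export
extinction_rate <- function(n_total, params) {
  if (!is.finite(params$k_total)) return(0)
  n_total / params$k_total
}

#' @rdname mutant_birth_rate
#' @export
migration_rate <- function(group, params, n_groups = 2) {
  if (n_groups <= 1) return(0)
  group_size(group) * params$nu
}

#' Full event-rate table of a community state
#'
#' Computes, from scratch and with the R-level rate functions, the realized
#' channel rates of every group: total wild-type birth
#' (`sum_j n_wt_j * b_wt_j`), total mutant birth, total death (`N_i * d_i`),
#' migration (`N_i * nu`, gated on `G > 1`), fission (`B_i`), and the shared
#' per-group extinction rate. Used as the audit oracle against the compiled
#' engine's cached rates, which must agree exactly.
#'
#' @param groups A list of [group_census()] objects.
#' @param params A [sim_params()] object.
#' @return A tibble with one row per group and the community total rate in
#'   attribute `"total_rate"`.
#' @export
event_rate_table <- function(groups, params) {
  G <- length(groups)
  n_total <- sum(vapply(groups, group_size, numeric(1)))
  D <- extinction_rate(n_total, params)
  rows <- purrr::map(groups, function(g) {
    b <- vapply(seq_len(params$m), function(j) mutant_birth_rate(g, j, params),
                numeric(1))
    # accumulate in double precision in the engine's summation order, so the
    # cached-vs-recomputed audit can demand bitwise equality
    wtv <- unname(g["wt", ])
    mutv <- unname(g["mut", ])
    bwt <- 0
    bmut <- 0
    for (j in seq_len(params$m)) {
      if (b[j] > 0) {
        bwt <- bwt + wtv[j] * (1 - params$gamma) * b[j]
        bmut <- bmut + mutv[j] * b[j]
      }
    }
    tibble::tibble(
      birth_wt = bwt, birth_mut = bmut,
      death = group_size(g) * death_rate(g, params),
      migration = migration_rate(g, params, n_groups = G),
      fission = fission_rate(g, params),
      extinction = D)
  })
  out <- dplyr::bind_rows(rows)
  out$total <- out$birth_wt + out$birth_mut + out$death + out$migration +
    out$fission
  attr(out, "total_rate") <- sum(out$total) + G * D
  out
}
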