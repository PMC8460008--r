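#' Initialize a community of identical groups
#'
#' Builds the standard starting state: `n_groups` identical groups, each
#' holding `floor(k_cells / 2)` wild-type cells (no mutants), split equally
#' over the `m` species; when the split is not exact the remainder cells go
#' to the lowest-index species. With the defaults (`k_cells = 100`,
#' `n_groups = 100`) every group starts with 50 cooperator cells.
#'
#' @param params A [sim_params()] object.
#' @param n_groups Number of initial groups.
#' @param n_cells Cells per initial group; defaults to `floor(k_cells / 2)`.
#' @return An object of class `community`: a list with `groups` (list of
#'   [group_census()]), `time`, and `params`.
#' @examples
#' comm <- init_community(sim_params(m = 3))
#' comm$groups[[1]]["wt", ]   # 17 17 16
#' @export
init_community <- function(params, n_groups = 100,
                           n_cells = floor(params$k_cells / 2)) {
  stopifnot(n_groups >= 1, n_cells >= params$m)
  base <- n_cells %/% params$m
  rem <- n_cells %% params$m
  wt <- base + as.integer(seq_len(params$m) <= rem)
  g <- group_census(wt = wt)
  structure(list(groups = rep(list(g), n_groups), time = 0, params = params),
            class = "community")
}

#' @export
print.community <- function(x, ...) {
  ns <- vapply(x$groups, group_size, numeric(1))
  cat(sprintf("<community> %d groups, %d cells, t = %g\n",
              length(x$groups), sum(ns), x$time))
  invisible(x)
}

#' Summarize a community state as a one-row tibble
#'
#' @param comm A `community` object.
#' @return A tibble with time, group count, cell totals, and per-species
#'   totals.
#' @export
community_summary <- function(comm) {
  m <- comm$params$m
  wt <- rowSums(vapply(comm$groups, function(g) g["wt", ], numeric(m)) |>
                  matrix(nrow = m))
  mut <- rowSums(vapply(comm$groups, function(g) g["mut", ], numeric(m)) |>
                   matrix(nrow = m))
  out <- tibble::tibble(time = comm$time, n_groups = length(comm$groups),
                        n_cells = sum(wt) + sum(mut),
                        n_wt = sum(wt), n_mut = sum(mut))
  sp <- tibble::as_tibble(as.list(stats::setNames(
    wt + mut, paste0("n_species", seq_len(m)))))
  dplyr::bind_cols(out, sp)
}
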