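#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation run into its sampled trajectory
#'
#' @param x A `fragsim` object.
#' @param ... Unused.
#' @return The trajectory tibble (`time`, `n_groups`, `n_cells`, `n_wt`,
#'   `n_mut`, per-species totals), one row per sampled time unit.
#' @method tidy fragsim
#' @export
tidy.fragsim <- function(x, ...) x$trajectory

#' One-row summary of a simulation run
#'
#' @param x A `fragsim` object.
#' @param ... Unused.
#' @return A one-row tibble: strategy, termination, steady-window means,
#'   wild-type fraction, run length and seed.
#' @method glance fragsim
#' @export
glance.fragsim <- function(x, ...) {
  tibble::tibble(
    s = x$strategy$s, n = x$strategy$n,
    termination = x$termination, excluded = x$excluded,
    persistent = is_persistent(x),
    time = x$time,
    n_groups = x$steady$n_groups, n_cells = x$steady$n_cells,
    n_wt = x$steady$n_wt, wt_fraction = x$steady$wt_fraction,
    seed = x$seed %||% NA_integer_)
}

#' @rdname tidy.fragsim
#' @method tidy fragevo
#' @export
tidy.fragevo <- function(x, ...) x$trajectory

#' @rdname glance.fragsim
#' @method glance fragevo
#' @export
glance.fragevo <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  tibble::tibble(
    s_init = x$init_strategy$s, n_init = x$init_strategy$n,
    s_final = last$mean_s, n_final = last$mean_n,
    termination = x$termination, time = x$time,
    n_cells = last$n_cells, n_groups = last$n_groups,
    seed = x$seed %||% NA_integer_)
}
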