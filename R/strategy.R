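#' Fragmentation strategies: the (s, n) triangle
#'
#' A fragmentation mode is a point `(s, n)` where `n` in (0, 1] is the
#' expected fraction of the parent's cells transmitted to offspring and `s`
#' in (0, 0.5] is the expected size of each offspring group, again as a
#' fraction of the parent's size. Valid strategies satisfy
#' `s <= n <= 1 - s` (the closed triangle, so the three archetype corners --
#' single-cell reproduction, complete fragmentation, binary fission -- are
#' admissible). The lower triangle (`n < s`) is logically impossible; above
#' the upper diagonal (`n > 1 - s`) the leftover "parent" would be smaller
#' than an offspring group, and one of the resulting groups is relabelled as
#' the parent instead.
#'
#' @param s Expected offspring-size fraction, in (0, 0.5].
#' @param n Expected transmitted-cell fraction, in (0, 1].
#' @return `frag_strategy()` returns a validated object of class
#'   `frag_strategy`; `strategy_valid()` returns a logical (vectorized over
#'   `s` and `n`).
#' @examples
#' frag_strategy(0.5, 0.5)            # binary fission
#' strategy_valid(0.3, 0.2)           # FALSE: lower triangle
#' strategy_archetypes(group_size = 100)
#' @export
frag_strategy <- function(s, n) {
  stopifnot(length(s) == 1, length(n) == 1)
  if (!strategy_valid(s, n))
    stop(sprintf(
      "invalid fragmentation strategy (s = %g, n = %g): need 0 < s <= 0.5, 0 < n <= 1 and s <= n <= 1 - s",
      s, n))
  structure(list(s = s, n = n), class = "frag_strategy")
}

#' @rdname frag_strategy
#' @export
strategy_valid <- function(s, n) {
  s > 0 & s <= 0.5 & n > 0 & n <= 1 & s <= n & n <= 1 - s
}

#' @export
print.frag_strategy <- function(x, ...) {
  cat(sprintf("<frag_strategy> s = %g, n = %g\n", x$s, x$n))
  invisible(x)
}

#' @rdname frag_strategy
#' @param group_size Reference group size N used to place the single-cell
#'   corners (`s = 1/N` plays the role of "one cell").
#' @export
strategy_archetypes <- function(group_size = 100) {
  e <- 1 / group_size
  tibble::tibble(
    archetype = c("single_cell", "complete_fragmentation", "binary_fission"),
    s = c(e, e, 0.5),
    n = c(e, 1 - e, 0.5))
}

#' Grids over the strategy triangle
#'
#' `strategy_grid()` lays a regular grid over the `(s, n)` rectangle and
#' keeps the admissible points; `upper_transect()` returns points along the
#' upper diagonal `n = 1 - s` (from complete fragmentation at small `s` to
#' binary fission at `s = 0.5`), the transect along which the productivity
#' maximum moves as species number grows.
#'
#' @param s_values,n_values Grid coordinates (numeric vectors).
#' @param keep_invalid If `TRUE`, inadmissible points are kept and flagged in
#'   the `valid` column instead of dropped.
#' @return A tibble with columns `s`, `n` (and `valid` if `keep_invalid`).
#' @export
strategy_grid <- function(s_values, n_values, keep_invalid = FALSE) {
  g <- tidyr::expand_grid(s = s_values, n = n_values)
  g$valid <- strategy_valid(g$s, g$n)
  if (keep_invalid) g else dplyr::select(dplyr::filter(g, .data$valid), -"valid")
}

#' @rdname strategy_grid
#' @param n_points Number of transect points.
#' @param s_min Smallest s on the transect (complete-fragmentation end).
#' @export
upper_transect <- function(n_points = 6, s_min = 0.02) {
  s <- seq(s_min, 0.5, length.out = n_points)
  tibble::tibble(s = s, n = 1 - s)
}
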