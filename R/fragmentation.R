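#' Truncated Poisson sampling on {1, ..., max_support}
#'
#' The offspring numbers of a fragmenting group are drawn from Poisson
#' distributions renormalized to a finite support: the total number of
#' transmitted cells `N_offspring` from expectation-parameter `n * N_i` on
#' `{1..N_i}`, and the per-offspring size `S_offspring` from `s * N_i` on
#' `{1..N_offspring}`. `rtpois()` draws from that law (compiled sampler);
#' [truncated_poisson_pmf()] is its independent analytic twin used for
#' validation.
#'
#' The Poisson rate is set to the stated expectation parameter and then
#' truncated/renormalized, so the mean of the truncated law deviates
#' slightly from `lambda` near the support edges.
#'
#' @param n Number of draws.
#' @param lambda Poisson expectation parameter (> 0).
#' @param max_support Upper end of the support (integer >= 1).
#' @return Integer vector of draws in `{1..max_support}`.
#' @examples
#' set.seed(1)
#' table(rtpois(1000, lambda = 2, max_support = 3))
#' @export
rtpois <- function(n, lambda, max_support) {
  stopifnot(lambda > 0, max_support >= 1)
  rtpois_cpp(as.integer(n), lambda, as.integer(max_support))
}

#' Sample cells without replacement from a census
#'
#' Draws `k` cells from a per-category census (categories are arbitrary:
#' species x type, or species x type x trait bin); the drawn counts follow
#' the multivariate hypergeometric law. This is the sampling kernel used to
#' allocate cells to offspring groups during fragmentation.
#'
#' @param census Non-negative integer vector of per-category counts.
#' @param k Number of cells to draw (`0 <= k <= sum(census)`).
#' @return Integer vector of drawn counts, same length (and names) as
#'   `census`; `census - drawn` is the remainder.
#' @examples
#' set.seed(1)
#' sample_census(c(wt = 2, mut = 2), 2)
#' @export
sample_census <- function(census, k) {
  stopifnot(all(census >= 0), k >= 0, k <= sum(census))
  out <- sample_census_cpp(as.integer(census), as.integer(k))
  names(out) <- names(census)
  out
}

#' Fragment a group according to an (s, n) strategy
#'
#' Implements the fragmentation event: draw `N_offspring` (truncated Poisson
#' with expectation parameter `n * N_i` on `{1..N_i}`), then `S_offspring`
#' (expectation parameter `s * N_i` on `{1..N_offspring}`), compute
#' `G_offspring = ceiling(N_offspring / S_offspring)`, give the first
#' `G_offspring - 1` offspring exactly `S_offspring` cells and the last the
#' remainder, all sampled without replacement from the parent census. Cells
#' are conserved exactly per category. If every cell is transmitted, the
#' last offspring group is relabelled as the parent, so an empty group never
#' survives the event.
#'
#' @param census Non-negative integer vector: the parent group's
#'   per-category census (must hold at least one cell).
#' @param strategy A [frag_strategy()] (or a list with elements `s`, `n`).
#' @param force_n_offspring,force_s_offspring Optional fixed values for
#'   `N_offspring` / `S_offspring`, bypassing the random draws (used for
#'   deterministic checks).
#' @return A list with `parent` and `offspring` (list of censuses), plus
#'   `n_offspring`, `s_offspring`, `g_offspring` and `parent_relabelled`.
#' @examples
#' set.seed(1)
#' fragment_group(c(wt = 10), frag_strategy(0.3, 0.7),
#'                force_n_offspring = 7, force_s_offspring = 3)
#' @export
fragment_group <- function(census, strategy,
                           force_n_offspring = NULL, force_s_offspring = NULL) {
  stopifnot(sum(census) >= 1)
  if (!strategy_valid(strategy$s, strategy$n))
    stop("invalid fragmentation strategy")
  res <- fragment_census_cpp(as.integer(census), strategy$s, strategy$n,
                             force_n_offspring %||% -1L,
                             force_s_offspring %||% -1L)
  nm <- names(census)
  if (!is.null(nm)) {
    names(res$parent) <- nm
    res$offspring <- lapply(res$offspring, stats::setNames, nm)
  }
  res
}
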