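#' Model parameters for the two-level birth--death process
#'
#' Bundles every rate constant and switch of the simulator: the cell level
#' (cooperator/cheater birth--death with mutation at birth) and the group
#' level (fission, extinction, migration). Time is measured in units of the
#' shortest possible cell generation (the maximum per-capita birth rate is 1).
#'
#' The defaults are a documented working set, not a published table: 1
#' species, cost of cooperation `gamma = 0.1` (a moderate cost chosen as a
#' representative value; set it explicitly for production runs), no mutation,
#' within-group carrying capacity `k_cells = 100`, baseline fission rate
#' `b0 = 0.01`, no size-dependent fission (`sigma = 0`), community scaling
#' constant `k_total = 10000`, and no migration (`nu = 0`).
#'
#' @param m Number of species in a group (integer >= 1). With `m = 1`
#'   cooperation is within-species (public goods); with `m > 1` growth
#'   requires cooperating partners of all other species (cross-feeding).
#' @param gamma Cost of cooperation, `0 <= gamma < 1`. Wild-type cells are
#'   born at `(1 - gamma)` times the mutant rate.
#' @param mu Probability that a wild-type birth yields a mutant (cheater)
#'   offspring, `0 <= mu <= 1`. There is no back-mutation.
#' @param k_cells Within-group carrying capacity (cells); sets the
#'   density-dependent per-capita death rate `N_i / k_cells`.
#' @param b0 Baseline group fission rate (per group per unit time).
#' @param sigma Slope of the size-dependent component of the fission rate:
#'   `B_i = b0 + sigma * N_i / k_cells`.
#' @param k_total Community-level scaling constant (cells); the per-group
#'   extinction rate is `N_total / k_total`. Use `Inf` to disable group
#'   extinction.
#' @param nu Per-capita migration rate (per cell per unit time).
#' @param mu_s,mu_n Per-birth probabilities of a small-effect mutation in the
#'   heritable fragmentation traits s and n (evolution mode only).
#' @param death_variant Either `"density_dependent"` (per-capita death
#'   `N_i / k_cells`) or `"constant_with_forced_fission"` (constant death
#'   `1 / k_cells`, with groups forced to fission on reaching `k_cells`
#'   cells).
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(m = 2, gamma = 0.1, mu = 0.01)
#' p$k_cells
#' @export
sim_params <- function(m = 1, gamma = 0.1, mu = 0, k_cells = 100,
                       b0 = 0.01, sigma = 0, k_total = 10000, nu = 0,
                       mu_s = 0, mu_n = 0,
                       death_variant = c("density_dependent",
                                         "constant_with_forced_fission")) {
  death_variant <- match.arg(death_variant)
  p <- list(m = as.integer(m), gamma = gamma, mu = mu, k_cells = k_cells,
            b0 = b0, sigma = sigma, k_total = k_total, nu = nu,
            mu_s = mu_s, mu_n = mu_n, death_variant = death_variant)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(
    "m must be an integer >= 1" = length(p$m) == 1 && p$m >= 1,
    "gamma must satisfy 0 <= gamma < 1" =
      length(p$gamma) == 1 && p$gamma >= 0 && p$gamma < 1,
    "mu must lie in [0, 1]" = length(p$mu) == 1 && p$mu >= 0 && p$mu <= 1,
    "k_cells must be positive" = p$k_cells > 0,
    "k_cells must be at least m" = p$k_cells >= p$m,
    "b0 must be non-negative" = p$b0 >= 0,
    "sigma must be non-negative" = p$sigma >= 0,
    "k_total must be positive (possibly Inf)" = p$k_total > 0,
    "nu must be non-negative" = p$nu >= 0,
    "mu_s must lie in [0, 1]" = p$mu_s >= 0 && p$mu_s <= 1,
    "mu_n must lie in [0, 1]" = p$mu_n >= 0 && p$mu_n <= 1
  )
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  species (m): %d   cost gamma: %g   mutation mu: %g\n",
              x$m, x$gamma, x$mu))
  cat(sprintf("  k_cells: %g   b0: %g   sigma: %g   k_total: %g   nu: %g\n",
              x$k_cells, x$b0, x$sigma, x$k_total, x$nu))
  cat(sprintf("  death variant: %s", x$death_variant))
  if (x$mu_s > 0 || x$mu_n > 0)
    cat(sprintf("   trait mutation (mu_s, mu_n): (%g, %g)", x$mu_s, x$mu_n))
  cat("\n")
  invisible(x)
}

# internal: list form consumed by the compiled engine
params_for_engine <- function(p) {
  list(m = p$m, gamma = p$gamma, mu = p$mu, k_cells = p$k_cells,
       b0 = p$b0, sigma = p$sigma,
       k_total = if (is.finite(p$k_total)) p$k_total else -1,
       nu = p$nu, mu_s = p$mu_s, mu_n = p$mu_n,
       death_variant = if (p$death_variant == "density_dependent") 0L else 1L)
}
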