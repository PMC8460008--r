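# shared fixtures: small random group states and quick-run controls

base_params <- function(...) sim_params(gamma = 0.1, ...)

# a list of group_census objects with mixed compositions (some zeros)
random_groups <- function(m, n_groups, max_cells = 30, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_groups), function(i) {
    repeat {
      wt <- rpois(m, 5)
      mut <- rpois(m, 2)
      if (sum(wt) + sum(mut) > 0) break
    }
    group_census(wt = wt, mut = mut)
  })
}

flatten_groups <- function(groups) lapply(groups, fragmodes:::flatten_group)

quick_control <- function(chunk = 200, ...) sim_control(chunk = chunk, ...)
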