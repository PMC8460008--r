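---
title: "Multilevel selection on fragmentation modes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel selection on fragmentation modes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fragmodes simulates communities of multicellular groups — think mixed
microbial biofilms or simple multicellular collectives — in which selection
acts at two levels at once: cells divide and die inside groups, and groups
themselves reproduce by fragmentation and go extinct. The package exists to
ask one question: which *mode of fragmentation* (how many cells a
reproducing group passes on, and in how many pieces) lets a community keep
its cooperators in the face of recurrent cheater mutations?

## The model

A community holds a fluctuating number $G$ of groups. Group $i$ contains
$N_i$ cells of $m$ species; each cell is wild-type (a cooperator, paying a
cost $\gamma$ to produce public goods) or a mutant (a cheater that consumes
without producing). All rates are linear; time is measured in units of the
shortest possible cell generation, so the maximum per-capita birth rate is 1.

**Cell birth.** The per-capita birth rate of a mutant of species $j$ in
group $i$ is
$$
b^{mut}_{i,j} =
\begin{cases}
n^{wt}_{i,j} / N_i, & m = 1,\\[2pt]
m^{\,m-1} \prod_{k \neq j} n^{wt}_{i,k} / N_i, & m > 1,
\end{cases}
$$
so growth requires cooperators — conspecifics when $m = 1$, partners of
every other species (cross-feeding) when $m > 1$. The factor $m^{m-1}$
makes the symmetric all-cooperator optimum exactly 1 for every $m$.
Wild-type cells are born at $(1-\gamma)\,b^{mut}_{i,j}$. A wild-type birth
yields a mutant with probability $\mu$; there is no back-mutation.

**Cell death.** Per-capita death is density dependent,
$d_i = N_i / K_{\text{cells}}$ (logistic regulation within the group). An
alternative variant uses a constant death rate $1/K_{\text{cells}}$ and
instead forces a group to fission the moment it reaches $K_{\text{cells}}$
cells.

**Group fission.** Groups fission at rate
$B_i = B_0 + \sigma N_i / K_{\text{cells}}$. The slope $\sigma$ dials the
strength of group selection: with $\sigma > 0$, large (hence
cooperator-rich) groups reproduce more.

**Fragmentation mode.** A mode is a point $(s, n)$ with
$s \le n \le 1 - s$: $n \in (0,1]$ is the expected fraction of the
parent's cells transmitted to offspring, $s \in (0, 0.5]$ the expected
size of each offspring group, both as fractions of $N_i$. At a fission,
$N_{\text{offspring}}$ is drawn from a Poisson law with expectation
parameter $n N_i$ renormalized to $\{1..N_i\}$, then
$S_{\text{offspring}}$ from one with parameter $s N_i$ on
$\{1..N_{\text{offspring}}\}$;
$G_{\text{offspring}} = \lceil N_{\text{offspring}}/S_{\text{offspring}}
\rceil$ groups are filled by sampling cells without replacement
(multivariate hypergeometric over the species-by-type census), the last
group taking the remainder. The corners of the triangle are the archetypes:
single-cell reproduction ($s = n = 1/N_i$), complete fragmentation
($s = 1/N_i$, $n = 1 - 1/N_i$), and binary fission ($s = n = 1/2$).

**Group extinction and migration.** Every group dies at the same rate
$D = N_{\text{total}} / K_{\text{total}}$, which bounds the community; and
each cell emigrates at per-capita rate $\nu$ to a uniformly chosen *other*
group (with a single group the channel is silent — there is no
destination).

**Evolution mode.** $(s, n)$ can itself be a heritable cell trait on a
discretized grid; offspring inherit the parental bin up to adjacent-bin
mutations at rates $\mu_s$, $\mu_n$, and a fissioning group uses the mean
trait of its member cells.

## Implementation

The event loop is an exact Gillespie algorithm over all channels (wild-type
and mutant birth per species per group, death, migration, fission,
extinction), implemented in compiled code with all randomness drawn from
R's RNG, so one `set.seed()` determines a run bit-for-bit. Per-group
channel rates are cached and re-derived from the group's census after every
event that touches it; `event_rate_table()` recomputes the whole table in R
from the documented rate functions, and the test suite demands *exact*
(bitwise) agreement between the two routes.

The state is sampled at every integer time; because event times almost
never hit integers, the sample records the state at the last event before
each boundary. All outputs are smoothed with a 200-point moving average,
and a run is declared at steady state when, over the last 200 smoothed
points, the relative RMS fluctuation of the total wild-type count falls
below 1% and that of the group count below 5%. Runs also stop on
extinction, on an unbounded-growth guard
($N_{\text{total}} > 50\,K_{\text{total}}$), on an event-count guard, or at
`t_max`; the last three are flagged `excluded` in every output rather than
dropped. For persistence classification (`is_persistent()`), a run counts
as persistent if it reached steady state with wild-type cells present, or
was cut at `t_max` still holding wild-type cells.

### Numerical choices

* **Truncated-Poisson parameterization.** The Poisson rate is set to the
  stated expectation parameter ($nN_i$ or $sN_i$) and then truncated and
  renormalized; the truncated mean therefore deviates slightly from the
  nominal product near the support edges. This is the simplest literal
  reading; whether the rate should instead be solved so the truncated mean
  is exact is undecidable from the printed description, and the difference
  is a fraction of a cell at the sizes simulated.
* **Closed triangle.** Validity is $s \le n \le 1-s$ (closed), so the three
  archetype corners are admissible strategies; the strict inequalities are
  read as describing the interior.
* **Empty parent.** If a draw transmits every cell, the last offspring
  group is relabelled as the parent; a zero-cell group never survives an
  event.
* **Initialization.** Runs start from `n_groups` identical groups of
  $\lfloor K_{\text{cells}}/2 \rfloor$ wild-type cells split equally over
  species, remainder cells to the lowest-index species.
* **Trait grid.** Default 10 bins in $s$ and 20 in $n$ — equal widths of
  0.05 on both axes — so that admissibility tested at bin centers keeps all
  three archetype corners representable (a 20-by-20 grid with unequal
  widths leaves no admissible bin at the binary-fission corner).
  Off-triangle mutants are projected along the $n$ direction onto the
  boundary; an $s$-step into a column with no admissible bin is cancelled.
  $s$- and $n$-mutations are independent Bernoulli events applied in that
  order, so rare double mutations are allowed.
* **Strategy of a mixed group.** The cell-count-weighted mean of bin
  centers; the admissible region is convex, so the mean needs no projection
  (a clamp guards floating-point edges).

### Parameter defaults

`sim_params()` ships a documented working set: $m = 1$, $\gamma = 0.1$,
$\mu = 0$, $K_{\text{cells}} = 100$, $B_0 = 0.01$, $\sigma = 0$,
$K_{\text{total}} = 10^4$, $\nu = 0$. The cost $\gamma = 0.1$ is a
representative moderate cost, not a canonical value — set it explicitly
for production runs. $K_{\text{total}}$ deserves a note: the community
holds roughly $B_0 \cdot E[G_{\text{offspring}}] \cdot K_{\text{total}}$
cells at stationarity, so low-output modes such as binary fission
($E[G_{\text{offspring}}] \approx 1.5$) need a large $K_{\text{total}}$ to
keep more than a handful of groups alive. Experiments that compare
archetypes on an equal footing (the meltdown/rescue and
maximum-mutation-rate protocols below) therefore use
$K_{\text{total}} = 10^5$, at which a binary-fission community still holds
on the order of fifteen groups rather than one or two.

## Experiment protocols

* `strategy_scan()` runs the simulator over a grid of admissible $(s,n)$
  points and tabulates steady-state productivity $N_{\text{total}}$, group
  count and wild-type fraction (inadmissible points are flagged, excluded
  runs are flagged, nothing is dropped silently).
* `max_mutation_rate()` starts each replicate at $\mu = 1$ and descends a
  geometric schedule (default ratio $10^{-1/4}$ down to $10^{-4}$) until
  the community first reaches a non-zero steady state; that $\mu$ is the
  replicate's $\mu_{\max}$, aggregated as the mean of $\log_{10}
  \mu_{\max}$ across replicates. Persisting at the top of the schedule is
  flagged `ceiling`; never persisting, `below_floor`. When summarizing
  across strategies, below-floor replicates are censored at one decade
  below the schedule floor.
* `sensitivity_sweep()` repeats the protocol along a $\sigma$ or $\nu$
  axis; `neighbour_average()` smooths a grid table over admissible
  von-Neumann neighbours.
* `simulate_evolution()` runs the trait-resolved dynamics and records the
  community mean $(s,n)$ every time unit plus full trait histograms at a
  configurable cadence.

## Validation oracles

Built before the engine was trusted, and independent of it
(`validate_oracles()` runs them all):

* the truncated-Poisson sampler against the analytic renormalized pmf
  (chi-square, rare cells pooled);
* the fragmentation kernel against an exhaustive enumeration of all
  $(N_{\text{offspring}}, S_{\text{offspring}})$ pairs mapped to partition
  shapes (total-variation distance; the bound scales as the $1/\sqrt{n}$
  sampling floor of the TV statistic, 0.01 at $10^5$ draws);
* the without-replacement cell sampler against an enumerated
  hypergeometric probability;
* the time-averaged size of an isolated group against the *exact*
  stationary law of its birth–death chain
  (`single_group_stationary_mean()`). The deterministic balance
  $(1-\gamma)K_{\text{cells}}$ is that law's large-capacity limit;
  demographic noise depresses the true mean by roughly
  $\mathrm{Var}(N)/N^* \approx 1$ cell at $K_{\text{cells}} = 100$, and
  multi-species groups carry a further composition-fluctuation correction
  of order $(m-1)/K_{\text{cells}}$ — one to three cells at the default
  size — because the partner-product birth rate is concave in the species
  shares. The species-invariance of the equilibrium is therefore exact in
  the deterministic limit and holds at the few-percent level in
  simulation; tests check the $m = 1$ mean against the exact law at three
  standard errors and the cross-$m$ agreement within 5% of the balance
  point.

## Desk-scale study conditions

The test suite replicates the model's qualitative results at reduced size
(one CPU, minutes instead of cluster-days). Conditions, chosen once:

| experiment | conditions |
|---|---|
| mean-field recovery | single group, $K_{\text{cells}} = 100$, $\mu = 0$, no group events, $t \le 2000$, 5 seeds per $m \in \{1,2,3\}$ |
| meltdown / rescue | 20 groups, $K_{\text{cells}} = 50$, $\gamma = \mu = 0.1$; meltdown with group events off; rescue with $B_0 = 0.01$, $K_{\text{total}} = 10^5$, complete fragmentation $(0.02, 0.98)$, 10 replicates each |
| $\mu_{\max}$ ordering ($m=1$) | same community; schedule ratio $10^{-1/2}$ to $10^{-4}$, 5 replicates, complete fragmentation vs binary fission |
| productivity transect | $m \in \{1,3\}$, $\mu = 0$, $K_{\text{total}} = 2\times10^4$, 6 points along $n = 1 - s$, 2 replicates |
| $\sigma$ / $\nu$ rescue ($m=2$) | $K_{\text{total}} = 10^4$, schedule floor $10^{-3}$, 3 replicates; $\sigma \in \{0, 1\}$, $\nu \in \{0, 0.01\}$ |
| evolution direction | $\mu = 0$, $\mu_s = \mu_n = 10^{-2}$, $t = 4000$, 5 seeds; $\sigma = 0$ ($m=1$, start $(0.35, 0.65)$) vs $\sigma = 1$ ($m=2$, start $(0.1, 0.9)$) |

Two aspects of these conditions matter for interpretation. First, with
$B_0 = 0.01$ a fission event releases an entire cohort of offspring at
once, so a community whose equilibrium group number is comparable to one
cohort lives on a handful of independent lineages and can die by
demographic accident alone; $K_{\text{total}}$ must be chosen with that in
mind (see above), and low-output strategies at desk scale always sit
closer to this drift threshold than their full-scale counterparts.
Second, the evolution runs use $\mu = 0$: the attractor of the
fragmentation mode is set by group-level productivity differences, which
exist without cheaters, and dropping cheater dynamics removes a large
extinction risk from small evolving communities. The directional claims
(toward complete fragmentation at $\sigma = 0$, toward binary fission with
$m = 2$ and strong size-dependent fission) are what the scaled runs test.

## What the simulations do and do not emulate

The generator produces the model's own idealized data: well-mixed groups
(no spatial assortment, hence no associative splitting), homogeneous
offspring sizes, linear rate functions, a single global competition term,
and memoryless migration of single cells. Passing tests therefore show
that the implementation realizes this stochastic process faithfully at
reduced scale — not that real biofilms behave this way, nor that results
at cluster-scale parameterizations (hundreds of groups of hundreds of
cells, $10^6$ time units of trait evolution, fine strategy grids) are
reproduced quantitatively. Known limitations: equilibrium quantities for
low-fission-output strategies are drift-dominated at desk scale; the
steady-state detector can take several thousand time units to fire near
criticality, so scan runs cut at `t_max` report trailing-window means and
carry the `excluded` flag; and the trait grid's 0.05 resolution bounds how
sharply evolutionary endpoints can localize.
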