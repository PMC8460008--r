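// Compiled core of the two-level (cell / group) Gillespie simulator.
//
// All randomness goes through R's RNG (unif_rand / exp_rand / R::rhyper),
// so a single set.seed() on the R side fully determines a run.
//
// State layout: a group is a flat integer census of length 2 * m * nbins,
// indexed ((type * m) + species) * nbins + bin, with type 0 = wild-type
// (cooperator) and type 1 = mutant (cheater). In fixed-strategy mode
// nbins == 1; in evolution mode bins are the admissible cells of the
// discretized (s, n) phenotype grid.
//
// Group order carries no meaning (extinction is uniform, migration targets
// are uniform), so groups are removed by swap-with-last; event selection
// uses block-partial sums of the per-group channel totals, giving
// O(G / 64 + 64) sampling with O(1) updates.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- truncated
// Poisson on {1..max_support}: P(k) proportional to lambda^k / k!
// (log-space weights; support sizes here are group sizes, i.e. small).
static int rtpois_one(double lambda, int max_support) {
  if (max_support < 1) stop("max_support must be >= 1");
  if (!(lambda > 0)) stop("lambda must be > 0");
  if (max_support == 1) return 1;
  std::vector<double> w(max_support);
  const double ll = std::log(lambda);
  double mx = R_NegInf;
  for (int k = 1; k <= max_support; ++k) {
    w[k - 1] = k * ll - R::lgammafn(k + 1.0);
    if (w[k - 1] > mx) mx = w[k - 1];
  }
  double tot = 0.0;
  for (int k = 0; k < max_support; ++k) {
    w[k] = std::exp(w[k] - mx);
    tot += w[k];
  }
  double u = unif_rand() * tot;
  for (int k = 0; k < max_support; ++k) {
    u -= w[k];
    if (u <= 0) return k + 1;
  }
  return max_support;
}

// [[Rcpp::export]]
IntegerVector rtpois_cpp(int n, double lambda, int max_support) {
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtpois_one(lambda, max_support);
  return out;
}

// ------------------------------------------------- multivariate hypergeometric
// Draw k cells without replacement from a per-category census, by sequential
// conditional univariate hypergeometric draws.
static std::vector<int> mvhyper(const std::vector<int>& census, int k) {
  const int nc = (int)census.size();
  std::vector<int> drawn(nc, 0);
  int total = 0;
  for (int i = 0; i < nc; ++i) total += census[i];
  if (k > total) stop("cannot draw more cells than the census holds");
  int rem_after = total;
  for (int i = 0; i < nc && k > 0; ++i) {
    rem_after -= census[i];
    if (census[i] == 0) continue;
    int x;
    if (rem_after == 0) {
      x = k;
    } else {
      x = (int)R::rhyper((double)census[i], (double)rem_after, (double)k);
    }
    drawn[i] = x;
    k -= x;
  }
  return drawn;
}

// [[Rcpp::export]]
IntegerVector sample_census_cpp(IntegerVector census, int k) {
  std::vector<int> c(census.begin(), census.end());
  std::vector<int> d = mvhyper(c, k);
  return IntegerVector(d.begin(), d.end());
}

// ------------------------------------------------------------- fragmentation
// Split a parent census according to strategy (s, n):
//   N_offspring  ~ truncPois(n * N, {1..N})
//   S_offspring  ~ truncPois(s * N, {1..N_offspring})
//   G_offspring  = ceil(N_offspring / S_offspring)
// The first G_offspring - 1 offspring get exactly S_offspring cells, the last
// gets the remainder; cells are sampled without replacement. If the parent is
// left empty, the last offspring group is relabelled as the parent.
struct FragResult {
  std::vector<int> parent;
  std::vector<std::vector<int> > offspring;
  int n_off, s_off, g_off;
  bool relabelled;
};

static FragResult fragment_core(const std::vector<int>& census, double s, double n,
                                int force_n, int force_s) {
  FragResult res;
  int N = 0;
  for (size_t i = 0; i < census.size(); ++i) N += census[i];
  if (N < 1) stop("cannot fragment an empty group");
  res.parent = census;
  res.n_off = (force_n > 0) ? force_n : rtpois_one(n * N, N);
  res.s_off = (force_s > 0) ? force_s : rtpois_one(s * N, res.n_off);
  if (res.n_off > N) stop("N_offspring exceeds group size");
  if (res.s_off > res.n_off) stop("S_offspring exceeds N_offspring");
  res.g_off = (res.n_off + res.s_off - 1) / res.s_off;  // ceil
  for (int g = 0; g < res.g_off; ++g) {
    int size = (g < res.g_off - 1) ? res.s_off
                                   : res.n_off - (res.g_off - 1) * res.s_off;
    std::vector<int> d = mvhyper(res.parent, size);
    for (size_t i = 0; i < res.parent.size(); ++i) res.parent[i] -= d[i];
    res.offspring.push_back(d);
  }
  int left = 0;
  for (size_t i = 0; i < res.parent.size(); ++i) left += res.parent[i];
  res.relabelled = false;
  if (left == 0) {  // all cells transmitted: relabel last offspring as parent
    res.parent = res.offspring.back();
    res.offspring.pop_back();
    res.relabelled = true;
  }
  return res;
}

// [[Rcpp::export]]
List fragment_census_cpp(IntegerVector census, double s, double n,
                         int force_n_offspring = -1, int force_s_offspring = -1) {
  std::vector<int> c(census.begin(), census.end());
  FragResult res = fragment_core(c, s, n, force_n_offspring, force_s_offspring);
  List off(res.offspring.size());
  for (size_t i = 0; i < res.offspring.size(); ++i)
    off[i] = IntegerVector(res.offspring[i].begin(), res.offspring[i].end());
  return List::create(
    _["parent"] = IntegerVector(res.parent.begin(), res.parent.end()),
    _["offspring"] = off,
    _["n_offspring"] = res.n_off,
    _["s_offspring"] = res.s_off,
    _["g_offspring"] = res.g_off,
    _["parent_relabelled"] = res.relabelled);
}

// ------------------------------------------------------------------- engine
struct Params {
  int m;
  double gamma, mu, k_cells, b0, sigma, k_total, nu, mu_s, mu_n;
  int death_variant;  // 0 = density-dependent, 1 = constant with forced fission
};

struct Group {
  std::vector<int> cnt;          // flat census
  std::vector<int> wt, mut;      // per-species caches
  int N;
  double sumS, sumN;             // trait sums over cells (evolution mode)
};

struct Channels {
  double bwt, bmut, death, mig, fiss, tot;
};

#define BLOCK 64

struct Engine {
  Params par;
  int m, nb;
  bool evolution;
  double s_fix, n_fix;
  std::vector<double> bin_s, bin_n;     // bin-center traits (length nb)
  std::vector<std::vector<int> > moves; // nb x 4: s_up, s_down, n_up, n_down
  std::vector<Group> grp;
  std::vector<Channels> ch;
  std::vector<double> grate;   // per-group channel total (= ch[i].tot)
  std::vector<double> bsum;    // block partial sums of grate
  long long ntot;              // community cell count
  // event tallies
  double ev_birth_wt, ev_birth_mut, ev_mutation, ev_death, ev_migration,
         ev_fission, ev_extinction, ev_forced_fission, ev_extinction_cells;

  int G() const { return (int)grp.size(); }

  void refresh_cache(Group& g) {
    g.wt.assign(m, 0);
    g.mut.assign(m, 0);
    g.N = 0;
    g.sumS = 0.0;
    g.sumN = 0.0;
    for (int t = 0; t < 2; ++t)
      for (int j = 0; j < m; ++j)
        for (int b = 0; b < nb; ++b) {
          int c = g.cnt[(t * m + j) * nb + b];
          if (!c) continue;
          if (t == 0) g.wt[j] += c; else g.mut[j] += c;
          g.N += c;
          g.sumS += c * bin_s[b];
          g.sumN += c * bin_n[b];
        }
  }

  // per-capita mutant birth rate of species j in group g
  double bmut_rate(const Group& g, int j) const {
    double N = (double)g.N;
    if (m == 1) return g.wt[0] / N;
    double r = std::pow((double)m, m - 1);
    for (int k = 0; k < m; ++k)
      if (k != j) r *= g.wt[k] / N;
    return r;
  }

  Channels group_channels(const Group& g, int Gnow) const {
    Channels c;
    c.bwt = 0.0; c.bmut = 0.0;
    for (int j = 0; j < m; ++j) {
      double b = bmut_rate(g, j);
      if (b > 0) {
        c.bwt += g.wt[j] * (1.0 - par.gamma) * b;
        c.bmut += g.mut[j] * b;
      }
    }
    double d = (par.death_variant == 0) ? g.N / par.k_cells : 1.0 / par.k_cells;
    c.death = g.N * d;
    c.mig = (Gnow > 1) ? g.N * par.nu : 0.0;
    c.fiss = par.b0 + par.sigma * g.N / par.k_cells;
    c.tot = c.bwt + c.bmut + c.death + c.mig + c.fiss;
    return c;
  }

  void set_grate(int i, double v) {
    bsum[i / BLOCK] += v - grate[i];
    grate[i] = v;
  }

  void update_group(int i) {
    ch[i] = group_channels(grp[i], G());
    set_grate(i, ch[i].tot);
  }

  void rebuild_sums() {
    bsum.assign((grp.size() + BLOCK - 1) / BLOCK + 1, 0.0);
    for (int i = 0; i < G(); ++i) bsum[i / BLOCK] += grate[i];
  }

  void recompute_all() {
    int n = G();
    ch.resize(n);
    grate.resize(n);
    ntot = 0;
    for (int i = 0; i < n; ++i) {
      ch[i] = group_channels(grp[i], n);
      grate[i] = ch[i].tot;
      ntot += grp[i].N;
    }
    rebuild_sums();
  }

  double rate_sum() const {
    double s = 0.0;
    for (size_t b = 0; b < bsum.size(); ++b) s += bsum[b];
    return s;
  }

  void append_group(Group&& g) {
    grp.push_back(std::move(g));
    int i = G() - 1;
    ch.push_back(group_channels(grp[i], G()));
    grate.push_back(0.0);
    if ((size_t)(i / BLOCK) >= bsum.size()) bsum.push_back(0.0);
    set_grate(i, ch[i].tot);
    ntot += grp[i].N;
  }

  // swap-with-last removal; ntot must already reflect the group's cells
  void drop_group(int i) {
    int last = G() - 1;
    ntot -= grp[i].N;
    set_grate(i, 0.0);
    if (i != last) {
      grp[i] = std::move(grp[last]);
      ch[i] = ch[last];
      set_grate(i, grate[last]);
    }
    set_grate(last, 0.0);
    grp.pop_back();
    ch.pop_back();
    grate.pop_back();
    if (G() == 1 && par.nu > 0) update_group(0);  // migration gating
  }

  // sample a group index proportional to grate, given u in [0, rate_sum)
  int pick_group(double u) const {
    size_t nb_ = bsum.size();
    for (size_t b = 0; b < nb_; ++b) {
      if (u < bsum[b]) {
        int lo = (int)b * BLOCK;
        int hi = std::min(lo + BLOCK, G());
        for (int i = lo; i < hi; ++i) {
          u -= grate[i];
          if (u < 0) return i;
        }
        return hi - 1;
      }
      u -= bsum[b];
    }
    return G() - 1;
  }

  // pick a bin within the (type, species) slice, proportional to counts
  int pick_bin(const Group& g, int type, int species) const {
    int base = (type * m + species) * nb;
    if (nb == 1) return 0;
    int tot = (type == 0) ? g.wt[species] : g.mut[species];
    double u = unif_rand() * (double)tot;
    int last = 0;
    for (int b = 0; b < nb; ++b) {
      if (g.cnt[base + b] == 0) continue;
      last = b;
      u -= g.cnt[base + b];
      if (u <= 0) return b;
    }
    return last;
  }

  // pick a uniform cell: (type, species) via cached counts, then a bin
  int pick_cell_uniform(const Group& g) const {
    double u = unif_rand() * (double)g.N;
    int type = 0, species = 0;
    bool found = false;
    for (int t = 0; t < 2 && !found; ++t)
      for (int j = 0; j < m; ++j) {
        int cnt = (t == 0) ? g.wt[j] : g.mut[j];
        if (cnt == 0) continue;
        type = t; species = j;  // last non-empty slice: drift fallback
        u -= cnt;
        if (u < 0) { found = true; break; }
      }
    int b = pick_bin(g, type, species);
    return (type * m + species) * nb + b;
  }

  void add_cell(Group& g, int idx) {
    g.cnt[idx]++;
    int b = idx % nb, j = (idx / nb) % m, t = idx / (nb * m);
    if (t == 0) g.wt[j]++; else g.mut[j]++;
    g.N++;
    g.sumS += bin_s[b];
    g.sumN += bin_n[b];
    ntot++;
  }

  void del_cell(Group& g, int idx) {
    g.cnt[idx]--;
    int b = idx % nb, j = (idx / nb) % m, t = idx / (nb * m);
    if (t == 0) g.wt[j]--; else g.mut[j]--;
    g.N--;
    g.sumS -= bin_s[b];
    g.sumN -= bin_n[b];
    ntot--;
  }

  // mutate the trait bin of a newborn (adjacent-bin moves, precomputed
  // boundary projection along n)
  int mutate_bin(int b) const {
    if (par.mu_s > 0 && unif_rand() < par.mu_s)
      b = moves[b][unif_rand() < 0.5 ? 0 : 1];
    if (par.mu_n > 0 && unif_rand() < par.mu_n)
      b = moves[b][unif_rand() < 0.5 ? 2 : 3];
    return b;
  }

  void do_fission(int i) {
    Group& g = grp[i];
    double s = s_fix, n = n_fix;
    if (evolution) {  // emergent group strategy = cell-mean trait, projected
      s = g.sumS / g.N;
      n = g.sumN / g.N;
      if (n < s) n = s;
      if (n > 1.0 - s) n = 1.0 - s;
    }
    bool was_single = (G() == 1);
    FragResult res = fragment_core(g.cnt, s, n, -1, -1);
    long long moved = 0;
    for (size_t k = 0; k < res.offspring.size(); ++k)
      for (size_t c = 0; c < res.offspring[k].size(); ++c)
        moved += res.offspring[k][c];
    g.cnt = res.parent;
    refresh_cache(g);
    ntot -= moved;   // re-added as offspring groups are appended
    update_group(i);
    for (size_t k = 0; k < res.offspring.size(); ++k) {
      Group ng;
      ng.cnt = std::move(res.offspring[k]);
      refresh_cache(ng);
      append_group(std::move(ng));
    }
    // a 1 -> many transition opens the migration channel for the parent
    if (was_single && par.nu > 0 && G() > 1) update_group(i);
  }

  // constant-death variant: groups fission the moment they reach K_cells
  void maybe_force_fission(int i) {
    if (par.death_variant == 1 && grp[i].N >= (int)par.k_cells) {
      ev_forced_fission += 1;
      do_fission(i);
    }
  }
};

static Params params_from_list(List par) {
  Params p;
  p.m = as<int>(par["m"]);
  p.gamma = as<double>(par["gamma"]);
  p.mu = as<double>(par["mu"]);
  p.k_cells = as<double>(par["k_cells"]);
  p.b0 = as<double>(par["b0"]);
  p.sigma = as<double>(par["sigma"]);
  p.k_total = as<double>(par["k_total"]);
  p.nu = as<double>(par["nu"]);
  p.mu_s = as<double>(par["mu_s"]);
  p.mu_n = as<double>(par["mu_n"]);
  p.death_variant = as<int>(par["death_variant"]);
  return p;
}

// From-scratch per-group channel-rate table (audit surface; compares against
// the R-level rate functions and against the engine's cached rates).
// [[Rcpp::export]]
NumericMatrix rate_table_cpp(List groups, List par, int nbins) {
  Engine e;
  e.par = params_from_list(par);
  e.m = e.par.m;
  e.nb = nbins;
  e.evolution = false;
  e.bin_s.assign(nbins, 0.0);
  e.bin_n.assign(nbins, 0.0);
  int G = groups.size();
  NumericMatrix out(G, 6);
  colnames(out) = CharacterVector::create("birth_wt", "birth_mut", "death",
                                          "migration", "fission", "total");
  std::vector<Group> gs(G);
  for (int i = 0; i < G; ++i) {
    IntegerVector cv = groups[i];
    gs[i].cnt.assign(cv.begin(), cv.end());
    e.refresh_cache(gs[i]);
  }
  for (int i = 0; i < G; ++i) {
    Channels c = e.group_channels(gs[i], G);
    out(i, 0) = c.bwt; out(i, 1) = c.bmut; out(i, 2) = c.death;
    out(i, 3) = c.mig; out(i, 4) = c.fiss; out(i, 5) = c.tot;
  }
  return out;
}

// Run the Gillespie process from t0 until t_end (or extinction / event
// guard), emitting one sample row per integer time (state at the last event
// before the boundary). Returns the samples, the final group censuses, the
// final clock, a status code and event tallies.
// status: 0 reached t_end, 1 extinct, 2 event-guard hit, 3 frozen (R == 0).
// [[Rcpp::export]]
List run_chunk_cpp(List groups_in, double t0, double t_end, List par,
                   double s_fix, double n_fix, bool evolution,
                   NumericVector bin_s, NumericVector bin_n,
                   IntegerMatrix trait_moves, double max_events) {
  Engine e;
  e.par = params_from_list(par);
  e.m = e.par.m;
  e.nb = bin_s.size();
  e.evolution = evolution;
  e.s_fix = s_fix;
  e.n_fix = n_fix;
  e.bin_s.assign(bin_s.begin(), bin_s.end());
  e.bin_n.assign(bin_n.begin(), bin_n.end());
  e.moves.assign(e.nb, std::vector<int>(4, 0));
  if (evolution) {
    if (trait_moves.nrow() != e.nb || trait_moves.ncol() != 4)
      stop("trait_moves must be nbins x 4");
    for (int b = 0; b < e.nb; ++b)
      for (int k = 0; k < 4; ++k) e.moves[b][k] = trait_moves(b, k);
  }
  int G0 = groups_in.size();
  e.grp.resize(G0);
  for (int i = 0; i < G0; ++i) {
    IntegerVector cv = groups_in[i];
    if ((int)cv.size() != 2 * e.m * e.nb) stop("census length mismatch");
    e.grp[i].cnt.assign(cv.begin(), cv.end());
    e.refresh_cache(e.grp[i]);
  }
  e.recompute_all();
  e.ev_birth_wt = e.ev_birth_mut = e.ev_mutation = e.ev_death = 0;
  e.ev_migration = e.ev_fission = e.ev_extinction = e.ev_forced_fission = 0;
  e.ev_extinction_cells = 0;

  const int ncol = 5 + e.m + 2;
  std::vector<double> rows;  // appended sample rows
  double time = t0;
  double next_sample = std::floor(t0) + 1.0;
  int status = 0;
  double n_events = 0.0;
  long long resync = 0;

  RNGScope scope;

  while (true) {
    int G = e.G();
    if (G == 0) { status = 1; break; }
    double rsum = e.rate_sum();
    double D = (e.par.k_total > 0 && R_finite(e.par.k_total))
                 ? (double)e.ntot / e.par.k_total : 0.0;
    double R = rsum + G * D;
    if (!(R > 0)) { status = 3; break; }
    double dt = exp_rand() / R;
    double tnew = time + dt;
    // emit samples for integer boundaries passed by this waiting time
    while (next_sample <= tnew && next_sample <= t_end + 1e-12) {
      double wtT = 0, mutT = 0, sS = 0, sN = 0;
      std::vector<double> sp(e.m, 0.0);
      for (int i = 0; i < G; ++i) {
        for (int j = 0; j < e.m; ++j) {
          wtT += e.grp[i].wt[j];
          mutT += e.grp[i].mut[j];
          sp[j] += e.grp[i].wt[j] + e.grp[i].mut[j];
        }
        sS += e.grp[i].sumS;
        sN += e.grp[i].sumN;
      }
      rows.push_back(next_sample);
      rows.push_back((double)G);
      rows.push_back((double)e.ntot);
      rows.push_back(wtT);
      rows.push_back(mutT);
      for (int j = 0; j < e.m; ++j) rows.push_back(sp[j]);
      double NT = (double)e.ntot;
      rows.push_back(NT > 0 ? sS / NT : NA_REAL);
      rows.push_back(NT > 0 ? sN / NT : NA_REAL);
      next_sample += 1.0;
    }
    if (tnew > t_end) { time = t_end; break; }
    time = tnew;

    // ------------------------------------------------ select and apply event
    double u = unif_rand() * R;
    if (u < rsum) {
      // per-group channel
      int gi = e.pick_group(u);
      Channels& c = e.ch[gi];
      double v = unif_rand() * c.tot;
      if (v < c.bwt + c.bmut) {
        bool wt_parent = v < c.bwt;
        Group& g = e.grp[gi];
        // choose species proportional to its share of the channel
        double w = unif_rand() * (wt_parent ? c.bwt : c.bmut);
        int j = -1;
        double cc = 0.0;
        for (int k = 0; k < e.m; ++k) {
          double b = e.bmut_rate(g, k);
          double term = wt_parent ? g.wt[k] * (1.0 - e.par.gamma) * b
                                  : g.mut[k] * b;
          if (term <= 0) continue;
          j = k;  // last positive-weight species: drift fallback
          cc += term;
          if (w < cc) break;
        }
        if (j < 0) continue;  // channel weight vanished between updates
        int pb = e.pick_bin(g, wt_parent ? 0 : 1, j);
        int ctype = wt_parent ? 0 : 1;
        if (wt_parent && e.par.mu > 0 && unif_rand() < e.par.mu) {
          ctype = 1;  // mutation at birth; no back-mutation
          e.ev_mutation += 1;
        }
        int cb = evolution ? e.mutate_bin(pb) : pb;
        e.add_cell(g, (ctype * e.m + j) * e.nb + cb);
        if (wt_parent) e.ev_birth_wt += 1; else e.ev_birth_mut += 1;
        e.update_group(gi);
        e.maybe_force_fission(gi);
      } else if (v < c.bwt + c.bmut + c.death) {
        Group& g = e.grp[gi];
        int idx = e.pick_cell_uniform(g);
        e.del_cell(g, idx);
        e.ev_death += 1;
        if (g.N == 0) e.drop_group(gi); else e.update_group(gi);
      } else if (v < c.bwt + c.bmut + c.death + c.mig) {
        // migration: uniform cell leaves, joins a uniform other group
        int idx = e.pick_cell_uniform(e.grp[gi]);
        int dest = (int)(unif_rand() * (G - 1));
        if (dest >= gi) dest++;
        if (dest >= G) dest = G - 1;
        e.del_cell(e.grp[gi], idx);
        e.add_cell(e.grp[dest], idx);
        e.ev_migration += 1;
        if (e.grp[gi].N == 0) {
          e.update_group(dest);
          e.drop_group(gi);
          if (dest == G - 1) dest = gi;  // dest was swapped into slot gi
        } else {
          e.update_group(gi);
          e.update_group(dest);
        }
        e.maybe_force_fission(dest);
      } else {
        e.ev_fission += 1;
        e.do_fission(gi);
      }
    } else {
      // extinction: every group has the same rate D
      int gi = (int)(unif_rand() * G);
      if (gi >= G) gi = G - 1;
      e.ev_extinction += 1;
      e.ev_extinction_cells += e.grp[gi].N;
      e.drop_group(gi);
    }

    n_events += 1.0;
    if (++resync % 262144 == 0) e.recompute_all();  // damp float drift
    if (n_events >= max_events) { status = 2; break; }
  }

  int nr = (int)(rows.size() / ncol);
  NumericMatrix samples(nr, ncol);
  for (int r = 0; r < nr; ++r)
    for (int c2 = 0; c2 < ncol; ++c2) samples(r, c2) = rows[r * ncol + c2];
  List gout(e.grp.size());
  for (size_t i = 0; i < e.grp.size(); ++i)
    gout[i] = IntegerVector(e.grp[i].cnt.begin(), e.grp[i].cnt.end());
  NumericVector ev = NumericVector::create(
    _["birth_wt"] = e.ev_birth_wt, _["birth_mut"] = e.ev_birth_mut,
    _["mutation"] = e.ev_mutation, _["death"] = e.ev_death,
    _["migration"] = e.ev_migration, _["fission"] = e.ev_fission,
    _["extinction"] = e.ev_extinction,
    _["forced_fission"] = e.ev_forced_fission,
    _["extinction_cells"] = e.ev_extinction_cells);
  return List::create(
    _["samples"] = samples, _["groups"] = gout, _["time"] = time,
    _["status"] = status, _["events"] = ev, _["n_events"] = n_events);
}
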