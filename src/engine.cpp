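// Forward-time haploid Wright-Fisher engine with a continuous linear map.
//
// The population is N haploid genomes; a genome is a sorted vector of indices
// into a shared mutation registry (only one copy of each mutation is stored).
// Each generation: fitness-proportional polygamous pairing (both parents drawn
// independently, selfing allowed), one offspring per pair built from a Poisson
// number of uniformly placed crossovers, Poisson(N*U) new mutations, then
// registry counts are refreshed and fixed/lost mutations retired.  All
// randomness comes from R's RNG so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Registry {
  std::vector<double> pos, s, t_origin, t_fate;
  std::vector<int> count;
  // fate: 0 segregating, 1 fixed, 2 lost
  std::vector<int> fate;
  std::vector<int> active;  // segregating ids

  int add(double p, double sel, int gen) {
    pos.push_back(p);
    s.push_back(sel);
    t_origin.push_back(gen);
    t_fate.push_back(NA_REAL);
    count.push_back(0);
    fate.push_back(0);
    int id = (int)pos.size() - 1;
    active.push_back(id);
    return id;
  }
};

typedef std::vector<std::vector<int> > Genomes;

// Weighted parent draw via binary search on the cumulative fitness.
inline int draw_parent(const std::vector<double>& cumw) {
  double u = unif_rand() * cumw.back();
  return (int)(std::upper_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

// Offspring from two parents given sorted crossover points on [0, R).
// Segments alternate between parents starting with `cur` (0 = a, 1 = b).
void make_offspring(const std::vector<int>& ga, const std::vector<int>& gb,
                    const Registry& reg, const std::vector<double>& cross,
                    int cur, std::vector<int>& out) {
  out.clear();
  size_t ia = 0, ib = 0;
  for (size_t c = 0; c <= cross.size(); ++c) {
    double hi = (c < cross.size()) ? cross[c] : std::numeric_limits<double>::infinity();
    // advance both parents through [lo, hi), copying from the current one
    while (ia < ga.size() && reg.pos[ga[ia]] < hi) {
      if (cur == 0) out.push_back(ga[ia]);
      ++ia;
    }
    while (ib < gb.size() && reg.pos[gb[ib]] < hi) {
      if (cur == 1) out.push_back(gb[ib]);
      ++ib;
    }
    cur = 1 - cur;

  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_sim(int N, double U, double R_len, int effect_model, double s_par,
                 int generations, double fitness_noise_sd, bool record_traj,
                 int traj_stride, double marker_pos, int paint_gen,
                 bool stop_at_marker_fixation,
                 Nullable<DataFrame> init_muts = R_NilValue) {
  if (N < 2) stop("N must be >= 2");
  Registry reg;
  Genomes pop(N), off(N);
  std::vector<int> marker(N, -1), marker_off(N, -1);
  bool painted = false;

  // optional standing variation: columns position, s, count
  if (init_muts.isNotNull()) {
    DataFrame im(init_muts);
    NumericVector ip = im["position"], is = im["s"];
    IntegerVector ic = im["count"];
    for (int m = 0; m < ip.size(); ++m) {
      int id = reg.add(ip[m], is[m], 0);
      // assign to `count` distinct genomes chosen uniformly
      std::vector<int> idx(N);
      for (int i = 0; i < N; ++i) idx[i] = i;
      for (int k = 0; k < ic[m]; ++k) {
        int j = k + (int)(unif_rand() * (N - k));
        std::swap(idx[k], idx[j]);
        std::vector<int>& g = pop[idx[k]];
        g.insert(std::upper_bound(g.begin(), g.end(), id,
                                  [&](int a, int b) { return reg.pos[a] < reg.pos[b]; }),
                 id);
      }
      reg.count[id] = ic[m];
    }
  }

  double fixed_logw = 0.0;
  std::vector<double> logw(N), w(N), cumw(N);

  // per-generation outputs
  std::vector<double> gs_mean, gs_var;
  std::vector<int> gs_gen, gs_nseg;
  std::vector<int> tr_id, tr_gen, tr_count;
  std::vector<int> het_gen, het_nallele;
  std::vector<double> het_H;

  std::vector<double> cross;
  std::vector<int> scratch_count(N, 0);

  int gen = 0;
  for (gen = 1; gen <= generations; ++gen) {
    // paint unique neutral markers at the start of the requested generation
    if (!painted && marker_pos >= 0 && gen == paint_gen) {
      for (int i = 0; i < N; ++i) marker[i] = i;
      painted = true;
      het_gen.push_back(gen - 1);
      het_H.push_back(1.0 - 1.0 / N);
      het_nallele.push_back(N);
    }

    // heritable log fitness from segregating mutations (fixed factors cancel)
    double mx = -1e300;
    for (int i = 0; i < N; ++i) {
      double lw = 0.0;
      const std::vector<int>& g = pop[i];
      for (size_t k = 0; k < g.size(); ++k) lw += std::log1p(reg.s[g[k]]);
      logw[i] = lw;
      if (lw > mx) mx = lw;
    }
    // generation stats recorded before reproduction (exclude noise)
    {
      double m = 0.0, v = 0.0;
      for (int i = 0; i < N; ++i) m += logw[i];
      m /= N;
      for (int i = 0; i < N; ++i) v += (logw[i] - m) * (logw[i] - m);
      v /= N;
      gs_gen.push_back(gen - 1);
      gs_mean.push_back(m + fixed_logw);
      gs_var.push_back(v);
      gs_nseg.push_back((int)reg.active.size());
    }
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      double wi = std::exp(logw[i] - mx);
      if (fitness_noise_sd > 0) wi *= std::exp(norm_rand() * fitness_noise_sd);
      w[i] = wi;
      tot += wi;
      cumw[i] = tot;
    }
    if (!(tot > 0) || !std::isfinite(tot)) stop("degenerate state: total fitness is not positive");

    // N offspring, each from an independently drawn fitness-weighted pair
    for (int i = 0; i < N; ++i) {
      int a = draw_parent(cumw), b = draw_parent(cumw);
      int k = (int)R::rpois(R_len);
      if (k == 0) {
        int p = (unif_rand() < 0.5) ? a : b;
        off[i] = pop[p];
        marker_off[i] = marker[p];
      } else {
        cross.resize(k);
        for (int c = 0; c < k; ++c) cross[c] = unif_rand() * R_len;
        std::sort(cross.begin(), cross.end());
        int start = (unif_rand() < 0.5) ? 0 : 1;
        make_offspring(pop[a], pop[b], reg, cross, start, off[i]);
        if (painted) {
          // parity of crossovers left of the marker decides the contributing parent
          int nleft = (int)(std::lower_bound(cross.begin(), cross.end(), marker_pos) - cross.begin());
          int p = ((start + nleft) % 2 == 0) ? a : b;
          marker_off[i] = marker[p];
        }
      }
    }

    // new mutations: Poisson(N*U), uniform position, uniform recipient
    int M = (int)R::rpois(N * U);
    for (int m = 0; m < M; ++m) {
      double p = unif_rand() * R_len;
      double sel = (effect_model == 0) ? s_par : R::rexp(s_par);
      int id = reg.add(p, sel, gen);
      std::vector<int>& g = off[(int)(unif_rand() * N)];
      g.insert(std::upper_bound(g.begin(), g.end(), id,
                                [&](int a, int b) { return reg.pos[a] < reg.pos[b]; }),
               id);
    }

    pop.swap(off);
    marker.swap(marker_off);

    // refresh registry counts and resolve fates
    for (size_t k = 0; k < reg.active.size(); ++k) reg.count[reg.active[k]] = 0;
    for (int i = 0; i < N; ++i)
      for (size_t k = 0; k < pop[i].size(); ++k) ++reg.count[pop[i][k]];
    std::vector<int> still;
    std::vector<char> drop(reg.pos.size(), 0);
    bool any_fixed = false;
    for (size_t k = 0; k < reg.active.size(); ++k) {
      int id = reg.active[k];
      if (reg.count[id] == 0) {
        reg.fate[id] = 2;
        reg.t_fate[id] = gen;
      } else if (reg.count[id] == N) {
        reg.fate[id] = 1;
        reg.t_fate[id] = gen;
        fixed_logw += std::log1p(reg.s[id]);
        drop[id] = 1;
        any_fixed = true;
      } else {
        still.push_back(id);
      }
    }
    if (any_fixed) {
      for (int i = 0; i < N; ++i) {
        std::vector<int>& g = pop[i];
        g.erase(std::remove_if(g.begin(), g.end(), [&](int id) { return drop[id] != 0; }),
                g.end());
      }
    }
    reg.active.swap(still);

    if (record_traj && (gen % traj_stride == 0)) {
      for (size_t k = 0; k < reg.active.size(); ++k) {
        int id = reg.active[k];
        tr_id.push_back(id + 1);
        tr_gen.push_back(gen);
        tr_count.push_back(reg.count[id]);
      }
    }

    if (painted) {
      std::fill(scratch_count.begin(), scratch_count.end(), 0);
      for (int i = 0; i < N; ++i) ++scratch_count[marker[i]];
      double H = 1.0;
      int nal = 0;
      for (int a = 0; a < N; ++a) {
        double f = (double)scratch_count[a] / N;
        H -= f * f;
        if (scratch_count[a] > 0) ++nal;
      }
      het_gen.push_back(gen);
      het_H.push_back(H);
      het_nallele.push_back(nal);
      if (stop_at_marker_fixation && nal == 1) break;
    }
  }

  int n_mut = (int)reg.pos.size();
  CharacterVector fate_str(n_mut);
  for (int id = 0; id < n_mut; ++id)
    fate_str[id] = (reg.fate[id] == 0) ? "segregating" : (reg.fate[id] == 1 ? "fixed" : "lost");

  List out = List::create(
      _["mutations"] = DataFrame::create(
          _["id"] = seq_len(n_mut), _["position"] = wrap(reg.pos), _["s"] = wrap(reg.s),
          _["count"] = wrap(reg.count), _["t_origin"] = wrap(reg.t_origin),
          _["fate"] = fate_str, _["t_fate"] = wrap(reg.t_fate)),
      _["genstats"] = DataFrame::create(
          _["generation"] = wrap(gs_gen), _["mean_log_fitness"] = wrap(gs_mean),
          _["var_log_fitness"] = wrap(gs_var), _["n_segregating"] = wrap(gs_nseg)),
      _["fixed_log_fitness"] = fixed_logw,
      _["generations_run"] = std::min(gen, generations));
  if (record_traj)
    out["trajectories"] = DataFrame::create(_["id"] = wrap(tr_id), _["generation"] = wrap(tr_gen),
                                            _["count"] = wrap(tr_count));
  if (marker_pos >= 0)
    out["heterozygosity"] = DataFrame::create(_["generation"] = wrap(het_gen),
                                              _["H"] = wrap(het_H),
                                              _["n_alleles"] = wrap(het_nallele));
  return out;
}
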