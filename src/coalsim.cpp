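// Structured-coalescent core for a two-population isolation-with-migration
// model with one instantaneous size change per derived population.
//
// Conventions (documented on the R side as well):
//   * time runs backwards in generations from the present (t = 0);
//   * pop sizes are DIPLOID individuals; pairwise coalescence rate within a
//     population of size N is 1 / (2N) per pair per generation;
//   * migration rates are backward per-lineage per-generation probabilities:
//     m_back1 moves a lineage from pop1 into pop2 (forward: pop1 receives
//     from pop2), m_back2 the reverse;
//   * at T_split all lineages pool into the ancestral population of size
//     N_anc_all and migration stops;
//   * size changes are step changes: pop d has size N_cur_d on
//     [0, T_change_d) and N_anc_d on [T_change_d, T_split).
//
// Uses R's RNG so set.seed() on the R side controls everything.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Lineage {
  int pop;        // 0 or 1 (0 = ancestral pool after split)
  int c1, c2;     // descendant sample chromosomes in pop1 / pop2
  double blen;    // branch length accrued so far (generations)
};

struct Branch {
  int c1, c2;
  double blen;
};

struct Model {
  double N_cur1, N_cur2, N_anc1, N_anc2, N_anc_all;
  double T_change1, T_change2, T_split;
  double m_back1, m_back2;
};

Model model_from_list(const List& m) {
  Model mod;
  mod.N_cur1    = as<double>(m["N_cur_p1"]);
  mod.N_cur2    = as<double>(m["N_cur_p2"]);
  mod.N_anc1    = as<double>(m["N_anc_p1"]);
  mod.N_anc2    = as<double>(m["N_anc_p2"]);
  mod.N_anc_all = as<double>(m["N_anc_all"]);
  mod.T_change1 = as<double>(m["T_change_p1"]);
  mod.T_change2 = as<double>(m["T_change_p2"]);
  mod.T_split   = as<double>(m["T_split"]);
  mod.m_back1   = as<double>(m["m12"]);
  mod.m_back2   = as<double>(m["m21"]);
  return mod;
}

inline double pop_size(const Model& m, int pop, double t) {
  if (t >= m.T_split) return m.N_anc_all;
  if (pop == 1) return (t < m.T_change1) ? m.N_cur1 : m.N_anc1;
  return (t < m.T_change2) ? m.N_cur2 : m.N_anc2;
}

// next epoch boundary strictly after t (Inf if none)
inline double next_boundary(const Model& m, double t) {
  double b = R_PosInf;
  if (t < m.T_change1 && m.T_change1 < m.T_split) b = std::min(b, m.T_change1);
  if (t < m.T_change2 && m.T_change2 < m.T_split) b = std::min(b, m.T_change2);
  if (t < m.T_split) b = std::min(b, m.T_split);
  return b;
}

// Simulate one genealogy; fills `branches` with every non-root branch and
// returns the TMRCA. n1 / n2 are haploid (chromosome) sample sizes.
double sim_genealogy(const Model& m, int n1, int n2,
                     std::vector<Branch>& branches) {
  std::vector<Lineage> lin;
  lin.reserve(n1 + n2);
  for (int i = 0; i < n1; ++i) lin.push_back({1, 1, 0, 0.0});
  for (int i = 0; i < n2; ++i) lin.push_back({2, 0, 1, 0.0});
  branches.clear();
  branches.reserve(2 * (n1 + n2));

  double t = 0.0;
  bool merged = (m.T_split <= 0.0);
  if (merged) for (auto& L : lin) L.pop = 0;

  while (lin.size() > 1) {
    int k1 = 0, k2 = 0;
    for (auto& L : lin) {
      if (L.pop == 1) ++k1; else if (L.pop == 2) ++k2;
    }
    double rate_c1 = 0, rate_c2 = 0, rate_c0 = 0, rate_m1 = 0, rate_m2 = 0;
    if (!merged) {
      if (k1 >= 2) rate_c1 = k1 * (k1 - 1) / 2.0 / (2.0 * pop_size(m, 1, t));
      if (k2 >= 2) rate_c2 = k2 * (k2 - 1) / 2.0 / (2.0 * pop_size(m, 2, t));
      rate_m1 = k1 * m.m_back1;
      rate_m2 = k2 * m.m_back2;
    } else {
      int k = (int) lin.size();
      rate_c0 = k * (k - 1) / 2.0 / (2.0 * m.N_anc_all);
    }
    double total = rate_c1 + rate_c2 + rate_c0 + rate_m1 + rate_m2;
    double bnd = merged ? R_PosInf : next_boundary(m, t);

    double dt;
    if (total <= 0.0) {
      dt = R_PosInf;  // nothing can happen until the next boundary
    } else {
      dt = -std::log(unif_rand()) / total;
    }

    if (t + dt >= bnd) {
      // advance to the boundary; accrue branch length, update regimes
      double step = bnd - t;
      for (auto& L : lin) L.blen += step;
      t = bnd;
      if (t >= m.T_split && !merged) {
        merged = true;
        for (auto& L : lin) L.pop = 0;
      }
      continue;
    }

    for (auto& L : lin) L.blen += dt;
    t += dt;

    double u = unif_rand() * total;
    if (u < rate_c1 + rate_c2 + rate_c0) {
      // coalescence: pick the deme, then a random pair within it
      int pop;
      if (u < rate_c1) pop = 1;
      else if (u < rate_c1 + rate_c2) pop = 2;
      else pop = 0;
      std::vector<int> idx;
      for (int i = 0; i < (int) lin.size(); ++i)
        if (lin[i].pop == pop) idx.push_back(i);
      int a = (int) (unif_rand() * idx.size());
      int b = (int) (unif_rand() * (idx.size() - 1));
      if (b >= a) ++b;
      int ia = idx[a], ib = idx[b];
      branches.push_back({lin[ia].c1, lin[ia].c2, lin[ia].blen});
      branches.push_back({lin[ib].c1, lin[ib].c2, lin[ib].blen});
      Lineage parent{pop, lin[ia].c1 + lin[ib].c1, lin[ia].c2 + lin[ib].c2, 0.0};
      if (ia > ib) std::swap(ia, ib);
      lin.erase(lin.begin() + ib);
      lin.erase(lin.begin() + ia);
      lin.push_back(parent);
    } else {
      // migration
      int pop = (u < rate_c1 + rate_c2 + rate_c0 + rate_m1) ? 1 : 2;
      std::vector<int> idx;
      for (int i = 0; i < (int) lin.size(); ++i)
        if (lin[i].pop == pop) idx.push_back(i);
      int a = (int) (unif_rand() * idx.size());
      lin[idx[a]].pop = (pop == 1) ? 2 : 1;
    }
  }
  return t;
}

inline double total_length(const std::vector<Branch>& br) {
  double L = 0.0;
  for (auto& b : br) L += b.blen;
  return L;
}

// sample one branch with probability proportional to its length
inline int sample_branch(const std::vector<Branch>& br, double L) {
  double u = unif_rand() * L, acc = 0.0;
  for (int i = 0; i < (int) br.size(); ++i) {
    acc += br[i].blen;
    if (u <= acc) return i;
  }
  return (int) br.size() - 1;
}

}  // namespace

// One conditioned mutation per site: derived-allele chromosome counts
// (k1, k2) per site, every site polymorphic in the pooled sample.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_counts(List model, int n1, int n2, int n_sites) {
  Model m = model_from_list(model);
  IntegerMatrix out(n_sites, 2);
  std::vector<Branch> br;
  for (int s = 0; s < n_sites; ++s) {
    sim_genealogy(m, n1, n2, br);
    double L = total_length(br);
    int i = sample_branch(br, L);
    out(s, 0) = br[i].c1;
    out(s, 1) = br[i].c2;
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Poisson mutation mode: per site, S ~ Poisson(mu * total branch length),
// each mutation dropped uniformly on the tree. Returns (site, k1, k2) rows.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_poisson(List model, int n1, int n2, int n_sites,
                              double mu) {
  Model m = model_from_list(model);
  std::vector<Branch> br;
  std::vector<int> site, c1, c2;
  for (int s = 0; s < n_sites; ++s) {
    sim_genealogy(m, n1, n2, br);
    double L = total_length(br);
    int nmut = (int) R::rpois(mu * L);
    for (int j = 0; j < nmut; ++j) {
      int i = sample_branch(br, L);
      site.push_back(s + 1);
      c1.push_back(br[i].c1);
      c2.push_back(br[i].c2);
    }
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerMatrix out((int) site.size(), 3);
  for (int i = 0; i < (int) site.size(); ++i) {
    out(i, 0) = site[i];
    out(i, 1) = c1[i];
    out(i, 2) = c2[i];
  }
  return out;
}

// Genealogy summaries for closed-form checks: TMRCA and total branch length.
// [[Rcpp::export]]
NumericMatrix cpp_sim_tree_stats(List model, int n1, int n2, int n_reps) {
  Model m = model_from_list(model);
  NumericMatrix out(n_reps, 2);
  std::vector<Branch> br;
  for (int r = 0; r < n_reps; ++r) {
    double tmrca = sim_genealogy(m, n1, n2, br);
    out(r, 0) = tmrca;
    out(r, 1) = total_length(br);
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  colnames(out) = CharacterVector::create("tmrca", "total_length");
  return out;
}
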