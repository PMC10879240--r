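#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Periodic 2D lattice membrane with conservative (Kawasaki) Metropolis
// exchange dynamics. Groups are 0-based here; R wrappers use 1..7.

static inline int pmod(int a, int L) { return (a + L) % L; }

static inline double pair_energy_around(const IntegerMatrix &g,
                                        const NumericMatrix &J,
                                        int i, int j, int gi,
                                        int skip_i, int skip_j) {
  const int L = g.nrow();
  static const int di[4] = {1, -1, 0, 0};
  static const int dj[4] = {0, 0, 1, -1};
  double e = 0.0;
  for (int d = 0; d < 4; ++d) {
    int ni = pmod(i + di[d], L), nj = pmod(j + dj[d], L);
    if (ni == skip_i && nj == skip_j) continue;
    e += J(gi, g(ni, nj));
  }
  return e;
}

// One call = n_sweeps sweeps of L*L attempted neighbour exchanges.
// Modifies copies of the lattices; returns the updated state plus
// per-group attempt/acceptance counters, displacement accumulators and
// (optionally) the per-sweep total energy.
// [[Rcpp::export]]
List cpp_abm_sweeps(IntegerMatrix groups_in, IntegerMatrix agents_in,
                    NumericVector dx_in, NumericVector dy_in,
                    NumericMatrix J, double temperature, int n_sweeps,
                    bool record_energy) {
  IntegerMatrix g = clone(groups_in);
  IntegerMatrix agents = clone(agents_in);
  NumericVector dx = clone(dx_in), dy = clone(dy_in);
  const int L = g.nrow();
  const int n_groups = J.nrow();
  static const int di[4] = {1, -1, 0, 0};
  static const int dj[4] = {0, 0, 1, -1};

  NumericVector attempted(n_groups), accepted(n_groups);
  NumericVector energy_trace(record_energy ? n_sweeps : 0);

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int m = 0; m < L * L; ++m) {
      int i = (int)(unif_rand() * L); if (i == L) i = L - 1;
      int j = (int)(unif_rand() * L); if (j == L) j = L - 1;
      int d = (int)(unif_rand() * 4); if (d == 4) d = 3;
      int ni = pmod(i + di[d], L), nj = pmod(j + dj[d], L);
      int ga = g(i, j), gb = g(ni, nj);
      attempted[ga] += 1.0; attempted[gb] += 1.0;
      double dE = 0.0;
      if (ga != gb) {
        double before = pair_energy_around(g, J, i, j, ga, ni, nj) +
                        pair_energy_around(g, J, ni, nj, gb, i, j);
        double after  = pair_energy_around(g, J, i, j, gb, ni, nj) +
                        pair_energy_around(g, J, ni, nj, ga, i, j);
        dE = after - before;
      }
      bool accept = dE <= 0.0 || unif_rand() < std::exp(-dE / temperature);
      if (accept) {
        int aa = agents(i, j), ab = agents(ni, nj);
        g(i, j) = gb; g(ni, nj) = ga;
        agents(i, j) = ab; agents(ni, nj) = aa;
        // displacement in lattice units, periodically unwrapped
        dx[aa - 1] += di[d]; dy[aa - 1] += dj[d];
        dx[ab - 1] -= di[d]; dy[ab - 1] -= dj[d];
        accepted[ga] += 1.0; accepted[gb] += 1.0;
      }
    }
    if (record_energy) {
      double e = 0.0;
      for (int i = 0; i < L; ++i)
        for (int j = 0; j < L; ++j) {
          e += J(g(i, j), g(pmod(i + 1, L), j));
          e += J(g(i, j), g(i, pmod(j + 1, L)));
        }
      energy_trace[sweep] = e;
    }
  }
  return List::create(_["groups"] = g, _["agents"] = agents,
                      _["dx"] = dx, _["dy"] = dy,
                      _["attempted"] = attempted, _["accepted"] = accepted,
                      _["energy_trace"] = energy_trace);
}

// Local order parameter: fraction of raft-forming lipids among the
// 9-site Moore neighbourhood (centre included), periodic boundaries.
// [[Rcpp::export]]
NumericMatrix cpp_local_order(IntegerMatrix groups, LogicalVector is_raft_group) {
  const int L = groups.nrow();
  NumericMatrix order(L, L);
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) {
      int cnt = 0;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          if (is_raft_group[groups(pmod(i + a, L), pmod(j + b, L))]) ++cnt;
      order(i, j) = cnt / 9.0;
    }
  return order;
}

// 4-connected components of raft sites (periodic), filtered by minimum
// size. Labels are 1..n_rafts in discovery order; 0 = non-raft.
// [[Rcpp::export]]
List cpp_label_rafts(LogicalMatrix raft_sites, int min_size) {
  const int L = raft_sites.nrow();
  IntegerMatrix labels(L, L);
  std::vector<int> sizes;
  static const int di[4] = {1, -1, 0, 0};
  static const int dj[4] = {0, 0, 1, -1};
  int next = 0;
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) {
      if (!raft_sites(i, j) || labels(i, j) != 0) continue;
      ++next;
      int sz = 0;
      std::deque<std::pair<int, int> > q;
      q.push_back(std::make_pair(i, j));
      labels(i, j) = next;
      while (!q.empty()) {
        std::pair<int, int> s = q.front(); q.pop_front();
        ++sz;
        for (int d = 0; d < 4; ++d) {
          int ni = pmod(s.first + di[d], L), nj = pmod(s.second + dj[d], L);
          if (raft_sites(ni, nj) && labels(ni, nj) == 0) {
            labels(ni, nj) = next;
            q.push_back(std::make_pair(ni, nj));
          }
        }
      }
      sizes.push_back(sz);
    }
  // filter components below min_size and relabel compactly
  std::vector<int> remap(next + 1, 0);
  std::vector<int> kept;
  int nk = 0;
  for (int c = 1; c <= next; ++c) {
    if (sizes[c - 1] >= min_size) {
      remap[c] = ++nk;
      kept.push_back(sizes[c - 1]);
    }
  }
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) labels(i, j) = remap[labels(i, j)];
  return List::create(_["labels"] = labels, _["sizes"] = wrap(kept));
}
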