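#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Multi-level greedy (Louvain-style) maximisation of a multi-scale quality
// criterion on a weighted undirected graph.
//
// Two gain modes cover all supported criteria:
//   mode 0 (configuration null): gain of joining community c is
//       tfac * w_ic - gamma * d_i * S_c / twoM
//     Newman (tfac=1, gamma=1), Reichardt-Bornholdt (gamma), linearised
//     stability (tfac = t), and Arenas-Fernandez-Gomez self-loops (caller
//     passes d_i + r and twoM + n*r).
//   mode 1 (Ronhovde-Nussinov Potts): gain of joining community c is
//       w_ic - gamma * (size_i * size_c - e_ic)
//     where e_ic counts original-graph edges between i and c.
//
// Sweep order is shuffled with R's RNG (unif_rand), so set.seed() on the R
// side makes runs reproducible. Ties are broken toward the lowest community
// id. Nodes whose best gain is negative are isolated into an empty community.

static void fisher_yates(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// [[Rcpp::export(name = ".louvainRun")]]
IntegerVector louvain_run(NumericMatrix W0, NumericVector d0, double twoM,
                          NumericVector size0, int mode, double gamma,
                          double tfac) {
  const int n0 = W0.nrow();
  std::vector<int> assign(n0);            // original node -> community label
  for (int i = 0; i < n0; ++i) assign[i] = i;

  // level state
  std::vector<std::vector<double>> W(n0, std::vector<double>(n0));
  std::vector<std::vector<double>> E(n0, std::vector<double>(n0, 0.0));
  std::vector<double> d(n0), sz(n0);
  for (int i = 0; i < n0; ++i) {
    d[i] = d0[i];
    sz[i] = size0[i];
    for (int j = 0; j < n0; ++j) {
      W[i][j] = (i == j) ? 0.0 : W0(i, j);
      if (mode == 1 && i != j && W0(i, j) > 0) E[i][j] = 1.0;
    }
  }

  int n = n0;
  bool improvedLevel = true;
  while (improvedLevel) {
    // ---- move phase -------------------------------------------------------
    std::vector<int> comm(n);
    for (int i = 0; i < n; ++i) comm[i] = i;
    std::vector<double> Scomm(d.begin(), d.end());   // sum of d per community
    std::vector<double> SZcomm(sz.begin(), sz.end());// sum of size per comm.
    std::vector<int> NCOM(n, 1);                     // members per community

    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;

    std::vector<double> wto(n, 0.0), eto(n, 0.0);
    std::vector<int> touched; touched.reserve(n);

    bool moved = true;
    int sweeps = 0;
    while (moved && sweeps < 100) {
      moved = false;
      ++sweeps;
      fisher_yates(order);
      for (int oi = 0; oi < n; ++oi) {
        int i = order[oi];
        int a = comm[i];
        // remove i from its community
        Scomm[a] -= d[i];
        SZcomm[a] -= sz[i];
        NCOM[a] -= 1;
        // neighbouring communities
        touched.clear();
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double w = W[i][j];
          double e = (mode == 1) ? E[i][j] : 0.0;
          if (w > 0 || e > 0) {
            int c = comm[j];
            if (wto[c] == 0.0 && eto[c] == 0.0) touched.push_back(c);
            wto[c] += w;
            eto[c] += e;
          }
        }
        // ensure the old community is considered even if i has no link to it
        if (wto[a] == 0.0 && eto[a] == 0.0 && NCOM[a] > 0) touched.push_back(a);
        std::sort(touched.begin(), touched.end());
        // best community; staying isolated has gain 0
        double bestGain = 0.0;
        int bestC = -1;
        for (size_t t = 0; t < touched.size(); ++t) {
          int c = touched[t];
          if (NCOM[c] == 0) continue;
          double g;
          if (mode == 0)
            g = tfac * wto[c] - gamma * d[i] * Scomm[c] / twoM;
          else
            g = wto[c] - gamma * (sz[i] * SZcomm[c] - eto[c]);
          if (g > bestGain + 1e-15) { bestGain = g; bestC = c; }
        }
        int target;
        if (bestC >= 0) {
          target = bestC;
        } else {
          // isolate: reuse own community if empty, else first empty slot
          if (NCOM[a] == 0) target = a;
          else {
            target = -1;
            for (int c = 0; c < n; ++c) if (NCOM[c] == 0) { target = c; break; }
            if (target < 0) target = a; // cannot happen: n slots, <= n comms
          }
        }
        comm[i] = target;
        Scomm[target] += d[i];
        SZcomm[target] += sz[i];
        NCOM[target] += 1;
        if (target != a) moved = true;
        for (size_t t = 0; t < touched.size(); ++t) {
          wto[touched[t]] = 0.0;
          eto[touched[t]] = 0.0;
        }
      }
    }

    // ---- aggregate --------------------------------------------------------
    std::vector<int> remap(n, -1);
    int k = 0;
    for (int i = 0; i < n; ++i)
      if (remap[comm[i]] < 0) remap[comm[i]] = k++;
    for (int i = 0; i < n; ++i) comm[i] = remap[comm[i]];

    for (int i = 0; i < n0; ++i) assign[i] = comm[assign[i]];

    improvedLevel = (k < n);
    if (improvedLevel) {
      std::vector<std::vector<double>> Wn(k, std::vector<double>(k, 0.0));
      std::vector<std::vector<double>> En(k, std::vector<double>(k, 0.0));
      std::vector<double> dn(k, 0.0), szn(k, 0.0);
      for (int i = 0; i < n; ++i) {
        dn[comm[i]] += d[i];
        szn[comm[i]] += sz[i];
        for (int j = i + 1; j < n; ++j) {
          int ci = comm[i], cj = comm[j];
          if (ci == cj) continue; // internal weight is constant under moves
          Wn[ci][cj] += W[i][j];
          Wn[cj][ci] += W[i][j];
          if (mode == 1) {
            En[ci][cj] += E[i][j];
            En[cj][ci] += E[i][j];
          }
        }
      }
      W.swap(Wn);
      E.swap(En);
      d.swap(dn);
      sz.swap(szn);
      n = k;
    }
  }

  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) out[i] = assign[i] + 1;
  return out;
}
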