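#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Louvain-style ascent for the symmetric hypergraph modularity
//   Q(z) = -sum_k [ beta_k cut_k(z) + gamma~_k sum_C rho(C)^k ],
// in the normalized volume representation (rho_v = d(v)/vol(V), gamma~_k =
// gamma_k vol(V)^k). Single-vertex sweeps in R-seeded random order alternate
// with edge-collapse proposals (relabelling an entire straddling hyperedge
// into one cluster) that let all-or-nothing hyperedges of size >= 3 become
// interior, which single moves cannot achieve from the singleton start.
// All randomness flows through R's RNG (Rcpp::sample), so results are
// reproducible under set.seed().

struct HWork {
  int n;
  std::vector<std::vector<int>> edges;   // 0-based vertex ids
  std::vector<double> a;                 // multiplicities
  std::vector<double> beta_e;            // beta of each edge's size
  std::vector<int> kidx;                 // edge -> index into ks
  std::vector<double> ks;                // distinct sizes (as double)
  std::vector<double> gs;                // scaled gamma per distinct size
  std::vector<double> rho;               // normalized vertex volumes
  std::vector<std::vector<int>> v2e;
};

static double full_q(const HWork& W, const std::vector<int>& z) {
  double q = 0.0;
  for (size_t j = 0; j < W.edges.size(); ++j) {
    const std::vector<int>& e = W.edges[j];
    const int z0 = z[e[0]];
    for (size_t t = 1; t < e.size(); ++t) {
      if (z[e[t]] != z0) { q -= W.beta_e[j] * W.a[j]; break; }
    }
  }
  std::vector<double> volC(W.n + 2, 0.0);
  for (int v = 0; v < W.n; ++v) volC[z[v]] += W.rho[v];
  for (size_t i = 0; i < W.ks.size(); ++i) {
    double s = 0.0;
    for (int c = 1; c <= W.n + 1; ++c) {
      if (volC[c] > 0.0) s += std::pow(volC[c], W.ks[i]);
    }
    q -= W.gs[i] * s;
  }
  return q;
}

// [[Rcpp::export(name = ".hmll_ascent")]]
List hmll_ascent(int n, List edge_list, NumericVector a, NumericVector beta_e,
                 IntegerVector kidx, NumericVector ks, NumericVector gs,
                 NumericVector rho, IntegerVector z0, int max_sweeps,
                 double tol, bool audit, bool merge_pass) {
  HWork W;
  W.n = n;
  const int M = edge_list.size();
  W.edges.resize(M);
  for (int j = 0; j < M; ++j) {
    IntegerVector e = edge_list[j];
    W.edges[j].assign(e.begin(), e.end());
    for (int& v : W.edges[j]) --v;       // to 0-based
  }
  W.a.assign(a.begin(), a.end());
  W.beta_e.assign(beta_e.begin(), beta_e.end());
  W.kidx.assign(kidx.begin(), kidx.end());   // already 0-based from R
  W.ks.assign(ks.begin(), ks.end());
  W.gs.assign(gs.begin(), gs.end());
  W.rho.assign(rho.begin(), rho.end());
  W.v2e.assign(n, {});
  for (int j = 0; j < M; ++j) {
    for (int v : W.edges[j]) W.v2e[v].push_back(j);
  }

  std::vector<int> z(z0.begin(), z0.end());  // labels 1..n
  std::vector<double> volC(n + 2, 0.0);
  std::vector<int> cnt(n + 2, 0);
  for (int v = 0; v < n; ++v) { volC[z[v]] += W.rho[v]; cnt[z[v]]++; }

  double q = full_q(W, z);
  double audit_dev = 0.0;
  long moves = 0;
  const int nk = (int)W.ks.size();

  std::vector<double> gain(n + 2, 0.0);
  std::vector<int> touched;
  std::vector<char> seen(n + 2, 0);
  std::vector<int> cand;

  auto fresh_label = [&]() {
    for (int c = 1; c <= n + 1; ++c) if (cnt[c] == 0) return c;
    return n + 1;
  };

  for (int phase = 0; phase < max_sweeps; ++phase) {
    // ---- single-vertex sweeps ----
    bool any_sweep_move = true;
    for (int sweep = 0; sweep < max_sweeps && any_sweep_move; ++sweep) {
      any_sweep_move = false;
      IntegerVector ord = Rcpp::sample(n, n, false);
      for (int oi = 0; oi < n; ++oi) {
        const int v = ord[oi] - 1;
        const int A = z[v];
        touched.clear();
        cand.clear();
        for (int j : W.v2e[v]) {
          const std::vector<int>& e = W.edges[j];
          if (e.size() < 2) continue;
          int unif = -1;
          bool uniform = true;
          for (int u : e) {
            if (u == v) continue;
            const int zu = z[u];
            if (!seen[zu]) { seen[zu] = 1; cand.push_back(zu); }
            if (unif == -1) unif = zu;
            else if (zu != unif) uniform = false;
          }
          if (uniform && unif != -1) {
            if (gain[unif] == 0.0) touched.push_back(unif);
            gain[unif] += W.beta_e[j] * W.a[j];
          }
        }
        for (int c : cand) seen[c] = 0;
        const double gA = gain[A];
        const double rv = W.rho[v];
        double dvolA = 0.0;
        for (int i = 0; i < nk; ++i) {
          dvolA -= W.gs[i] * (std::pow(volC[A] - rv, W.ks[i]) -
                              std::pow(volC[A], W.ks[i]));
        }
        if (cnt[A] > 1) cand.push_back(fresh_label());
        std::sort(cand.begin(), cand.end());
        double best_dq = tol;
        int best_B = -1;
        for (int B : cand) {
          if (B == A) continue;
          double dq = gain[B] - gA + dvolA;
          for (int i = 0; i < nk; ++i) {
            dq -= W.gs[i] * (std::pow(volC[B] + rv, W.ks[i]) -
                             std::pow(volC[B], W.ks[i]));
          }
          if (dq > best_dq) { best_dq = dq; best_B = B; }
        }
        for (int c : touched) gain[c] = 0.0;
        if (best_B >= 0) {
          z[v] = best_B;
          volC[A] -= rv; cnt[A]--;
          volC[best_B] += rv; cnt[best_B]++;
          q += best_dq;
          ++moves;
          any_sweep_move = true;
          if (audit) {
            const double qf = full_q(W, z);
            audit_dev = std::max(audit_dev, std::fabs(qf - q));
            q = qf;
          }
        }
      }
    }
    // ---- edge-collapse pass ----
    bool collapsed = false;
    {
      const double qf = full_q(W, z);
      audit_dev = std::max(audit_dev, std::fabs(qf - q));
      q = qf;
    }
    IntegerVector eord = (M > 0) ? Rcpp::sample(M, M, false) : IntegerVector(0);
    std::vector<char> emark(M, 0);
    std::vector<double> loss(n + 2, 0.0);
    for (int ei = 0; ei < M; ++ei) {
      const int j = eord[ei] - 1;
      const std::vector<int>& e = W.edges[j];
      if (e.size() < 2) continue;
      bool straddle = false;
      for (size_t t = 1; t < e.size(); ++t) {
        if (z[e[t]] != z[e[0]]) { straddle = true; break; }
      }
      if (!straddle) continue;
      // labels present in e (+ fresh)
      cand.clear();
      for (int u : e) {
        if (!seen[z[u]]) { seen[z[u]] = 1; cand.push_back(z[u]); }
      }
      for (int c : cand) seen[c] = 0;
      cand.push_back(fresh_label());
      std::sort(cand.begin(), cand.end());
      // affected edges: those sharing a vertex with e
      std::vector<int> aff;
      for (int u : e) {
        for (int f : W.v2e[u]) {
          if (!emark[f]) { emark[f] = 1; aff.push_back(f); }
        }
      }
      for (int f : aff) emark[f] = 0;
      double best_dq = tol;
      int best_L = -1;
      for (int L : cand) {
        // cut change
        double cut_gain = 0.0;
        for (int f : aff) {
          const std::vector<int>& ef = W.edges[f];
          bool unif_before = true, unif_after = true;
          int zb = -1, za = -1;
          for (int u : ef) {
            int lb = z[u];
            int la = lb;
            for (int w2 : e) { if (w2 == u) { la = L; break; } }
            if (zb == -1) zb = lb; else if (lb != zb) unif_before = false;
            if (za == -1) za = la; else if (la != za) unif_after = false;
            if (!unif_before && !unif_after) break;
          }
          cut_gain += W.beta_e[f] * W.a[f] *
            ((unif_after ? 1.0 : 0.0) - (unif_before ? 1.0 : 0.0));
        }
        // volume change: mass moving into L from other labels
        touched.clear();
        double gain_L = 0.0;
        for (int u : e) {
          if (z[u] != L) {
            if (loss[z[u]] == 0.0) touched.push_back(z[u]);
            loss[z[u]] += W.rho[u];
            gain_L += W.rho[u];
          }
        }
        double dvol = 0.0;
        for (int i = 0; i < nk; ++i) {
          double s = std::pow(volC[L] + gain_L, W.ks[i]) -
                     std::pow(volC[L], W.ks[i]);
          for (int c : touched) {
            s += std::pow(volC[c] - loss[c], W.ks[i]) -
                 std::pow(volC[c], W.ks[i]);
          }
          dvol += W.gs[i] * s;
        }
        for (int c : touched) loss[c] = 0.0;
        const double dq = cut_gain - dvol;
        if (dq > best_dq) { best_dq = dq; best_L = L; }
      }
      if (best_L >= 0) {
        for (int u : e) {
          if (z[u] != best_L) {
            volC[z[u]] -= W.rho[u]; cnt[z[u]]--;
            z[u] = best_L;
            volC[best_L] += W.rho[u]; cnt[best_L]++;
          }
        }
        q += best_dq;
        ++moves;
        collapsed = true;
        if (audit) {
          const double qf = full_q(W, z);
          audit_dev = std::max(audit_dev, std::fabs(qf - q));
          q = qf;
        }
      }
    }
    // ---- cluster-merge pass (super-node moves) ----
    // Vertex sweeps and edge collapses can fragment a community into
    // edge-connected sub-clusters that no single move can fuse; merging
    // whole clusters connected by straddling hyperedges is the Louvain
    // aggregation step expressed directly on the flat partition.
    bool merged_any = false;
    while (merge_pass) {
      // candidate pairs: labels co-occurring in a straddling edge
      std::set<std::pair<int,int>> pairs;
      for (int j = 0; j < M; ++j) {
        const std::vector<int>& e = W.edges[j];
        for (size_t s = 0; s < e.size(); ++s) {
          for (size_t t = s + 1; t < e.size(); ++t) {
            int c1 = z[e[s]], c2 = z[e[t]];
            if (c1 != c2) pairs.insert({std::min(c1, c2), std::max(c1, c2)});
          }
        }
      }
      if (pairs.empty()) break;
      double best_dq = tol;
      std::pair<int,int> best_pair{-1, -1};
      for (const auto& pr : pairs) {
        const int c1 = pr.first, c2 = pr.second;
        double cut_gain = 0.0;
        for (int j = 0; j < M; ++j) {
          const std::vector<int>& e = W.edges[j];
          bool before = true, after = true;
          int zb = -1, za = -1;
          for (int u : e) {
            const int lb = z[u];
            const int la = (lb == c2) ? c1 : lb;
            if (zb == -1) zb = lb; else if (lb != zb) before = false;
            if (za == -1) za = la; else if (la != za) after = false;
            if (!before && !after) break;
          }
          cut_gain += W.beta_e[j] * W.a[j] *
            ((after ? 1.0 : 0.0) - (before ? 1.0 : 0.0));
        }
        double dvol = 0.0;
        for (int i = 0; i < nk; ++i) {
          dvol += W.gs[i] * (std::pow(volC[c1] + volC[c2], W.ks[i]) -
                             std::pow(volC[c1], W.ks[i]) -
                             std::pow(volC[c2], W.ks[i]));
        }
        const double dq = cut_gain - dvol;
        if (dq > best_dq) { best_dq = dq; best_pair = pr; }
      }
      if (best_pair.first < 0) break;
      const int c1 = best_pair.first, c2 = best_pair.second;
      for (int v = 0; v < n; ++v) if (z[v] == c2) z[v] = c1;
      volC[c1] += volC[c2]; cnt[c1] += cnt[c2];
      volC[c2] = 0.0; cnt[c2] = 0;
      q += best_dq;
      ++moves;
      merged_any = true;
      if (audit) {
        const double qf = full_q(W, z);
        audit_dev = std::max(audit_dev, std::fabs(qf - q));
        q = qf;
      }
    }
    if (merged_any) collapsed = true;
    if (!collapsed) break;
  }
  q = full_q(W, z);
  if (!std::isfinite(q)) stop("non-finite modularity during ascent");
  return List::create(_["z"] = IntegerVector(z.begin(), z.end()),
                      _["q"] = q, _["moves"] = (double)moves,
                      _["audit_dev"] = audit_dev);
}
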