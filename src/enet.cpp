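#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for  min_w ||x - P w||^2 + lambda1 ||w||_1 + lambda2 ||w||_2^2
// parameterized by the Gram matrix G = P'P and q = P'x, solved along a
// lambda1 path with warm starts.  Zeros are exact (soft-threshold updates).
//
// Stationarity for coordinate j (others fixed):
//   w_j = S(2 c_j, lambda1) / (2 (G_jj + lambda2)),  c_j = q_j - sum_{k!=j} G_jk w_k
// where S(z, t) = sign(z) * max(|z| - t, 0).
//
// Iteration is glmnet-style: full passes over all coordinates alternate with
// inner loops restricted to the current active set (nonzero coefficients),
// whose Gw bookkeeping touches only active entries. A solution is accepted
// only when a full pass moves no coordinate by more than tol, which is the
// KKT check for the inactive set.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export(name = ".enet_cd_path")]]
List enet_cd_path(NumericMatrix G, NumericVector q, NumericVector lambda1,
                  double lambda2, int maxit, double tol) {
  const int p = q.size();
  const int L = lambda1.size();
  NumericMatrix W(p, L);
  IntegerVector iters(L);
  LogicalVector converged(L);
  NumericVector final_delta(L);
  const double* g = REAL(G);

  std::vector<double> w(p, 0.0), Gw(p, 0.0);
  std::vector<int> act;
  act.reserve(p);

  for (int l = 0; l < L; ++l) {
    const double lam1 = lambda1[l];
    bool ok = false;
    long total_it = 0;
    double maxdel = R_PosInf;
    for (int outer = 0; outer < maxit; ++outer) {
      // full pass, maintaining the complete Gw vector
      maxdel = 0.0;
      for (int j = 0; j < p; ++j) {
        const double gjj = g[j + (std::size_t)j * p];
        const double denom = 2.0 * (gjj + lambda2);
        double wnew = 0.0;
        if (denom > 0.0) {
          const double cj = q[j] - Gw[j] + gjj * w[j];
          wnew = soft(2.0 * cj, lam1) / denom;
        }
        const double del = wnew - w[j];
        if (del != 0.0) {
          const double* col = g + (std::size_t)j * p;
          for (int k = 0; k < p; ++k) Gw[k] += col[k] * del;
          w[j] = wnew;
          const double ad = std::fabs(del);
          if (ad > maxdel) maxdel = ad;
        }
      }
      ++total_it;
      if (maxdel < tol) { ok = true; break; }
      // inner loop on the active set only
      act.clear();
      for (int j = 0; j < p; ++j) if (w[j] != 0.0) act.push_back(j);
      const int na = (int)act.size();
      for (int it = 0; it < maxit; ++it) {
        double md = 0.0;
        for (int a = 0; a < na; ++a) {
          const int j = act[a];
          const double gjj = g[j + (std::size_t)j * p];
          const double denom = 2.0 * (gjj + lambda2);
          if (denom <= 0.0) continue;
          const double cj = q[j] - Gw[j] + gjj * w[j];
          const double wnew = soft(2.0 * cj, lam1) / denom;
          const double del = wnew - w[j];
          if (del != 0.0) {
            const double* col = g + (std::size_t)j * p;
            for (int b = 0; b < na; ++b) Gw[act[b]] += col[act[b]] * del;
            w[j] = wnew;
            const double ad = std::fabs(del);
            if (ad > md) md = ad;
          }
        }
        ++total_it;
        if (md < tol) break;
      }
      // refresh the full Gw before the verifying full pass
      std::fill(Gw.begin(), Gw.end(), 0.0);
      for (int j = 0; j < p; ++j) {
        if (w[j] != 0.0) {
          const double* col = g + (std::size_t)j * p;
          const double wj = w[j];
          for (int k = 0; k < p; ++k) Gw[k] += col[k] * wj;
        }
      }
    }
    iters[l] = (int)std::min<long>(total_it, INT_MAX);
    converged[l] = ok;
    final_delta[l] = maxdel;
    for (int j = 0; j < p; ++j) W(j, l) = w[j];
  }
  return List::create(_["W"] = W, _["iters"] = iters,
                      _["converged"] = converged, _["final_delta"] = final_delta);
}
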